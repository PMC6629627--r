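test_that("single-codon families and the start codon are left untouched", {
  r <- recode_first15("ATG")
  expect_equal(r$recoded_sequence, "ATG")
  expect_equal(nrow(r$substitutions), 0)
  # GTG start has synonyms as Val but is never altered
  r2 <- recode_first15("GTGGGC")
  expect_equal(substr(r2$recoded_sequence, 1, 3), "GTG")
})

test_that("four-codon families resolve per the scoring tuple", {
  # independent route: enumerate the Gly family and apply the rule by hand
  fam <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "G"]
  counts <- t(vapply(strsplit(fam, ""), function(x) {
    c(gc = sum(x %in% c("G", "C")), a = sum(x == "A"), t = sum(x == "T"))
  }, c(gc = 0, a = 0, t = 0)))
  manual <- fam[order(counts[, "gc"], -counts[, "a"], -counts[, "t"], fam)][1]
  expect_equal(manual, "GGA")
  r <- recode_first15("ATGGGC")
  expect_equal(substr(r$recoded_sequence, 4, 6), "GGA")
  expect_equal(r$substitutions$to, "GGA")
})

test_that("recoding preserves the protein, never raises GC, never lowers A", {
  set.seed(404)
  for (i in 1:40) {
    orf <- random_orf(sample(5:25, 1), gc_rich = (i %% 2 == 0))
    r <- recode_first15(orf)
    expect_equal(translate_orf(r$recoded_sequence), translate_orf(orf))
    head_len <- min(45, nchar(orf))
    expect_lte(gc_count(substr(r$recoded_sequence, 1, head_len)),
               gc_count(substr(orf, 1, head_len)))
    expect_gte(a_count(substr(r$recoded_sequence, 1, head_len)),
               a_count(substr(orf, 1, head_len)))
    # idempotence
    r2 <- recode_first15(r$recoded_sequence)
    expect_equal(r2$recoded_sequence, r$recoded_sequence)
    expect_equal(nrow(r2$substitutions), 0)
    # no stop codons introduced
    expect_false(grepl("\\*", substr(translate_orf(r$recoded_sequence), 1,
                                     nchar(orf) / 3 - 1)))
  }
})

test_that("short ORFs recode all complete codons except a final stop", {
  orf <- "ATGGGCGGCTAA"  # M G G *
  r <- recode_first15(orf)
  expect_equal(r$recoded_sequence, "ATGGGAGGATAA")
  expect_equal(r$substitutions$index, c(2L, 3L))
})

test_that("malformed ORFs are rejected", {
  expect_error(recode_first15("ATGTAAGGC"), "internal stop")
  expect_error(recode_first15("ATGGXC"), "non-ACGT")
  expect_error(recode_first15("ATGGG"), "multiple of 3")
  expect_error(recode_first15("CCCGGC"), "start codon")
})

test_that("unpairable windows score zero and forced hairpins score negative", {
  expect_equal(window_energy(strrep("A", 50)), 0)
  expect_equal(window_energy("ACA"), 0)  # too short to pair
  hairpin <- paste0(strrep("GC", 5), "AAAA", strrep("GC", 5))
  expect_lt(window_energy(hairpin), 0)
  # a 10-bp GC stem contributes at least -3 * 10 is the floor; sanity bound
  expect_gte(window_energy(hairpin), -3 * 10)
})

test_that("the nested-pairing model equals exhaustive-minimum enumeration", {
  set.seed(505)
  for (i in 1:40) {
    n <- sample(10:30, 1)
    rna <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
                        prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    expect_equal(window_energy(rna), enum_fold_energy(rna),
                 info = paste("window:", rna))
  }
})

test_that("transcript windows span +1 through ORF nucleotide 90", {
  utr <- strrep("ACGU", 10)  # rejected: U is not DNA
  expect_error(transcript_window(utr, "ATGAAA"), "A/C/G/T")
  utr <- strrep("ACGT", 10)
  orf <- random_orf(40)
  w <- transcript_window(utr, orf)
  expect_equal(nchar(w$sequence), 40 + 90)
  expect_equal(w$tss_offset, 40)
  # shorter ORFs truncate at the ORF end
  w2 <- transcript_window(utr, "ATGAAAGAA")
  expect_equal(nchar(w2$sequence), 40 + 9)
})

test_that("recode_report is a fixed point on AU-minimal heads and relieves GC-rich ones", {
  # every codon already the scoring-tuple minimum of its family
  minimal <- paste0("ATG", strrep("AAA", 14))
  rep0 <- recode_report("", minimal)
  expect_equal(rep0$recoded_sequence, minimal)
  expect_equal(nrow(rep0$substitutions), 0)
  expect_equal(rep0$window_energy_after, rep0$window_energy_before)

  set.seed(606)
  gc_orf <- random_orf(20, gc_rich = TRUE)
  repg <- recode_report(strrep("ACT", 5), gc_orf)
  expect_lt(gc_count(substr(repg$recoded_sequence, 1, 45)),
            gc_count(substr(gc_orf, 1, 45)))
})

test_that("recoding relieves predicted 5' structure for most GC-rich ORFs", {
  set.seed(707)
  relieved <- vapply(1:120, function(i) {
    orf <- random_orf(16, gc_rich = TRUE)
    r <- recode_report("TTATAAGGAGGAAAAA", orf)  # short structured leader + RBS-like UTR
    r$window_energy_after >= r$window_energy_before
  }, logical(1))
  expect_gte(mean(relieved), 0.9)
})

test_that("the external folding backend contract is explicit", {
  # a custom function backend is honored
  expect_equal(window_energy("GGGGAAAACCCC", backend = function(rna) -99), -99)
  expect_error(window_energy("GGGGAAAACCCC", backend = "nope"), "backend")
  if (nzchar(Sys.which("RNAfold"))) {
    e <- window_energy(paste0(strrep("GC", 8), "GAAA", strrep("GC", 8)), backend = "vienna")
    expect_lt(e, 0)
  }
})
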