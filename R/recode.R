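#' Synonymously recode the first 15 codons of an ORF
#'
#' Translation initiation in bacteria is highly sensitive to mRNA
#' secondary structure between the ribosome binding site and the early
#' coding sequence. This heuristic replaces each of the first 15 codons
#' with the synonymous codon that minimizes pairing potential: codons are
#' scored by the tuple (GC count ascending, A count descending, T/U count
#' descending, codon string ascending as the final tie-break), making the
#' choice deterministic. The start codon is never altered (initiation
#' identity is functional even when GTG/TTG have synonyms), the protein
#' sequence is always preserved, and stop codons are never introduced.
#' ORFs shorter than 15 codons have all complete codons recoded except a
#' final stop codon.
#'
#' @param orf DNA coding sequence (A/C/G/T), in frame, length a multiple
#'   of 3, starting with ATG, GTG or TTG.
#' @param table genetic code: named character vector mapping DNA codons to
#'   single-letter amino acids (default [Biostrings::GENETIC_CODE]).
#' @param n_codons how many leading codons to consider (default 15).
#' @return list of class `recoded_orf`: `original_sequence`,
#'   `recoded_sequence`, `substitutions` (data.frame `index`, `from`,
#'   `to`; 1-based codon indices).
#' @export
recode_first15 <- function(orf, table = Biostrings::GENETIC_CODE, n_codons = 15L) {
  codons <- split_codons(orf)
  aa <- translate_codons(codons, table)
  n_cod <- length(codons)
  stops <- which(aa == "*")
  if (length(stops) && any(stops < n_cod)) {
    stop("internal stop codon in frame", call. = FALSE)
  }
  if (!codons[1] %in% c("ATG", "GTG", "TTG")) {
    stop("ORF must start with a start codon (ATG/GTG/TTG)", call. = FALSE)
  }
  last <- min(n_codons, n_cod)
  if (last == n_cod && aa[n_cod] == "*") last <- n_cod - 1L
  recoded <- codons
  subs <- list()
  if (last >= 2L) {
    for (i in 2:last) {
      best <- best_synonym(codons[i], table)
      if (best != codons[i]) {
        subs[[length(subs) + 1L]] <- data.frame(index = i, from = codons[i],
                                                to = best)
        recoded[i] <- best
      }
    }
  }
  structure(list(original_sequence = paste(codons, collapse = ""),
                 recoded_sequence = paste(recoded, collapse = ""),
                 substitutions = if (length(subs)) do.call(rbind, subs) else
                   data.frame(index = integer(), from = character(), to = character())),
            class = "recoded_orf")
}

split_codons <- function(orf) {
  orf <- toupper(gsub("\\s", "", orf))
  if (nchar(orf) < 3L) stop("ORF must be at least one codon long", call. = FALSE)
  if (nchar(orf) %% 3L != 0L) stop("ORF length must be a multiple of 3", call. = FALSE)
  if (grepl("[^ACGT]", orf)) stop("ORF contains non-ACGT characters", call. = FALSE)
  substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
}

translate_codons <- function(codons, table) {
  aa <- unname(table[codons])
  if (any(is.na(aa))) stop("codon not in the genetic code table", call. = FALSE)
  aa
}

# lowest (GC asc, A desc, T desc, codon asc) synonymous codon for `codon`
best_synonym <- function(codon, table) {
  aa <- table[[codon]]
  fam <- names(table)[table == aa]
  counts <- function(c, b) vapply(strsplit(c, ""), function(x) sum(x %in% b), integer(1))
  ord <- order(counts(fam, c("G", "C")), -counts(fam, "A"), -counts(fam, "T"), fam)
  fam[ord[1]]
}

#' @export
print.recoded_orf <- function(x, ...) {
  cat(sprintf("<recoded_orf: %d nt, %d substitution(s)%s>\n",
              nchar(x$original_sequence), nrow(x$substitutions),
              if (!is.null(x$window_energy_before)) {
                sprintf(", window dG %.2f -> %.2f kcal/mol",
                        x$window_energy_before, x$window_energy_after)
              } else ""))
  if (nrow(x$substitutions)) print(x$substitutions, row.names = FALSE)
  invisible(x)
}

#' Transcript window from the transcription start site into the ORF
#'
#' The folding window used to score 5' structure runs from the
#' transcription start site (+1) through the 90th nucleotide of the ORF
#' (shorter ORFs truncate at the ORF end).
#'
#' @param utr 5' UTR sequence (from +1 to just before the start codon);
#'   may be empty.
#' @param orf ORF sequence.
#' @return list of class `transcript_window`: `sequence` (DNA),
#'   `tss_offset` (number of UTR nucleotides).
#' @export
transcript_window <- function(utr, orf) {
  utr <- toupper(gsub("\\s", "", utr))
  orf <- toupper(gsub("\\s", "", orf))
  if (grepl("[^ACGT]", paste0(utr, orf))) stop("sequences must be A/C/G/T", call. = FALSE)
  win <- paste0(utr, substr(orf, 1, min(90L, nchar(orf))))
  structure(list(sequence = win, tss_offset = nchar(utr)),
            class = "transcript_window")
}

#' Compose recoding and window-energy scoring
#'
#' Recodes the leading codons of the ORF, builds the transcript window
#' (same UTR) for the original and recoded sequences, and scores both by
#' folding free energy.
#'
#' @inheritParams transcript_window
#' @param backend folding backend, see [window_energy()].
#' @param table genetic code table.
#' @return A `recoded_orf` with `window_energy_before` and
#'   `window_energy_after` (kcal/mol) added.
#' @export
recode_report <- function(utr, orf, backend = "nussinov",
                          table = Biostrings::GENETIC_CODE) {
  rec <- recode_first15(orf, table = table)
  rec$window_energy_before <- window_energy(transcript_window(utr, orf), backend)
  rec$window_energy_after <- window_energy(transcript_window(utr, rec$recoded_sequence), backend)
  rec
}
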