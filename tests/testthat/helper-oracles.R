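# Independent oracles used across the suite. Each reimplements the quantity
# it checks by a different route than the package code.

# Exact product-Gaussian KDE evaluated pairwise at each point (no grid).
exact_kde_at <- function(x, y, hx, hy) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(dnorm((x[i] - x) / (hx / 4)) * dnorm((y[i] - y) / (hy / 4)))
  }, numeric(1))
}

# Minimum folding energy by memoized recursion on the LAST position of the
# interval (the package DP decomposes on the first position): position j is
# unpaired, or pairs with some k <= j - 4.
enum_fold_energy <- function(rna) {
  s <- strsplit(rna, "")[[1]]
  n <- length(s)
  pe <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1, NA_real_)
  }
  memo <- new.env(parent = emptyenv())
  best <- function(i, j) {
    if (j - i < 4L) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- best(i, j - 1L)
    for (k in i:(j - 4L)) {
      e <- pe(s[k], s[j])
      if (!is.na(e)) {
        left <- if (k - 1L >= i) best(i, k - 1L) else 0
        v <- min(v, e + left + best(k + 1L, j - 1L))
      }
    }
    memo[[key]] <- v
    v
  }
  if (n < 5L) 0 else best(1L, n)
}

# Dense grid search over the pooled log-residual Hill objective.
hill_grid_min <- function(x, y, grid_y0, grid_dy, grid_n, grid_K) {
  obj <- function(y0, dy, n, K) {
    p <- hill_params(y0, dy, n, K)
    sum((log(y) - log(hill_eval(p, x)))^2)
  }
  best <- Inf; arg <- NULL
  for (y0 in grid_y0) for (dy in grid_dy) for (n in grid_n) for (K in grid_K) {
    v <- obj(y0, dy, n, K)
    if (v < best) { best <- v; arg <- c(y0 = y0, dy = dy, n = n, K = K) }
  }
  list(min = best, arg = arg)
}

# Random in-frame ORF: fixed start codon, no internal stops.
random_orf <- function(n_codons, gc_rich = FALSE) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  pool <- if (gc_rich) sense[vapply(strsplit(sense, ""),
                                    function(x) sum(x %in% c("G", "C")),
                                    integer(1)) >= 2] else sense
  paste0("ATG", paste(sample(pool, n_codons - 1L, replace = TRUE), collapse = ""))
}

gc_count <- function(seq) sum(strsplit(seq, "")[[1]] %in% c("G", "C"))
a_count <- function(seq) sum(strsplit(seq, "")[[1]] == "A")

translate_orf <- function(orf) {
  cods <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
  paste(Biostrings::GENETIC_CODE[cods], collapse = "")
}

paper_hill_truth <- function() hill_params(2000, 106700, 1.88, 4.66)
default_kinetic_truth <- function() kinetic_params(0.02, 0.05, 0.03, 15)
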