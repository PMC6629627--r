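#' Minimum folding free energy of a transcript window
#'
#' Scores the RNA transcript of a window (DNA input, T transcribed to U)
#' by its minimum free energy over admissible nested secondary
#' structures. The result is always <= 0; a sequence admitting no
#' canonical pair (e.g. poly-A) scores 0.
#'
#' Backends:
#' \describe{
#'   \item{`"nussinov"` (default)}{Built-in simplified nested-pairing
#'     model: stacking-free pair energies GC = -3, AU = -2, GU = -1
#'     kcal/mol, minimum hairpin loop of 3 unpaired nucleotides, no
#'     pseudoknots, minimized by interval dynamic programming. This is
#'     the reference model for all property tests.}
#'   \item{`"vienna"`}{External thermodynamic folding via the `RNAfold`
#'     executable (ViennaRNA), when installed.}
#'   \item{a function}{Any `function(rna_sequence) -> energy` acts as a
#'     pluggable backend.}
#' }
#'
#' @param window a [transcript_window()] (or a plain DNA/RNA string).
#' @param backend `"nussinov"`, `"vienna"`, or a function.
#' @return Minimum free energy in kcal/mol (<= 0).
#' @export
window_energy <- function(window, backend = "nussinov") {
  seq <- if (inherits(window, "transcript_window")) window$sequence else
    toupper(gsub("\\s", "", window))
  rna <- chartr("T", "U", seq)
  if (grepl("[^ACGU]", rna)) stop("window must be an A/C/G/T(U) sequence", call. = FALSE)
  if (is.function(backend)) return(backend(rna))
  switch(backend,
         nussinov = nussinov_energy(rna),
         vienna = vienna_energy(rna),
         stop(sprintf("unknown folding backend '%s'; provide \"nussinov\", \"vienna\", or a function(rna) -> energy",
                      backend), call. = FALSE))
}

# pair energies of the simplified model; +Inf marks a disallowed pair
pair_energy_value <- function(a, b) {
  key <- paste0(a, b)
  e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  unname(e[key])
}

# Interval DP over E[i, j] = min energy of s[i..j] with min hairpin loop 3:
# either i is unpaired, or i pairs with some k >= i + 4.
nussinov_energy <- function(rna) {
  n <- nchar(rna)
  if (n < 5L) return(0)
  s <- strsplit(rna, "")[[1]]
  E <- matrix(0, n, n)
  for (len in 5:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      best <- E[i + 1L, j]
      ks <- (i + 4L):j
      pe <- pair_energy_value(s[i], s[ks])
      ok <- which(!is.na(pe))
      if (length(ok)) {
        k <- ks[ok]
        inner <- ifelse(k - 1L >= i + 1L, E[cbind(i + 1L, k - 1L)], 0)
        outer <- ifelse(k + 1L <= j, E[cbind(pmin(k + 1L, n), j)], 0)
        outer[k + 1L > j] <- 0
        best <- min(best, pe[ok] + inner + outer)
      }
      E[i, j] <- best
    }
  }
  E[1L, n]
}

vienna_energy <- function(rna) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop(paste("folding backend 'vienna' requires the RNAfold executable on PATH;",
               "install ViennaRNA or use the built-in \"nussinov\" backend"),
         call. = FALSE)
  }
  out <- system2(exe, args = c("--noPS"), input = rna, stdout = TRUE)
  last <- out[length(out)]
  m <- regmatches(last, regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", last))
  if (!length(m)) stop("could not parse RNAfold output", call. = FALSE)
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}
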