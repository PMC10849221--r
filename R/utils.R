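# Coordinate convention used throughout: +1 is the first nucleotide of the
# start codon, -1 the nucleotide immediately upstream; there is no position
# 0 and windows are inclusive of both endpoints.

#' Extract a window around the start codon in start-codon coordinates
#'
#' @param utr5 5'-UTR nucleotide string (may be empty).
#' @param cds coding sequence nucleotide string.
#' @param window integer vector `c(start, end)` in start-codon coordinates
#'   (negative = upstream, positive = CDS; no position 0).
#' @return A list with `seq` (the available subsequence) and `complete`
#'   (TRUE iff the full window is covered by the supplied sequence).
#' @export
window_subseq <- function(utr5, cds, window) {
  stopifnot(length(window) == 2)
  if (window[1] > window[2]) stop("invalid window: start > end")
  if (any(window == 0)) stop("position 0 does not exist in this coordinate system")
  full <- paste0(utr5, cds)
  u <- nchar(utr5)
  pos_to_idx <- function(p) if (p > 0) u + p else u + p + 1
  i <- pos_to_idx(window[1])
  j <- pos_to_idx(window[2])
  lo <- max(1L, i)
  hi <- min(nchar(full), j)
  seq <- if (lo <= hi) substr(full, lo, hi) else ""
  list(seq = seq, complete = (i >= 1 && j <= nchar(full)))
}

normalize_nt <- function(x) {
  x <- toupper(gsub("\\s+", "", x))
  gsub("U", "T", x, fixed = TRUE)
}

assert_nt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTRYSWKMBDHVN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-IUPAC letters: %s", what,
                 paste(unique(unlist(strsplit(gsub("[ACGTRYSWKMBDHVN]", "", x[bad]), ""))),
                       collapse = ", ")))
  }
  invisible(x)
}

split_codons <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3")
  substring(cds, seq(1, nchar(cds), by = 3), seq(3, nchar(cds), by = 3))
}

geometric_mean <- function(x) exp(mean(log(x)))
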