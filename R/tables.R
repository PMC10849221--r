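# Packaged reference tables: genetic-code helpers, the dipeptide
# instability weights (Guruprasad et al. 1990), the bacterial N-end rule,
# wobble penalties for tAI, and a synthetic tRNA gene-copy table.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "CTG", "GTG", "TTG")

codon_env <- new.env(parent = emptyenv())

#' Codon-to-amino-acid mapping (standard code)
#' @return Named character vector over all 64 codons; stops are `*`.
#' @export
codon_table <- function() {
  if (is.null(codon_env$tab)) {
    nt <- c("T", "C", "A", "G")
    codons <- as.vector(t(outer(as.vector(t(outer(nt, nt, paste0))), nt, paste0)))
    aa <- vapply(codons, function(cd) seqinr::translate(seqinr::s2c(cd)), character(1))
    codon_env$tab <- setNames(aa, codons)
  }
  codon_env$tab
}

sense_codons <- function() {
  tab <- codon_table()
  names(tab)[tab != "*"]
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Dipeptide instability weight values (DIWV)
#'
#' The published 20 x 20 dipeptide weights behind the protein instability
#' index; rows index the first residue of the dipeptide, columns the second.
#'
#' @return A 20 x 20 numeric matrix with amino-acid one-letter dimnames.
#' @export
diwv_table <- function() {
  v <- c(
    1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
    1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
    1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
    1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
    -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
    1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
    1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
    13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
    1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
    20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
    1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
    1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
    1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
    1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
    1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
    -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
    24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34)
  matrix(v, nrow = 20, byrow = TRUE, dimnames = list(AA_LETTERS, AA_LETTERS))
}

#' Bacterial N-end rule half-life classes
#'
#' Destabilizing N-terminal residues (L, F, W, Y, R, K) give a half-life
#' under two minutes; proline is excluded (its class cannot be called from
#' the N-end rule alone); all other residues are stabilizing (over ten
#' hours).
#'
#' @return Named character vector residue -> class.
#' @export
n_end_rules <- function() {
  cls <- setNames(rep("STABLE_GT_10H", 20), AA_LETTERS)
  cls[c("L", "F", "W", "Y", "R", "K")] <- "UNSTABLE_LT_2MIN"
  cls["P"] <- "EXCLUDED_PRO"
  cls
}

#' Default wobble-pairing selective constraints (s-values) for tAI
#'
#' Standard anticodon:codon wobble penalties: Watson-Crick pairs carry no
#' penalty; `G:U` 0.41, `I:C` 0.28, `I:A` 0.9999, `U:G` 0.68 and the
#' lysidine-modified `C:A` (AUA decoding) 0.89.
#'
#' @return Named numeric vector of penalties in `[0, 1]`.
#' @export
default_s_values <- function() {
  c("G:U" = 0.41, "I:C" = 0.28, "I:A" = 0.9999, "U:G" = 0.68, "L:A" = 0.89)
}

#' Synthetic tRNA gene-copy table (E. coli K-12-like inventory)
#'
#' A stand-in copy-number table with an anticodon inventory structured like
#' the E. coli K-12 tRNA gene set (GNN isoacceptors reading NNC/NNU boxes,
#' UNN reading NNA, CNN reading NNG where those codons are sense). Copy
#' numbers are representative magnitudes, not measured values; supply your
#' own table for organism-accurate tAI.
#'
#' @return A tibble with columns `anticodon` and `copies`.
#' @export
default_trna_copies <- function() {
  tab <- codon_table()
  base_copies <- c(A = 5, R = 4, N = 2, D = 3, C = 1, Q = 2, E = 4, G = 5,
                   H = 1, I = 3, L = 5, K = 4, M = 4, F = 2, P = 3, S = 4,
                   T = 3, V = 5, W = 1, Y = 2)
  rows <- list()
  prefixes <- unique(substr(sense_codons(), 1, 2))
  for (pre in prefixes) {
    for (third in c("C", "A", "G")) {
      codon <- paste0(pre, third)
      if (is.na(tab[codon]) || tab[codon] == "*") next
      aa <- tab[[codon]]
      anti <- revcomp(codon)
      copies <- unname(base_copies[aa]) + if (third == "C") 1L else 0L
      rows[[length(rows) + 1]] <- tibble::tibble(anticodon = anti, copies = copies)
    }
  }
  out <- dplyr::distinct(dplyr::bind_rows(rows))
  stopifnot(!anyDuplicated(out$anticodon))
  out
}

#' Default per-codon ribosome dwell times
#'
#' Dwell time inversely proportional to the codon's tAI weight under the
#' packaged tRNA copy table, rescaled so the mean dwell over the 61 sense
#' codons is `mean_dwell` seconds (default 0.05 s, i.e. 20 codons/s).
#'
#' @param mean_dwell target mean dwell time in seconds.
#' @param trna_copies tRNA copy table (see [default_trna_copies()]).
#' @param s_values wobble penalties (see [default_s_values()]).
#' @return Named numeric vector codon -> dwell time (s) over sense codons.
#' @export
default_dwell_times <- function(mean_dwell = 0.05,
                                trna_copies = default_trna_copies(),
                                s_values = default_s_values()) {
  w <- tai_weights(trna_copies, s_values)
  dwell <- 1 / w
  dwell * (mean_dwell / mean(dwell))
}
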