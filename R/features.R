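#' Classify upstream AUG occurrence in the 5'-UTR
#'
#' Scans the window from `-window_len` to `-3` (start-codon coordinates)
#' for an upstream ATG. An upstream ATG whose offset from the main start
#' codon is divisible by 3 is in frame with the ORF; when both frames
#' occur, in-frame takes precedence.
#'
#' @param utr5 5'-UTR string (may be shorter than the window; only the
#'   available sequence is scanned).
#' @param window_len upstream window length in nucleotides (default 12).
#' @return One of `"NONE"`, `"IN_FRAME"`, `"OUT_OF_FRAME"`.
#' @export
classify_uaug <- function(utr5, window_len = 12) {
  u <- nchar(utr5)
  if (u < 3) return("NONE")
  found <- character()
  for (p in seq(-min(window_len, u), -3)) {
    # p is the start position of a candidate uATG (p..p+2, all upstream)
    idx <- u + p + 1
    if (substr(utr5, idx, idx + 2) == "ATG") {
      found <- c(found, if ((-p) %% 3 == 0) "IN_FRAME" else "OUT_OF_FRAME")
    }
  }
  if (length(found) == 0) return("NONE")
  if ("IN_FRAME" %in% found) "IN_FRAME" else "OUT_OF_FRAME"
}

#' Start / stop codon type of a filtered CDS
#' @param cds coding sequence passing [filter_protein_coding()].
#' @return The first codon (one of ATG/GTG/TTG/CTG) or the terminal stop
#'   codon (one of TAA/TGA/TAG).
#' @export
start_codon_type <- function(cds) {
  cd <- substr(cds, 1, 3)
  if (!cd %in% START_CODONS) stop("not a standard start codon: ", cd)
  cd
}

#' @rdname start_codon_type
#' @export
stop_codon_type <- function(cds) {
  cd <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (!cd %in% STOP_CODONS) stop("terminal codon is not a stop codon: ", cd)
  cd
}

#' Build codon relative-adaptiveness weights from a reference CDS set
#'
#' Sharp-Li relative adaptiveness: within each synonymous family the weight
#' of a codon is its count divided by the count of the most frequent
#' synonym. Zero counts are replaced by a pseudo-count of 0.5 occurrences
#' before division. Stop codons are excluded, as is the initiator codon of
#' each reference CDS.
#'
#' @param reference_cds character vector of CDS sequences.
#' @return Named numeric vector codon -> weight in (0, 1] over the 61
#'   sense codons.
#' @export
build_cai_weights <- function(reference_cds) {
  if (length(reference_cds) == 0) stop("empty reference set")
  counts <- setNames(numeric(length(sense_codons())), sense_codons())
  for (cds in reference_cds) {
    codons <- split_codons(cds)
    codons <- codons[-1]                      # initiator excluded
    codons <- codons[!codons %in% STOP_CODONS]
    t <- table(codons)
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  tab <- codon_table()
  w <- counts
  for (aa in unique(tab[sense_codons()])) {
    fam <- sense_codons()[tab[sense_codons()] == aa]
    cc <- counts[fam]
    if (all(cc == 0)) {
      warning("amino acid ", aa, " absent from reference; its codons get weight 1")
      w[fam] <- 1
      next
    }
    cc[cc == 0] <- 0.5
    w[fam] <- cc / max(cc)
  }
  w
}

#' Codon adaptation index of a CDS
#'
#' Geometric mean of relative-adaptiveness weights over codons 2..L-1
#' (initiator and stop excluded).
#'
#' @param cds coding sequence.
#' @param weights named weight vector from [build_cai_weights()].
#' @return CAI in (0, 1].
#' @export
compute_cai <- function(cds, weights) {
  codons <- body_codons(cds)
  if (length(codons) == 0) stop("no codons between initiator and stop")
  missing <- setdiff(unique(codons), names(weights))
  if (length(missing)) stop("weights missing for codons: ", paste(missing, collapse = ", "))
  geometric_mean(weights[codons])
}

body_codons <- function(cds) {
  codons <- split_codons(cds)
  n <- length(codons)
  keep <- codons[-c(1, n)]
  keep[!keep %in% STOP_CODONS]
}

#' Absolute and relative tAI codon weights from a tRNA gene-copy table
#'
#' For each sense codon the absolute adaptiveness is
#' `W = sum over recognizing anticodons of (1 - s) * copies`, combining the
#' Watson-Crick anticodon with the wobble anticodon implied by the codon's
#' third base (`G:U`, `I:C`, `I:A`, `U:G` penalties), plus the
#' lysidine-modified CAT anticodon for AUA. Relative weights are `W /
#' max(W)`; zero weights are replaced by the geometric mean of the nonzero
#' weights.
#'
#' @param trna_copies tibble with columns `anticodon`, `copies`.
#' @param s_values named wobble penalties (see [default_s_values()]).
#' @return Named numeric vector codon -> relative weight over sense codons.
#' @export
tai_weights <- function(trna_copies = default_trna_copies(),
                        s_values = default_s_values()) {
  copies <- setNames(trna_copies$copies, trna_copies$anticodon)
  n_of <- function(anti) if (anti %in% names(copies)) copies[[anti]] else 0
  W <- setNames(numeric(length(sense_codons())), sense_codons())
  for (codon in sense_codons()) {
    wc <- revcomp(codon)
    third <- substr(codon, 3, 3)
    wob <- switch(third,
      "T" = list(anti = paste0("G", substr(wc, 2, 3)), s = s_values[["G:U"]]),
      "C" = list(anti = paste0("A", substr(wc, 2, 3)), s = s_values[["I:C"]]),
      "A" = list(anti = paste0("A", substr(wc, 2, 3)), s = s_values[["I:A"]]),
      "G" = list(anti = paste0("T", substr(wc, 2, 3)), s = s_values[["U:G"]]))
    W[codon] <- n_of(wc) + (1 - wob$s) * n_of(wob$anti)
    if (codon == "ATA") {
      W[codon] <- W[codon] + (1 - s_values[["L:A"]]) * n_of("CAT")
    }
  }
  if (all(W == 0)) stop("all-zero adaptiveness: tRNA copy table covers no codon")
  w <- W / max(W)
  if (any(w == 0)) w[w == 0] <- geometric_mean(w[w > 0])
  w
}

#' tRNA adaptation index of a CDS
#'
#' Geometric mean of relative tAI weights over codons 2..L-1.
#'
#' @param cds coding sequence.
#' @param trna_copies tRNA gene-copy table (see [default_trna_copies()]).
#' @param s_values wobble penalties (see [default_s_values()]).
#' @return tAI in (0, 1].
#' @export
compute_tai <- function(cds, trna_copies = default_trna_copies(),
                        s_values = default_s_values()) {
  w <- tai_weights(trna_copies, s_values)
  codons <- body_codons(cds)
  if (length(codons) == 0) stop("no codons between initiator and stop")
  geometric_mean(w[codons])
}

#' Folding energy of a window around the start codon
#'
#' Computes the minimum free energy of the windowed subsequence in
#' start-codon coordinates. The default backend is a deterministic Nussinov
#' base-pair maximization (minimum hairpin loop 3, pseudo-energy -1.0
#' kcal/mol per pair); the `"vienna"` backend shells out to `RNAfold` for a
#' nearest-neighbor thermodynamic MFE when that program is on the PATH.
#'
#' @param utr5,cds sequences flanking the start codon.
#' @param window `c(start, end)` in start-codon coordinates.
#' @param backend `"nussinov"` (default) or `"vienna"`.
#' @return MFE in kcal/mol (<= 0), or `NA` when the available sequence does
#'   not cover the full window.
#' @export
folding_energy_window <- function(utr5, cds, window = c(1, 30),
                                  backend = c("nussinov", "vienna")) {
  backend <- match.arg(backend)
  ws <- window_subseq(utr5, cds, window)
  if (!ws$complete) return(NA_real_)
  fold_mfe(ws$seq, backend)
}

fold_mfe <- function(seq, backend = "nussinov") {
  if (nchar(seq) == 0) return(0)
  if (backend == "vienna") {
    if (Sys.which("RNAfold") == "") stop("RNAfold not found on PATH")
    out <- system2("RNAfold", c("--noPS"), input = seq, stdout = TRUE)
    m <- regmatches(out[2], regexpr("-?[0-9]+\\.?[0-9]*(?= ?\\)$)", out[2], perl = TRUE))
    return(as.numeric(m))
  }
  -1.0 * nussinov_maxpairs_cpp(seq, 3L)
}

#' N-end rule half-life class of a protein
#'
#' The classified residue is the second residue when N-terminal methionine
#' excision applies (default policy: residue 2 in A, C, G, P, S, T, V),
#' otherwise the initiator methionine. Destabilizing residues give a
#' half-life under 2 minutes, proline is excluded, everything else is
#' stable beyond 10 hours.
#'
#' @param protein amino-acid string starting with M.
#' @param met_excision `"small-residue"` (default), `"always"`, or `"never"`.
#' @return One of `"STABLE_GT_10H"`, `"UNSTABLE_LT_2MIN"`, `"EXCLUDED_PRO"`.
#' @export
n_end_half_life <- function(protein, met_excision = c("small-residue", "always", "never")) {
  met_excision <- match.arg(met_excision)
  if (substr(protein, 1, 1) != "M") stop("protein must start with initiator M")
  res <- substr(protein, 1, 1)
  if (nchar(protein) >= 2) {
    second <- substr(protein, 2, 2)
    excise <- switch(met_excision,
      "small-residue" = second %in% c("A", "C", "G", "P", "S", "T", "V"),
      "always" = TRUE,
      "never" = FALSE)
    if (excise) res <- second
  }
  rules <- n_end_rules()
  if (!res %in% names(rules)) stop("unknown residue: ", res)
  unname(rules[res])
}

#' Protein instability index
#'
#' `II = (10 / L) * sum over consecutive dipeptides of DIWV(x_i, x_{i+1})`
#' using the packaged dipeptide instability weights; values above 40
#' predict an unstable protein in vitro.
#'
#' @param protein amino-acid string (length >= 2).
#' @return Instability index (dimensionless).
#' @export
instability_index <- function(protein) {
  L <- nchar(protein)
  if (L < 2) stop("protein must have at least 2 residues")
  aa <- strsplit(protein, "")[[1]]
  if (!all(aa %in% AA_LETTERS)) {
    stop("unknown residue letter: ", paste(setdiff(aa, AA_LETTERS), collapse = ", "))
  }
  diwv <- diwv_table()
  (10 / L) * sum(diwv[cbind(aa[-L], aa[-1])])
}

#' Positional nucleotide frequency matrix around the start codon
#'
#' Relative A/C/G/T frequencies at each position of the window, computed
#' over the records that cover that position.
#'
#' @param records gene-record tibble (see [assemble_gene_records()]).
#' @param window `c(start, end)` in start-codon coordinates (default
#'   `c(-15, 15)`).
#' @return A tibble with columns `position`, `A`, `C`, `G`, `T`, `n_obs`;
#'   each covered row's frequencies sum to 1.
#' @export
nucleotide_frequency_matrix <- function(records, window = c(-15, 15)) {
  if (nrow(records) == 0) stop("no records")
  positions <- setdiff(seq(window[1], window[2]), 0)
  rows <- lapply(positions, function(p) {
    nts <- vapply(seq_len(nrow(records)), function(i) {
      ws <- window_subseq(records$utr5[i], records$cds[i], c(p, p))
      if (ws$complete) ws$seq else NA_character_
    }, character(1))
    nts <- nts[!is.na(nts)]
    n <- length(nts)
    cnt <- table(factor(nts, levels = c("A", "C", "G", "T")))
    freq <- if (n > 0) as.numeric(cnt) / n else rep(NA_real_, 4)
    tibble::tibble(position = p, A = freq[1], C = freq[2], G = freq[3],
                   T = freq[4], n_obs = n)
  })
  dplyr::bind_rows(rows)
}

#' Compute per-gene sequence and protein features
#'
#' @param records gene-record tibble.
#' @param cai_weights optional named weight vector; defaults to weights
#'   built from the input CDS set itself (self-referential usage).
#' @param trna_copies,s_values tAI inputs.
#' @param uaug_window upstream window length for [classify_uaug()].
#' @param fold_backend folding backend for the MFE windows.
#' @return A tibble with one row per gene: `Type` (first-in-operon),
#'   `uAUG`, `Start`, `Stop`, `CAI`, `tAI`, `MFE_m30_m1`, `MFE_p1_p30`,
#'   `Length` (amino acids), `Nend`, `Instability`.
#' @export
compute_features <- function(records, cai_weights = NULL,
                             trna_copies = default_trna_copies(),
                             s_values = default_s_values(),
                             uaug_window = 12, fold_backend = "nussinov") {
  if (is.null(cai_weights)) cai_weights <- build_cai_weights(records$cds)
  tai_w <- tai_weights(trna_copies, s_values)
  tibble::tibble(
    gene_id = records$gene_id,
    Type = records$is_first_gene,
    uAUG = vapply(records$utr5, classify_uaug, character(1),
                  window_len = uaug_window, USE.NAMES = FALSE),
    Start = vapply(records$cds, start_codon_type, character(1), USE.NAMES = FALSE),
    Stop = vapply(records$cds, stop_codon_type, character(1), USE.NAMES = FALSE),
    CAI = vapply(records$cds, function(s) geometric_mean(cai_weights[body_codons(s)]),
                 numeric(1), USE.NAMES = FALSE),
    tAI = vapply(records$cds, function(s) geometric_mean(tai_w[body_codons(s)]),
                 numeric(1), USE.NAMES = FALSE),
    MFE_m30_m1 = purrr::map2_dbl(records$utr5, records$cds,
                                 ~folding_energy_window(.x, .y, c(-30, -1), fold_backend)),
    MFE_p1_p30 = purrr::map2_dbl(records$utr5, records$cds,
                                 ~folding_energy_window(.x, .y, c(1, 30), fold_backend)),
    Length = nchar(records$protein),
    Nend = vapply(records$protein, n_end_half_life, character(1), USE.NAMES = FALSE),
    Instability = vapply(records$protein, instability_index, numeric(1), USE.NAMES = FALSE)
  )
}

#' Assemble the model feature table
#'
#' Joins sequence/protein features, translation-rate features and the
#' response table. Candidate windowed-MFE features whose missing fraction
#' across the joined data exceeds `missing_threshold` are dropped entirely
#' (never imputed); genes missing any retained numeric feature are then
#' dropped and recorded in the `"dropped_genes"` attribute. Categorical
#' features are one-hot encoded with the most frequent level as reference;
#' the encoded 0/1 columns are appended and their block structure stored in
#' the `"feature_blocks"` attribute.
#'
#' @param features tibble from [compute_features()].
#' @param rates tibble from [compute_rate_profiles()] (columns `gene_id`,
#'   `InitRate`, `ElongRate`, optionally `TransimTR`).
#' @param responses tibble from [build_response()].
#' @param missing_threshold maximum tolerated missing fraction for a
#'   windowed-MFE feature (default 0.15).
#' @return The joined, encoded feature table.
#' @export
build_feature_table <- function(features, rates, responses,
                                missing_threshold = 0.15) {
  tbl <- dplyr::inner_join(features, rates, by = "gene_id")
  tbl <- dplyr::inner_join(tbl, responses, by = "gene_id")
  if (nrow(tbl) == 0) stop("empty joined feature table")

  mfe_cols <- grep("^MFE_", names(tbl), value = TRUE)
  dropped_features <- character()
  for (cc in mfe_cols) {
    if (mean(is.na(tbl[[cc]])) > missing_threshold) {
      tbl[[cc]] <- NULL
      dropped_features <- c(dropped_features, cc)
    }
  }
  num_cols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  incomplete <- !stats::complete.cases(tbl[num_cols])
  dropped_genes <- tbl$gene_id[incomplete]
  tbl <- tbl[!incomplete, ]
  if (nrow(tbl) == 0) stop("all genes dropped by missing-feature filter")

  enc <- encode_onehot(tbl)
  out <- dplyr::bind_cols(tbl, enc$columns)
  attr(out, "feature_blocks") <- enc$blocks
  attr(out, "dropped_features") <- dropped_features
  attr(out, "dropped_genes") <- dropped_genes
  out
}

# One-hot encode Type/uAUG/Start/Stop/Nend with the most frequent level as
# reference; numeric features map to themselves. Returns the new columns
# and a feature -> encoded-column mapping (the atomic blocks used by the
# subset search).
encode_onehot <- function(tbl) {
  blocks <- list()
  cols <- list()
  categorical <- intersect(c("uAUG", "Start", "Stop", "Nend"), names(tbl))
  for (cc in categorical) {
    lev <- names(sort(table(tbl[[cc]]), decreasing = TRUE))
    for (l in lev[-1]) {
      nm <- paste0(cc, "_", l)
      cols[[nm]] <- as.numeric(tbl[[cc]] == l)
      blocks[[cc]] <- c(blocks[[cc]], nm)
    }
    if (length(lev) == 1) blocks[[cc]] <- character()
  }
  if ("Type" %in% names(tbl)) {
    cols[["Type_num"]] <- as.numeric(tbl$Type)
    blocks[["Type"]] <- "Type_num"
  }
  for (cc in intersect(c("CAI", "tAI", "MFE_p1_p30", "MFE_m30_m1",
                         "Length", "Instability"), names(tbl))) {
    blocks[[cc]] <- cc
  }
  list(columns = tibble::as_tibble(cols), blocks = blocks)
}
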