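# Shared fixture builders; everything is generated in code at test time.

# A tiny hand-built gene-record tibble with controllable UTR lengths.
make_records <- function(utr_lens = rep(35, 6), seed = 1) {
  set.seed(seed)
  n <- length(utr_lens)
  body <- setdiff(sense_codons_for_tests(), c("TAA", "TAG", "TGA"))
  cds <- vapply(seq_len(n), function(i) {
    paste(c("ATG", sample(body, 30, replace = TRUE), "TAA"), collapse = "")
  }, character(1))
  utr <- vapply(utr_lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  kept <- filter_protein_coding(tibble::tibble(gene_id = sprintf("t%02d", 1:n),
                                               seq = cds))$kept
  op <- tibble::tibble(gene_id = kept$gene_id, operon_id = kept$gene_id,
                       position = 1L, utr5 = utr[seq_len(nrow(kept))])
  assemble_gene_records(kept, op)
}

sense_codons_for_tests <- function() {
  nt <- c("T", "C", "A", "G")
  codons <- as.vector(outer(as.vector(outer(nt, nt, paste0)), nt, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

# Write a character vector to a temp file and return the path.
tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent brute-force Spearman oracle: explicit counting ranks and the
# textbook Pearson-on-ranks formula (no calls into the package or cor()).
spearman_bruteforce <- function(x, y) {
  rank_count <- function(v) {
    vapply(seq_along(v), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }, numeric(1))
  }
  rx <- rank_count(x); ry <- rank_count(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Independent instability-index oracle: per-dipeptide lookup and sum.
instability_oracle <- function(protein) {
  diwv <- diwv_table()
  aa <- strsplit(protein, "")[[1]]
  total <- 0
  for (i in seq_len(length(aa) - 1)) {
    total <- total + diwv[aa[i], aa[i + 1]]
  }
  10 * total / length(aa)
}

# A pre-encoded feature table with known planted structure for the search.
make_search_fixture <- function(n = 260, seed = 1, planted = "CAI") {
  set.seed(seed)
  blocks <- list(Type = "Type_num", uAUG = "uAUG_x", Start = "Start_x",
                 Stop = "Stop_x", CAI = "CAI", tAI = "tAI",
                 MFE_p1_p30 = "MFE_p1_p30", Length = "Length",
                 Nend = "Nend_x", Instability = "Instability")
  tbl <- tibble::tibble(gene_id = sprintf("g%04d", 1:n))
  for (cc in unlist(blocks)) tbl[[cc]] <- rnorm(n)
  tbl$new_tr <- rnorm(n)
  signal <- 0.4 * tbl$new_tr
  for (f in planted) signal <- signal + 1.0 * tbl[[blocks[[f]]]]
  tbl$pa <- 10^(signal + rnorm(n, 0, 0.1))
  tbl$mrna <- 1
  tbl$pa_per_mrna <- tbl$pa
  attr(tbl, "feature_blocks") <- blocks
  tbl
}

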