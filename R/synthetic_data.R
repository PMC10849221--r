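#' Configuration for the synthetic operon/expression generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' operons of one or more genes, A/G-rich Shine-Dalgarno motifs about six
#' nucleotides upstream of the start codon, an A-rich start context,
#' codon-usage bias, and expression with a planted monotone dependence on
#' named features plus log-normal noise.
#'
#' @param n_operons number of operons.
#' @param genes_per_operon mean of the (shifted) geometric operon size.
#' @param sd_strength probability that a UTR carries the consensus AGGAGG
#'   at spacing 5-7 nt.
#' @param codon_bias exponential tilt toward high-adaptiveness codons in
#'   the CDS body (0 = uniform).
#' @param effect_sizes named coefficients of the planted monotone effects
#'   on standardized feature scores; recognised names:
#'   `initiation_rate`, `elongation_rate`, `type`, `start`, `stop`,
#'   `length`, `cai`, `tai`, `instability`.
#' @param noise_sd Gaussian noise sd on log10 protein abundance.
#' @param mrna_rho correlation between log10 mRNA and log10 PA.
#' @param replicate_noise_sd log10-scale replicate noise.
#' @param seed integer seed.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_operons = 120, genes_per_operon = 2,
                         sd_strength = 0.7, codon_bias = 2,
                         effect_sizes = c(initiation_rate = 1.5,
                                          elongation_rate = 1.5,
                                          type = 0.3, start = 0.3,
                                          stop = 0.3, length = 0.3),
                         noise_sd = 0.15, mrna_rho = 0.6,
                         replicate_noise_sd = 0.1, seed = 1) {
  stopifnot(n_operons >= 1, sd_strength >= 0, sd_strength <= 1,
            codon_bias >= 0, noise_sd >= 0,
            mrna_rho >= -1, mrna_rho <= 1)
  structure(list(n_operons = n_operons, genes_per_operon = genes_per_operon,
                 sd_strength = sd_strength, codon_bias = codon_bias,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 mrna_rho = mrna_rho, replicate_noise_sd = replicate_noise_sd,
                 seed = seed), class = "synth_config")
}

#' Generate synthetic gene records and operon annotation
#'
#' Every generated CDS has a valid start codon (ATG 90%, GTG 7%, TTG 3%),
#' a terminal stop (TAA 70%, TGA 20%, TAG 10%), no internal stop, length
#' 60-900 nt; every UTR is 20-40 nt of A-rich background, with the SD
#' consensus planted at spacing 5-7 with probability `sd_strength`. All
#' records pass [filter_protein_coding()] by construction.
#'
#' @param config a [synth_config()].
#' @return List with `records` (gene-record tibble) and `operon_table`.
#' @export
generate_genes <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  sizes <- 1 + stats::rgeom(config$n_operons,
                            prob = 1 / max(1, config$genes_per_operon))
  n_genes <- sum(sizes)
  operon_id <- rep(sprintf("op%04d", seq_along(sizes)), sizes)
  position <- unlist(lapply(sizes, seq_len))
  gene_id <- sprintf("g%05d", seq_len(n_genes))

  # codon sampling distribution tilted toward high-tAI codons
  w <- tai_weights()
  body <- sense_codons()
  probs <- exp(config$codon_bias * w[body])
  probs <- probs / sum(probs)

  utr_bg <- c(A = 0.40, C = 0.15, G = 0.25, T = 0.20)  # A-rich start context
  nts <- names(utr_bg)

  utr5 <- character(n_genes)
  cds <- character(n_genes)
  for (i in seq_len(n_genes)) {
    ulen <- sample(20:40, 1)
    u <- sample(nts, ulen, replace = TRUE, prob = utr_bg)
    if (runif(1) < config$sd_strength) {
      spacing <- sample(5:7, 1)
      end <- ulen - spacing          # motif occupies end-5 .. end
      u[(end - 5):end] <- strsplit("AGGAGG", "")[[1]]
    }
    utr5[i] <- paste(u, collapse = "")
    n_codons <- sample(20:300, 1)    # 60-900 nt total
    start <- sample(c("ATG", "GTG", "TTG"), 1, prob = c(0.90, 0.07, 0.03))
    stop_cd <- sample(c("TAA", "TGA", "TAG"), 1, prob = c(0.70, 0.20, 0.10))
    inner <- sample(body, n_codons - 2, replace = TRUE, prob = probs)
    cds[i] <- paste(c(start, inner, stop_cd), collapse = "")
  }

  operon_table <- tibble::tibble(gene_id = gene_id, operon_id = operon_id,
                                 position = as.integer(position), utr5 = utr5)
  kept <- filter_protein_coding(tibble::tibble(gene_id = gene_id, seq = cds))$kept
  stopifnot(nrow(kept) == n_genes)
  records <- assemble_gene_records(kept, operon_table)
  list(records = records, operon_table = operon_table)
}

# Monotone numeric scores of the features a planted effect can act on.
feature_scores <- function(records, rates, features) {
  start_score <- c(ATG = 1, GTG = 0.5, TTG = 0.3, CTG = 0.2)
  stop_score <- c(TAA = 1, TGA = 0.5, TAG = 0.2)
  tibble::tibble(
    gene_id = records$gene_id,
    initiation_rate = log10(rates$InitRate),
    elongation_rate = rates$ElongRate,
    type = as.numeric(records$is_first_gene),
    start = unname(start_score[features$Start]),
    stop = unname(stop_score[features$Stop]),
    length = log10(features$Length),
    cai = features$CAI,
    tai = features$tAI,
    instability = -features$Instability)
}

#' Generate synthetic expression tables for a gene set
#'
#' In the default `"feature"` mode, `log10 PA` is a linear combination of
#' standardized planted feature scores plus Gaussian noise; in
#' `"mechanistic"` mode it follows the log of the TASEP translation rate
#' instead. mRNA is log-normal with correlation `mrna_rho` to log10 PA;
#' the mRNA table has two conditions with three replicates each.
#'
#' @param records gene-record tibble from [generate_genes()].
#' @param config a [synth_config()].
#' @param mode `"feature"` or `"mechanistic"`.
#' @param t_factor measurement-window multiplier for the mechanistic mode's
#'   TASEP runs.
#' @return List with `pa_table` (gene_id, pa), `mrna_table` (6 replicate
#'   columns), `grouping` (column -> condition sidecar), `rates`, and
#'   `truth` (the planted standardized scores and noiseless signal).
#' @export
generate_expression <- function(records, config, mode = c("feature", "mechanistic"),
                                t_factor = 1) {
  mode <- match.arg(mode)
  rates <- compute_rate_profiles(records, simulate = (mode == "mechanistic"),
                                 t_factor = t_factor, seed = config$seed)
  features <- compute_features(records)
  ok <- !is.na(rates$InitRate)
  records <- records[ok, ]; rates <- rates[ok, ]; features <- features[ok, ]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1)

  scores <- feature_scores(records, rates, features)
  n <- nrow(scores)
  if (mode == "feature") {
    signal <- rep(0, n)
    for (f in names(config$effect_sizes)) {
      if (!f %in% names(scores)) stop("unknown effect feature: ", f)
      v <- scores[[f]]
      z <- if (sd(v) > 0) as.numeric(scale(v)) else rep(0, n)
      signal <- signal + config$effect_sizes[[f]] * z
    }
  } else {
    tr <- rates$TransimTR
    signal <- 1.5 * as.numeric(scale(log10(tr + 1e-6)))
  }
  log_pa <- 2.5 + signal + rnorm(n, 0, config$noise_sd)
  pa <- 10^log_pa

  z_pa <- as.numeric(scale(log_pa))
  z_m <- config$mrna_rho * z_pa + sqrt(1 - config$mrna_rho^2) * rnorm(n)
  log_mrna <- 1.5 + 0.4 * z_m
  cond_means <- cbind(aerobic = 10^(log_mrna + rnorm(n, 0, 0.05)),
                      anaerobic = 10^(log_mrna + rnorm(n, 0, 0.05)))
  mrna_table <- tibble::tibble(gene_id = scores$gene_id)
  grouping <- list()
  for (cond in colnames(cond_means)) {
    for (r in 1:3) {
      col <- paste0(cond, "_r", r)
      mrna_table[[col]] <- cond_means[, cond] *
        10^rnorm(n, 0, config$replicate_noise_sd)
      grouping[[length(grouping) + 1]] <- tibble::tibble(column = col, condition = cond)
    }
  }
  list(pa_table = tibble::tibble(gene_id = scores$gene_id, pa = pa),
       mrna_table = mrna_table,
       grouping = dplyr::bind_rows(grouping),
       rates = rates,
       truth = dplyr::mutate(scores, signal = signal, log10_pa = log_pa))
}

#' Write a synthetic dataset in the pipeline's file dialects
#'
#' Emits `cds.fasta`, `operons.tsv`, `pa.tsv`, `mrna.tsv` and
#' `mrna_groups.tsv` — exactly the formats [read_fasta()],
#' [read_operon_table()] and [read_expression_table()] consume.
#'
#' @param genes output of [generate_genes()].
#' @param expr output of [generate_expression()].
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_synth_files <- function(genes, expr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "cds.fasta")
  writeLines(paste0(">", genes$records$gene_id, "\n",
                    genes$records$cds), fa)
  readr::write_tsv(genes$operon_table, file.path(dir, "operons.tsv"))
  readr::write_tsv(expr$pa_table, file.path(dir, "pa.tsv"))
  readr::write_tsv(expr$mrna_table, file.path(dir, "mrna.tsv"))
  readr::write_tsv(expr$grouping, file.path(dir, "mrna_groups.tsv"))
  invisible(dir)
}
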