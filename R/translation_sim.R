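#' Parameters of the initiation-rate energetics model
#'
#' The initiation rate is `alpha = A_scale * exp(-dG_total / RT)` with
#' `dG_total = dG_duplex + dG_spacing + dG_unfold`:
#' * `dG_duplex` — best hybridization of the 16S rRNA anti-SD tail
#'   (3'-UCCUCC-5', i.e. mRNA consensus AGGAGG) against any hexamer in the
#'   `-20..-5` upstream region; per-pair pseudo-energies `G:C` -1.5,
#'   `A:U` -1.0, `G:U` -0.5 kcal/mol.
#' * `dG_spacing` — quadratic penalty `spacing_penalty * (spacing -
#'   spacing_opt)^2` for the aligned spacer between the SD hexamer and the
#'   start codon (optimum 5 nt).
#' * `dG_unfold` — cost of opening mRNA structure, `unfold_weight * (-MFE)`
#'   of the `-35..+35` window (default weight 0.1).
#' `A_scale` is calibrated so a perfect SD at optimal spacing in an
#' unstructured UTR gives `alpha = 1` per second. `RT = 0.6156` kcal/mol
#' (37 degrees C).
#'
#' @param pair_energies named per-pair pseudo-energies (kcal/mol).
#' @param sd_search upstream region searched for the SD hexamer.
#' @param spacing_opt,spacing_penalty spacer optimum (nt) and quadratic
#'   penalty weight (kcal/mol/nt^2).
#' @param unfold_window,unfold_weight structure window and its weight.
#' @param RT thermal energy in kcal/mol.
#' @return A parameter list of class `init_params`.
#' @export
init_energy_params <- function(pair_energies = c(GC = -1.5, AU = -1.0, GU = -0.5),
                               sd_search = c(-20, -5),
                               spacing_opt = 5, spacing_penalty = 0.25,
                               unfold_window = c(-35, 35), unfold_weight = 0.1,
                               RT = 0.6156) {
  sd_consensus <- "AGGAGG"  # mRNA-side image of the anti-SD tail 3'-UCCUCC-5'
  dg_perfect <- sum(ifelse(strsplit(sd_consensus, "")[[1]] == "G",
                           pair_energies[["GC"]], pair_energies[["AU"]]))
  structure(list(pair_energies = pair_energies, sd_consensus = sd_consensus,
                 sd_search = sd_search, spacing_opt = spacing_opt,
                 spacing_penalty = spacing_penalty,
                 unfold_window = unfold_window, unfold_weight = unfold_weight,
                 RT = RT, a_scale = exp(dg_perfect / RT)),
            class = "init_params")
}

#' Translation initiation rate from 5'-UTR energetics
#'
#' @param utr5,cds gene sequences. The UTR must cover the anti-SD search
#'   window (20 nt); shorter UTRs return `NA` with reason `RBS_TOO_SHORT`
#'   (such genes are discarded upstream of modelling).
#' @param params energetics parameters (see [init_energy_params()]).
#' @param fold_backend folding backend for the unfold term.
#' @return Initiation rate alpha in 1/s, or `NA` if the RBS is too short.
#' @export
initiation_rate <- function(utr5, cds, params = init_energy_params(),
                            fold_backend = "nussinov") {
  if (nchar(utr5) < -params$sd_search[1]) {
    return(structure(NA_real_, reason = "RBS_TOO_SHORT"))
  }
  dg_bind <- best_sd_binding(utr5, params)
  # unfold cost: structure of the window around the start codon, clipped to
  # the available sequence
  full <- paste0(utr5, cds)
  u <- nchar(utr5)
  i <- max(1, u + params$unfold_window[1] + 1)
  j <- min(nchar(full), u + params$unfold_window[2])
  mfe <- fold_mfe(substr(full, i, j), fold_backend)
  dg_unfold <- params$unfold_weight * (-mfe)
  dg_total <- dg_bind + dg_unfold
  params$a_scale * exp(-dg_total / params$RT)
}

# Best (most negative) duplex + spacing score over all hexamer placements
# with the hexamer inside the search region; 0 if no placement binds.
best_sd_binding <- function(utr5, params) {
  cons <- strsplit(params$sd_consensus, "")[[1]]
  e <- params$pair_energies
  u <- nchar(utr5)
  best <- 0
  # hexamer start positions (paper coordinates) keeping the hexamer within
  # the search region
  p_lo <- params$sd_search[1]
  p_hi <- params$sd_search[2] - 5
  for (p in seq(p_lo, p_hi)) {
    idx <- u + p + 1
    hex <- strsplit(substr(utr5, idx, idx + 5), "")[[1]]
    if (length(hex) < 6) next
    dg <- 0
    for (k in 1:6) {
      if (cons[k] == "G") {
        if (hex[k] == "G") dg <- dg + e[["GC"]]
      } else {  # consensus A pairs anti-SD U
        if (hex[k] == "A") dg <- dg + e[["AU"]]
        else if (hex[k] == "G") dg <- dg + e[["GU"]]
      }
    }
    spacing <- -(p + 5) - 1
    score <- dg + params$spacing_penalty * (spacing - params$spacing_opt)^2
    if (score < best) best <- score
  }
  best
}

#' Per-codon elongation (hop) rates from a dwell-time table
#'
#' @param cds coding sequence.
#' @param dwell_table named codon -> dwell time (s) covering all 61 sense
#'   codons (default [default_dwell_times()]).
#' @return List with `hop_rates` (1/dwell per sense codon of the gene, in
#'   order) and `gene_elongation_rate` (`L / sum(dwell)`, codons/s — the
#'   harmonic-mean translocation speed).
#' @export
elongation_rates <- function(cds, dwell_table = default_dwell_times()) {
  codons <- split_codons(cds)
  codons <- codons[-length(codons)]  # drop terminal stop
  missing <- setdiff(unique(codons), names(dwell_table))
  if (length(missing)) stop("dwell table missing codons: ", paste(missing, collapse = ", "))
  dwell <- unname(dwell_table[codons])
  if (any(dwell <= 0)) stop("non-positive dwell time")
  list(hop_rates = 1 / dwell,
       gene_elongation_rate = length(dwell) / sum(dwell))
}

#' Construct a per-gene rate profile
#'
#' @param gene_id identifier.
#' @param alpha initiation rate (1/s).
#' @param hop_rates per-codon hop rates (1/s).
#' @param beta termination rate (1/s); default 10 (non-limiting).
#' @param footprint ribosome footprint in codons; default 10.
#' @return A `rate_profile` object.
#' @export
rate_profile <- function(gene_id, alpha, hop_rates, beta = 10, footprint = 10) {
  stopifnot(alpha >= 0, all(hop_rates > 0), beta > 0, footprint >= 1)
  structure(list(gene_id = gene_id, alpha = alpha, hop_rates = hop_rates,
                 beta = beta, footprint = footprint),
            class = "rate_profile")
}

#' Stochastic TASEP simulation of ribosome traffic on one mRNA
#'
#' Continuous-time kinetic Monte Carlo of an open one-dimensional lattice
#' of codon sites with extended ribosomes (footprint `l` codons):
#' initiation at rate alpha when the first `l` sites are vacant, per-codon
#' hops at the A-site codon's rate under hard-core exclusion, termination
#' at rate beta once the A-site is the last codon. Identical seeds give
#' identical trajectories.
#'
#' @param profile a [rate_profile()].
#' @param t_burn,t_measure burn-in and measurement windows (model seconds);
#'   defaults `10 * L / mean(k)` and `50 * L / mean(k)`.
#' @param seed integer RNG seed.
#' @param n_batch number of sub-windows used for the flux standard error.
#' @return A `tasep_sim` object: `translation_rate` (terminations per
#'   second of measurement), `density` (per-site time-averaged occupancy),
#'   `terminations`, `initiations`, `collisions` (hops that land a ribosome
#'   in contact with the one ahead), `flux_se`, ribosome counts at the
#'   window boundaries and the window length.
#' @export
tasep_simulate <- function(profile, t_burn = NULL, t_measure = NULL, seed = 1,
                           n_batch = 20) {
  L <- length(profile$hop_rates)
  tau <- L / mean(profile$hop_rates)
  if (is.null(t_burn)) t_burn <- 10 * tau
  if (is.null(t_measure)) t_measure <- 50 * tau
  stopifnot(t_burn > 0, t_measure > 0)
  res <- tasep_kmc_cpp(profile$hop_rates, profile$alpha, profile$beta,
                       as.integer(profile$footprint), t_burn, t_measure,
                       as.integer(n_batch), as.integer(seed))
  res$gene_id <- profile$gene_id
  res$t_measure <- t_measure
  res$elapsed_model_time <- t_burn + t_measure
  class(res) <- "tasep_sim"
  # split-half convergence diagnostic
  nb <- length(res$batch_flux)
  h1 <- res$batch_flux[seq_len(nb %/% 2)]
  h2 <- res$batch_flux[(nb %/% 2 + 1):nb]
  se <- sqrt(stats::var(h1) / length(h1) + stats::var(h2) / length(h2))
  if (is.finite(se) && se > 0 && abs(mean(h1) - mean(h2)) > 3 * se) {
    warning("flux may not have converged: split-half estimates differ by > 3 SE")
  }
  res
}

#' Steady-state translation rate of a simulation
#' @param result a `tasep_sim` object.
#' @return Protein production flux in proteins/s.
#' @export
transim_translation_rate <- function(result) {
  if (result$t_measure <= 0) stop("zero measurement window")
  result$terminations / result$t_measure
}

#' @export
print.tasep_sim <- function(x, ...) {
  cat(sprintf("TASEP simulation%s: flux %.4g /s (SE %.2g), %d terminations, %d collisions\n",
              if (is.null(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              x$translation_rate, x$flux_se, as.integer(x$terminations),
              as.integer(x$collisions)))
  invisible(x)
}

#' Exact stationary state of a small TASEP by master-equation solve
#'
#' Enumerates every admissible ribosome configuration, builds the full
#' continuous-time generator, and solves for the stationary distribution.
#' Intended as a validation oracle for [tasep_simulate()] on small systems.
#'
#' @param hop_rates per-codon hop rates (length L <= 12 recommended).
#' @param alpha,beta boundary rates.
#' @param footprint ribosome size (1 or 2).
#' @param max_states guard on the configuration-space size.
#' @return List with `current` (exact stationary flux), `density` (exact
#'   per-site occupancies) and `n_states`.
#' @export
exact_steady_state <- function(hop_rates, alpha, beta, footprint = 1,
                               max_states = 20000) {
  L <- length(hop_rates)
  l <- footprint
  stopifnot(l >= 1)
  # states: decreasing leading-edge positions in [l, L + l - 1], gaps >= l
  states <- list()
  gen <- function(prefix, max_next) {
    states[[length(states) + 1]] <<- prefix
    if (max_next < l) return()
    for (pos in seq(max_next, l)) gen(c(prefix, pos), pos - l)
  }
  gen(integer(0), L + l - 1)
  n <- length(states)
  if (n > max_states) stop("state space too large: ", n, " states")
  key <- vapply(states, function(st) paste0("s", paste(st, collapse = ",")), character(1))
  idx <- setNames(seq_len(n), key)

  Q <- matrix(0, n, n)
  for (s in seq_len(n)) {
    st <- states[[s]]
    m <- length(st)
    # initiation
    if (m == 0 || st[m] >= 2 * l) {
      to <- idx[[paste0("s", paste(c(st, l), collapse = ","))]]
      Q[s, to] <- Q[s, to] + alpha
    }
    for (k in seq_len(m)) {
      i <- st[k]
      a <- max(1, i - l + 1)
      if (a == L) {  # termination (front ribosome)
        to <- idx[[paste0("s", paste(st[-1], collapse = ","))]]
        Q[s, to] <- Q[s, to] + beta
      } else if (k == 1 || st[k - 1] - i > l) {
        nxt <- st
        nxt[k] <- i + 1
        to <- idx[[paste0("s", paste(nxt, collapse = ","))]]
        Q[s, to] <- Q[s, to] + hop_rates[a]
      }
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi <- solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0

  term_rate <- vapply(states, function(st) {
    if (length(st) > 0 && max(1, st[1] - l + 1) == L) beta else 0
  }, numeric(1))
  current <- sum(pi * term_rate)
  density <- numeric(L)
  for (s in seq_len(n)) {
    for (i in states[[s]]) {
      from <- max(1, i - l + 1)
      to <- min(i, L)
      density[from:to] <- density[from:to] + pi[s]
    }
  }
  list(current = current, density = density, n_states = n)
}

#' Compute rate profiles (and optionally TASEP rates) for a gene set
#'
#' @param records gene-record tibble.
#' @param params initiation energetics parameters.
#' @param dwell_table codon dwell times.
#' @param beta,footprint TASEP boundary/geometry parameters.
#' @param simulate if TRUE, run the TASEP per gene and add `TransimTR`,
#'   `mean_density` and `collisions` columns.
#' @param t_factor multiplies the default measurement window when
#'   simulating.
#' @param seed base seed; per-gene simulation seeds are derived from it.
#' @param fold_backend folding backend for the initiation unfold term.
#' @return A tibble `gene_id`, `InitRate`, `ElongRate` (plus simulation
#'   columns); genes whose RBS is too short get `NA` rates and a `discard
#'   reason` column entry `RBS_TOO_SHORT`.
#' @export
compute_rate_profiles <- function(records, params = init_energy_params(),
                                  dwell_table = default_dwell_times(),
                                  beta = 10, footprint = 10,
                                  simulate = FALSE, t_factor = 1, seed = 1,
                                  fold_backend = "nussinov") {
  n <- nrow(records)
  alpha <- numeric(n)
  elong <- numeric(n)
  reason <- rep(NA_character_, n)
  hop_list <- vector("list", n)
  for (i in seq_len(n)) {
    a <- initiation_rate(records$utr5[i], records$cds[i], params, fold_backend)
    if (is.na(a)) {
      alpha[i] <- NA_real_
      elong[i] <- NA_real_
      reason[i] <- attr(a, "reason")
      next
    }
    alpha[i] <- a
    er <- elongation_rates(records$cds[i], dwell_table)
    elong[i] <- er$gene_elongation_rate
    hop_list[[i]] <- er$hop_rates
  }
  out <- tibble::tibble(gene_id = records$gene_id, InitRate = alpha,
                        ElongRate = elong, discard_reason = reason)
  if (simulate) {
    tr <- rep(NA_real_, n); md <- rep(NA_real_, n); cl <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (is.na(alpha[i])) next
      prof <- rate_profile(records$gene_id[i], alpha[i], hop_list[[i]],
                           beta = beta, footprint = footprint)
      L <- length(prof$hop_rates)
      tau <- L / mean(prof$hop_rates)
      sim <- suppressWarnings(tasep_simulate(
        prof, t_burn = 10 * tau, t_measure = 50 * tau * t_factor,
        seed = (seed + i) %% .Machine$integer.max))
      tr[i] <- sim$translation_rate
      md[i] <- mean(sim$density)
      cl[i] <- sim$collisions
    }
    out$TransimTR <- tr
    out$mean_density <- md
    out$collisions <- cl
  }
  out
}

#' Read / write the translation-simulator sequence dialect
#'
#' Tab-separated with header `name`, `sequence` (UTR+CDS) and `start_pos`
#' (1-based position of the first start-codon nucleotide in `sequence`).
#'
#' @param path file path.
#' @return `read_transim_input()` returns a tibble `gene_id`, `utr5`, `cds`.
#' @export
read_transim_input <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), sequence = readr::col_character(),
    start_pos = readr::col_integer()))
  seqs <- normalize_nt(tbl$sequence)
  tibble::tibble(
    gene_id = tbl$name,
    utr5 = substr(seqs, 1, tbl$start_pos - 1),
    cds = substr(seqs, tbl$start_pos, nchar(seqs)))
}

#' @rdname read_transim_input
#' @param records gene-record tibble to write.
#' @export
write_transim_input <- function(records, path) {
  readr::write_tsv(tibble::tibble(
    name = records$gene_id,
    sequence = paste0(records$utr5, records$cds),
    start_pos = nchar(records$utr5) + 1L), path)
}
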