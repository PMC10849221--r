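test_that("Spearman matches the brute-force rank oracle on all n=6 permutations", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1)), -1)
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))

  y <- c(2.3, -1.1, 0.4, 5.0, 3.3, -2.2)
  perms <- rbind(1:6)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  expect_equal(nrow(perms), 720)
  for (i in seq_len(nrow(perms))) {
    x <- as.numeric(perms[i, ])
    expect_equal(spearman_cor(x, y), spearman_bruteforce(x, y),
                 tolerance = 1e-12)
  }
  # ties handled by average ranks
  expect_equal(spearman_cor(c(1, 1, 2), c(5, 5, 9)),
               spearman_bruteforce(c(1, 1, 2), c(5, 5, 9)), tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    r <- spearman_cor(x, y)
    expect_equal(spearman_cor(exp(x), y), r, tolerance = 1e-12)
    expect_equal(spearman_cor(x, y^3 + 5 * y), r, tolerance = 1e-12)
  }
})

test_that("pooled t-test matches closed-form arithmetic", {
  same <- ttest_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  got <- ttest_two_tailed(a, b)
  # closed form: pooled variance then t = (ma - mb) / sqrt(sp2 (1/n1 + 1/n2))
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_exp <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(got$t, t_exp, tolerance = 1e-12)
  flipped <- ttest_two_tailed(b, a)
  expect_equal(flipped$t, -got$t)
  expect_equal(flipped$p, got$p)
  expect_error(ttest_two_tailed(c(1, 1), c(1, 1)), "zero pooled variance")
  w <- ttest_two_tailed(a, c(2, 3, 4, 50), welch = TRUE)
  expect_true(is.finite(w$t) && w$p >= 0 && w$p <= 1)
})

test_that("train/test split is exact, disjoint and deterministic", {
  ids <- sprintf("g%04d", 1:1660)
  sp <- train_test_split(ids, 0.8, seed = 3)
  expect_length(sp$train, 1328)
  expect_length(sp$test, 332)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- train_test_split(ids, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, train_test_split(ids, 0.8, seed = 4)))
  small <- train_test_split(sprintf("g%d", 1:10), 0.8, seed = 1)
  expect_length(small$train, 8)
  expect_error(train_test_split("g1", 0.8, 1), "at least 2")
})

test_that("New_TR recovers a noiseless monotone signal and rejects pure noise", {
  set.seed(100)
  n <- 400
  rates <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                          InitRate = 10^runif(n, -6, 0),
                          ElongRate = runif(n, 14, 20))
  # response is an exact monotone function of the elongation rate
  resp <- tibble::tibble(gene_id = rates$gene_id,
                         pa = exp(0.5 * rates$ElongRate),
                         mrna = 1, pa_per_mrna = exp(0.5 * rates$ElongRate))
  fit <- fit_new_tr(rates, resp, model_spec("SVR_RBF", seed = 2, target = "PA"))
  expect_gte(fit$spearman_test, 0.99)
  expect_equal(nrow(tidy(fit)), n)          # predictions for every gene
  expect_equal(sum(fit$split_sizes), n)

  # pure-noise response: all six families stay inside the null band
  set.seed(101)
  resp_null <- tibble::tibble(gene_id = rates$gene_id, pa = rlnorm(n),
                              mrna = 1, pa_per_mrna = rlnorm(n))
  for (alg in c("LINEAR", "RIDGE", "LASSO", "ELASTIC_NET",
                "RANDOM_FOREST", "SVR_RBF")) {
    f <- suppressWarnings(
      fit_new_tr(rates, resp_null, model_spec(alg, seed = 3, target = "PA")))
    # a fully shrunk (constant) predictor carries no spurious signal either
    expect_true(is.na(f$spearman_test) || abs(f$spearman_test) < 0.2)
  }
  # degenerate constant input column errors
  rates_bad <- dplyr::mutate(rates, ElongRate = 17)
  expect_error(fit_new_tr(rates_bad, resp, model_spec("LINEAR", seed = 1)),
               "degenerate")
})

test_that("refitting with the same seed reproduces scores exactly", {
  set.seed(200)
  n <- 150
  rates <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                          InitRate = 10^runif(n, -6, 0),
                          ElongRate = runif(n, 14, 20))
  resp <- tibble::tibble(gene_id = rates$gene_id,
                         pa = 10^(0.3 * scale(log10(rates$InitRate))[, 1] + rnorm(n, 0, 0.2)),
                         mrna = 1)
  resp$pa_per_mrna <- resp$pa
  for (alg in c("LINEAR", "RIDGE", "LASSO", "ELASTIC_NET",
                "RANDOM_FOREST", "SVR_RBF")) {
    f1 <- fit_new_tr(rates, resp, model_spec(alg, seed = 9))
    f2 <- fit_new_tr(rates, resp, model_spec(alg, seed = 9))
    expect_equal(f1$spearman_test, f2$spearman_test, tolerance = 1e-12)
    expect_equal(tidy(f1)$new_tr, tidy(f2)$new_tr, tolerance = 1e-12)
  }
})

test_that("learned New_TR outperforms the raw simulated rate on planted data", {
  wins <- 0
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(n_operons = 50, sd_strength = 1, noise_sd = 0.1,
                        seed = 300 + s)
    g <- generate_genes(cfg)
    e <- generate_expression(g$records, cfg)
    resp <- build_response(
      e$pa_table,
      quantile_normalize(aggregate_replicates(e$mrna_table, e$grouping)))
    sims <- compute_rate_profiles(g$records, simulate = TRUE, t_factor = 2,
                                  seed = 300 + s)
    raw <- dplyr::inner_join(sims, resp, by = "gene_id")
    raw_rho <- suppressWarnings(spearman_cor(raw$TransimTR, raw$pa))
    fit <- fit_new_tr(e$rates, resp, model_spec("SVR_RBF", seed = s, target = "PA"))
    if (is.na(raw_rho) || fit$spearman_total >= raw_rho) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.9 * n_seeds))
})
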