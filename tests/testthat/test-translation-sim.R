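test_that("initiation-rate energetics are calibrated and ordered", {
  params <- init_energy_params()
  # perfect SD at optimal spacing 5 in an unstructured A background -> alpha = 1
  utr <- paste0(paste(rep("A", 9), collapse = ""), "AGGAGG", "AAAAA")
  cds <- paste(rep("A", 45), collapse = "")
  expect_equal(initiation_rate(utr, cds, params), 1, tolerance = 1e-9)
  # no binding, no structure -> alpha = A_scale exactly
  utr_c <- paste(rep("C", 20), collapse = "")
  cds_c <- paste(rep("C", 45), collapse = "")
  expect_equal(as.numeric(initiation_rate(utr_c, cds_c, params)),
               params$a_scale, tolerance = 1e-12)
  # strong SD / weak-gene contrast spans >= 3 orders of magnitude
  hairpin <- paste0(paste(rep("C", 8), collapse = ""),
                    "GGGGGGGGAAAACCCCCCCC")  # stem right before the start
  a_weak <- initiation_rate(hairpin, cds_c, params)
  expect_gt(1 / a_weak, 1e3)
  # RBS too short -> discarded with reason
  a_short <- initiation_rate("AAAAAAAAAA", cds, params)
  expect_true(is.na(a_short))
  expect_equal(attr(a_short, "reason"), "RBS_TOO_SHORT")
})

test_that("elongation rates are reciprocal dwell times", {
  cds <- paste(c("ATG", rep("AAA", 99)[1:99], "TAA"), collapse = "")
  dwell <- setNames(rep(0.1, 2), c("ATG", "AAA"))
  er <- elongation_rates(cds, dwell)
  expect_equal(length(er$hop_rates), 100)
  expect_equal(er$gene_elongation_rate, 10)
  expect_true(all(er$hop_rates == 10))
  # halving every dwell doubles the gene rate
  er2 <- elongation_rates(cds, dwell / 2)
  expect_equal(er2$gene_elongation_rate, 20)
  # mixed dwell harmonic aggregation: 2 codons at 0.1 and 0.3 s
  er3 <- elongation_rates("ATGAAATAA", c(ATG = 0.1, AAA = 0.3))
  expect_equal(er3$gene_elongation_rate, 2 / 0.4)
  expect_error(elongation_rates("ATGAAATAA", c(ATG = 0.1, AAA = -1)), "non-positive")
  expect_error(elongation_rates("ATGAAATAA", c(ATG = 0.1)), "missing codons")
})

test_that("exact steady state solves small systems analytically", {
  # L = 1: two states, current alpha*beta/(alpha+beta)
  expect_equal(exact_steady_state(1, 1, 1, 1)$current, 0.5, tolerance = 1e-12)
  expect_equal(exact_steady_state(1, 2, 1, 1)$current, 2 / 3, tolerance = 1e-12)
  # L = 2, l = 1, all rates 1: hand-solved 4-state chain gives 2/5
  expect_equal(exact_steady_state(rep(1, 2), 1, 1, 1)$current, 0.4,
               tolerance = 1e-12)
  # L = 2, l = 2: single-ribosome 3-state cycle, current 1/3
  expect_equal(exact_steady_state(rep(1, 2), 1, 1, 2)$current, 1 / 3,
               tolerance = 1e-12)
  # no injection
  expect_equal(exact_steady_state(rep(1, 4), 0, 1, 1)$current, 0)
  ex <- exact_steady_state(rep(1, 6), 1, 1, 1)
  expect_equal(ex$n_states, 64)
  expect_true(all(ex$density >= 0 & ex$density <= 1))
})

test_that("TASEP simulation agrees with the exact oracle and conserves particles", {
  prof <- rate_profile("g", 1, rep(1, 6), beta = 1, footprint = 1)
  sim <- tasep_simulate(prof, t_burn = 500, t_measure = 20000, seed = 42)
  ex <- exact_steady_state(rep(1, 6), 1, 1, 1)
  expect_lt(abs(sim$translation_rate - ex$current), 3 * sim$flux_se)
  expect_true(all(sim$density >= 0 & sim$density <= 1))
  expect_equal(max(abs(sim$density - ex$density)), 0, tolerance = 0.02)
  # particle conservation over the measurement window
  expect_equal(sim$ribosomes_initial + sim$initiations - sim$terminations,
               sim$ribosomes_final)
  # two estimators of the same current
  expect_equal(transim_translation_rate(sim), sim$translation_rate)

  # alpha = 0: nothing moves
  empty <- tasep_simulate(rate_profile("e", 0, rep(1, 10), beta = 1, footprint = 1),
                          t_burn = 10, t_measure = 100, seed = 1)
  expect_equal(empty$translation_rate, 0)
  expect_true(all(empty$density == 0))
})

test_that("TASEP is seed-deterministic and monotone in the initiation rate", {
  prof <- rate_profile("g", 0.5, rep(2, 40), beta = 5, footprint = 2)
  s1 <- tasep_simulate(prof, t_burn = 100, t_measure = 1000, seed = 7)
  s2 <- tasep_simulate(prof, t_burn = 100, t_measure = 1000, seed = 7)
  expect_identical(s1$density, s2$density)
  expect_identical(s1$terminations, s2$terminations)
  expect_identical(s1$collisions, s2$collisions)
  s3 <- tasep_simulate(prof, t_burn = 100, t_measure = 1000, seed = 8)
  expect_false(identical(s1$terminations, s3$terminations))

  # expected current never decreases with alpha (statistical, averaged seeds)
  flux_at <- function(a) {
    mean(vapply(1:5, function(s) {
      p <- rate_profile("m", a, rep(1, 50), beta = 10, footprint = 1)
      tasep_simulate(p, t_burn = 300, t_measure = 3000, seed = s)$translation_rate
    }, numeric(1)))
  }
  f <- vapply(c(0.05, 0.2, 0.8), flux_at, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("rate-profile computation discards short-RBS genes and simulates on demand", {
  rec <- make_records(utr_lens = c(10, 35, 35, 35, 35, 35), seed = 21)
  rates <- compute_rate_profiles(rec)
  expect_equal(rates$discard_reason[1], "RBS_TOO_SHORT")
  expect_true(is.na(rates$InitRate[1]))
  expect_true(all(!is.na(rates$InitRate[-1])))
  rs <- compute_rate_profiles(rec[2:3, ], simulate = TRUE, t_factor = 0.2, seed = 5)
  expect_true(all(c("TransimTR", "mean_density", "collisions") %in% names(rs)))
  expect_true(all(rs$TransimTR >= 0))
})

test_that("the simulator dialect round-trips", {
  rec <- make_records(seed = 2)
  p <- tempfile(fileext = ".tsv")
  write_transim_input(rec, p)
  back <- read_transim_input(p)
  expect_equal(back$utr5, rec$utr5)
  expect_equal(back$cds, rec$cds)
})
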