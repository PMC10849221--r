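test_that("uAUG classification handles frame, precedence and short UTRs", {
  expect_equal(classify_uaug("CCCCCCCCCCCC"), "NONE")
  expect_equal(classify_uaug("CCCCCCATGCCC"), "IN_FRAME")      # offset -6
  expect_equal(classify_uaug("CCCCCATGCCCC"), "OUT_OF_FRAME")  # offset -7
  # both frames present: in-frame wins
  expect_equal(classify_uaug("CATGCCATGCCC"), "IN_FRAME")  # -11 out, -6 in
  expect_equal(classify_uaug("CC"), "NONE")
  # exhaustive placement scan: ATG planted at each offset in a C background
  for (p in 3:12) {
    u <- rep("C", 12)
    u[(12 - p + 1):(12 - p + 3)] <- c("A", "T", "G")
    got <- classify_uaug(paste(u, collapse = ""))
    expect_equal(got, if (p %% 3 == 0) "IN_FRAME" else "OUT_OF_FRAME",
                 label = paste("offset", -p))
  }
  # property: IN_FRAME never without an in-frame ATG
  set.seed(5)
  for (i in 1:300) {
    u <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
    cls <- classify_uaug(u)
    offs <- which(vapply(3:12, function(p) {
      substr(u, 12 - p + 1, 12 - p + 3) == "ATG"
    }, logical(1))) + 2
    if (cls == "NONE") expect_length(offs, 0)
    if (cls == "IN_FRAME") expect_true(any(offs %% 3 == 0))
    if (cls == "OUT_OF_FRAME") {
      expect_true(length(offs) > 0 && all(offs %% 3 != 0))
    }
  }
})

test_that("start and stop codon typing", {
  expect_equal(start_codon_type("ATGAAATAA"), "ATG")
  expect_equal(stop_codon_type("ATGAAATAA"), "TAA")
  expect_equal(start_codon_type("GTGAAATGA"), "GTG")
  expect_equal(stop_codon_type("GTGAAATGA"), "TGA")
  expect_equal(stop_codon_type("TTGAAATAG"), "TAG")
  expect_error(stop_codon_type("ATGAAAAAA"), "not a stop")
})

test_that("CAI weights follow relative adaptiveness with pseudo-counts", {
  # Lys counts AAA:30, AAG:15 (plus an initiator and stop, excluded)
  ref <- paste(c("ATG", rep("AAA", 30), rep("AAG", 15), "TAA"), collapse = "")
  w <- suppressWarnings(build_cai_weights(ref))
  expect_equal(w[["AAA"]], 1)
  expect_equal(w[["AAG"]], 0.5)
  # unseen synonym gets 0.5 pseudo-count
  ref2 <- paste(c("ATG", rep("AAA", 30), "TAA"), collapse = "")
  w2 <- suppressWarnings(build_cai_weights(ref2))
  expect_equal(w2[["AAG"]], 0.5 / 30)
  # absent amino acid -> neutral weight with warning
  one_per_aa <- tapply(names(codon_table()), codon_table(), `[`, 1)
  body <- setdiff(unname(one_per_aa[rownames(diwv_table())]), "TGG")  # no Trp
  ref3 <- paste(c("ATG", body, "TAA"), collapse = "")
  expect_warning(w3 <- build_cai_weights(ref3), "amino acid W absent")
  expect_equal(w3[["TGG"]], 1)
  expect_equal(w2[["TGG"]], 1)
})

test_that("CAI is a geometric mean over body codons with its invariances", {
  w <- setNames(rep(1, length(sense_codons_for_tests())),
                sense_codons_for_tests())
  cds <- paste(c("ATG", "AAA", "GGG", "TAA"), collapse = "")
  expect_equal(compute_cai(cds, w), 1)
  w["AAA"] <- 0.5
  expect_equal(compute_cai(paste(c("ATG", "AAA", "GGG", "TAA"), collapse = ""), w),
               sqrt(0.5), tolerance = 1e-12)
  # permutation invariance and bounds
  set.seed(3)
  w[] <- runif(length(w), 0.05, 1)
  body <- sample(sense_codons_for_tests(), 20, replace = TRUE)
  c1 <- compute_cai(paste(c("ATG", body, "TAA"), collapse = ""), w)
  c2 <- compute_cai(paste(c("ATG", sample(body), "TAA"), collapse = ""), w)
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_gt(c1, 0); expect_lte(c1, 1)
  # replacing a codon by a higher-weight synonym never decreases CAI
  expect_gte(compute_cai("ATGAAAGGGTAA", setNames(rep(1, 61), names(w))),
             compute_cai("ATGAAAGGGTAA", w))
})

test_that("tAI reproduces hand-computed toy weights", {
  # no wobble: only Watson-Crick anticodons count
  s_off <- c("G:U" = 1, "I:C" = 1, "I:A" = 1, "U:G" = 1, "L:A" = 1)
  copies <- tibble::tibble(anticodon = c("AAA", "GAA"), copies = c(4, 2))
  w <- tai_weights(copies, s_off)      # W(TTT)=4, W(TTC)=2, rest 0 -> geomean fill
  expect_equal(w[["TTT"]], 1)
  expect_equal(w[["TTC"]], 0.5)
  tai <- compute_tai("ATGTTTTTCTAA", copies, s_off)
  expect_equal(tai, sqrt(0.5), tolerance = 1e-12)
  # degenerate limit: uniform copies over all WC anticodons, no wobble
  uni <- tibble::tibble(anticodon = unique(vapply(sense_codons_for_tests(),
    function(cd) paste(rev(strsplit(chartr("ACGT", "TGCA", cd), "")[[1]]), collapse = ""),
    character(1))), copies = 2)
  wu <- tai_weights(uni, s_off)
  expect_true(all(abs(wu - 1) < 1e-12))
  expect_equal(compute_tai("ATGTTTGGGTAA", uni, s_off), 1)
  # permutation invariance / bounds under the packaged defaults
  t1 <- compute_tai("ATGTTTGGGAAATAA")
  t2 <- compute_tai("ATGGGGAAATTTTAA")
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_gt(t1, 0); expect_lte(t1, 1)
})

test_that("windowed folding energy uses the base-pair maximization fallback", {
  polyA <- paste(rep("A", 30), collapse = "")
  expect_equal(folding_energy_window("", paste0(polyA, "AAA"), c(1, 30)), 0)
  # four nested G-C pairs
  expect_equal(fold_mfe("GGGGAAAACCCC"), -4)
  # hairpin-loop constraint: a pair needs >= 3 unpaired between
  expect_equal(fold_mfe("GAAC"), 0)
  expect_equal(fold_mfe("GAAAC"), -1)
  # window not fully covered -> missing
  short_utr <- paste(rep("A", 10), collapse = "")
  expect_true(is.na(folding_energy_window(short_utr, "ATGAAATAA", c(-30, -1))))
  expect_error(folding_energy_window("A", "ATG", c(10, 2)), "invalid window")
})

test_that("N-end rule classification with Met-excision policy", {
  expect_equal(n_end_half_life("MAKL"), "STABLE_GT_10H")    # A excised, A stable
  expect_equal(n_end_half_life("MPKL"), "EXCLUDED_PRO")     # P excised, excluded
  expect_equal(n_end_half_life("MRKL"), "STABLE_GT_10H")    # R retained Met
  expect_equal(n_end_half_life("MLKL", met_excision = "always"), "UNSTABLE_LT_2MIN")
  expect_equal(n_end_half_life("M"), "STABLE_GT_10H")       # short: residue 1
  expect_error(n_end_half_life("AKL"), "initiator M")
})

test_that("instability index matches the independent lookup-sum oracle", {
  diwv <- diwv_table()
  expect_equal(instability_index("MKK"), (10 / 3) * (diwv["M", "K"] + diwv["K", "K"]))
  # closed form: homopolymer with all-1 weights
  expect_equal(instability_index(paste(rep("K", 25), collapse = "")),
               10 * 24 / 25)
  set.seed(11)
  for (i in 1:50) {
    p <- paste(sample(rownames(diwv), sample(2:60, 1), replace = TRUE),
               collapse = "")
    expect_equal(instability_index(p), instability_oracle(p), tolerance = 1e-9)
  }
  expect_error(instability_index("MKX"), "unknown residue")
  expect_error(instability_index("M"), "at least 2")
})

test_that("nucleotide frequency matrix normalizes per covered position", {
  rec <- tibble::tibble(gene_id = c("a", "b"),
                        utr5 = c("AAAA", "GGGG"),
                        cds = rep("ATGAAATAA", 2),
                        protein = rep("MK", 2),
                        operon_id = c("a", "b"),
                        position_in_operon = c(1L, 1L),
                        is_first_gene = c(TRUE, TRUE))
  fm <- nucleotide_frequency_matrix(rec, c(-4, 3))
  expect_false(any(fm$position == 0))
  r1 <- fm[fm$position == -1, ]
  expect_equal(c(r1$A, r1$C, r1$G, r1$T), c(0.5, 0, 0.5, 0))
  rp1 <- fm[fm$position == 1, ]
  expect_equal(rp1$A, 1)   # both start with ATG
  sums <- rowSums(fm[, c("A", "C", "G", "T")])
  expect_true(all(abs(sums[fm$n_obs > 0] - 1) < 1e-12))
  # identical records give degenerate frequencies
  fm2 <- nucleotide_frequency_matrix(rec[c(1, 1), ], c(-2, 2))
  expect_true(all(apply(fm2[, c("A", "C", "G", "T")], 1, max) == 1))
})

test_that("feature-table assembly applies the missing-data rule and encoding", {
  # 2 of 10 genes (20%) have UTRs too short for the -30..-1 window
  rec <- make_records(utr_lens = c(25, 25, rep(35, 8)), seed = 9)
  feats <- compute_features(rec)
  expect_equal(sum(is.na(feats$MFE_m30_m1)), 2)
  rates <- tibble::tibble(gene_id = rec$gene_id,
                          InitRate = 10^seq(-6, -1, length.out = 10),
                          ElongRate = seq(15, 20, length.out = 10))
  resp <- tibble::tibble(gene_id = rec$gene_id, pa = 1:10, mrna = rep(1, 10),
                         pa_per_mrna = 1:10)
  ft <- build_feature_table(feats, rates, resp)
  expect_false("MFE_m30_m1" %in% names(ft))     # 20% > 15% threshold
  expect_true("MFE_p1_p30" %in% names(ft))
  expect_equal(attr(ft, "dropped_features"), "MFE_m30_m1")
  expect_equal(nrow(ft), 10)                    # nobody else dropped
  blocks <- attr(ft, "feature_blocks")
  expect_true(all(c("Type", "CAI", "tAI", "Length") %in% names(blocks)))
  expect_true(all(unlist(blocks) %in% names(ft)))

  # with complete UTRs both windows are retained
  rec2 <- make_records(utr_lens = rep(35, 10), seed = 10)
  ft2 <- build_feature_table(compute_features(rec2), rates, resp)
  expect_true(all(c("MFE_m30_m1", "MFE_p1_p30") %in% names(ft2)))
  # join semantics: genes absent from responses are excluded
  ft3 <- build_feature_table(compute_features(rec2), rates, resp[1:6, ])
  expect_equal(nrow(ft3), 6)
})
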