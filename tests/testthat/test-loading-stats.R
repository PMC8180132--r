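two_group_em <- function(seed = 50, ...) {
  small_experiment(seed = seed, n_transcripts = 150, n_cells = 15,
                   molecules_per_cell = 3000, keep_molecules = FALSE, ...)$em
}

test_that("mean_expression_compare classifies against the diagonal", {
  em <- two_group_em()
  # identical matrices: force fixed cells to mirror live cells
  em_tied <- em
  tr <- em$cell_data$treatment
  em_tied$log_tpm[, tr == "fixed"] <- em$log_tpm[, tr == "live"]
  cmp <- mean_expression_compare(em_tied)
  expect_equal(cmp$tied, nrow(em$counts))
  expect_equal(cmp$above + cmp$below + cmp$tied, nrow(em$counts))

  # a feature expressed only in live is above the diagonal
  em_live_only <- em
  f <- rownames(em$counts)[1]
  em_live_only$log_tpm[f, tr == "fixed"] <- 0
  em_live_only$log_tpm[f, tr == "live"] <- 5
  expect_equal(mean_expression_compare(em_live_only, f)$above, 1)
  expect_error(mean_expression_compare(em, character(0)), "empty")
})

test_that("mean comparison counts equal a per-feature loop oracle", {
  em <- two_group_em(seed = 51)
  feats <- sample(rownames(em$counts), 100)
  cmp <- mean_expression_compare(em, feats)
  tr <- em$cell_data$treatment
  above <- below <- tied <- 0
  for (f in feats) {
    a <- mean(em$log_tpm[f, tr == "live"])
    b <- mean(em$log_tpm[f, tr == "fixed"])
    if (a > b) above <- above + 1 else if (b > a) below <- below + 1 else
      tied <- tied + 1
  }
  expect_equal(c(cmp$above, cmp$below, cmp$tied), c(above, below, tied))
})

test_that("CV uses sample sd over TPM and excludes zero-mean features", {
  counts <- cbind(l1 = c(5, 0, 1), l2 = c(5, 2, 1),
                  f1 = c(5, 1, 0), f2 = c(5, 3, 0))
  rownames(counts) <- c("const", "var", "dead")
  em <- make_em(counts, lengths = rep(1, 3),
                treatment = c("live", "live", "fixed", "fixed"))
  cv <- cv_vs_mean(em)
  # constant relative abundance is not possible post-TPM here except by
  # construction; check the loop oracle instead
  tr <- em$cell_data$treatment
  for (i in 1:3) {
    for (grp in c("live", "fixed")) {
      v <- em$tpm[i, tr == grp]
      expected <- if (mean(v) > 0) stats::sd(v) / mean(v) else NA_real_
      got <- cv[[paste0("cv_", grp)]][i]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
  expect_true(is.na(cv$cv_fixed[3]))  # dead in fixed
  expect_gte(attr(cv, "n_excluded"), 1)
})

test_that("CV of a constant feature is 0 and CV is scale-invariant", {
  x <- c(0, 2)
  expect_equal(stats::sd(x) / mean(x), sqrt(2))  # sample-sd convention
  em <- two_group_em(seed = 52)
  cv1 <- cv_vs_mean(em)
  # multiply one feature's tpm by a positive constant
  em2 <- em
  em2$tpm[1, ] <- em2$tpm[1, ] * 7
  cv2 <- cv_vs_mean(em2)
  expect_equal(cv2$cv_live[1], cv1$cv_live[1], tolerance = 1e-12)
  expect_equal(cv2$cv_fixed[1], cv1$cv_fixed[1], tolerance = 1e-12)
})

test_that("cv_vs_mean matches a loop oracle on 50 features", {
  em <- two_group_em(seed = 53)
  feats <- rownames(em$counts)[1:50]
  cv <- cv_vs_mean(em, feats)
  tr <- em$cell_data$treatment
  for (i in seq_along(feats)) {
    v <- em$tpm[feats[i], tr == "live"]
    expect_equal(cv$cv_live[i],
                 if (mean(v) > 0) stats::sd(v) / mean(v) else NA_real_,
                 tolerance = 1e-12)
  }
})

test_that("dropout sweep counts, tests and stars behave", {
  em <- two_group_em(seed = 54)
  sweep <- dropout_threshold_sweep(em, c(0, 1, 5, 10))
  # threshold 0 equals nonzero-tpm counts
  expect_equal(sweep$counts[, "0"], colSums(em$tpm > 0))
  # counts nonincreasing in threshold for every cell
  expect_true(all(apply(sweep$counts, 1, function(r) all(diff(r) <= 0))))
  # beyond the global max everything is 0 and the test is ns
  big <- dropout_threshold_sweep(em, c(0, max(em$tpm) + 1))
  expect_equal(unname(big$counts[, 2]), rep(0, ncol(em$tpm)))
  expect_equal(big$summary$stars[2], "ns")
  expect_true(is.na(big$summary$p[2]))
  expect_error(dropout_threshold_sweep(em, c(5, 1)), "ascending")
})

test_that("significance tiers map p-values as in the figure legends", {
  expect_equal(fixbias:::p_stars(c(0.2, 0.03, 0.005, 5e-5, NA)),
               c("ns", "*", "**", "****", "ns"))
})

test_that("abundance classes use strict pooled-mean cuts", {
  counts <- cbind(l1 = c(100, 4, 50), l2 = c(100, 4, 50),
                  f1 = c(100, 4, 50), f2 = c(100, 4, 50))
  rownames(counts) <- c("high", "low", "mid")
  em <- make_em(counts, lengths = rep(1, 3),
                treatment = c("live", "live", "fixed", "fixed"))
  # pooled mean TPM: high ~ 649k, low ~ 26k, mid ~ 325k (all >> 30)
  acc <- abundance_class_compare(em, low_cut = 3e4, high_cut = 6e5)
  expect_equal(acc$n_low, 1)
  expect_equal(acc$n_high, 1)
  expect_equal(acc$low$per_feature$feature_id, "low")
  # boundary features belong to neither class (strict)
  acc2 <- abundance_class_compare(em, low_cut = 26315.78947368421,
                                  high_cut = 6e5)
  expect_lte(acc2$n_low, 1)
  expect_error(abundance_class_compare(em, 30, 5), "low_cut")
  # both classes empty: one warning each
  expect_warning(expect_warning(abundance_class_compare(em, 1e-9, 1e9),
                                "empty low"), "empty high")
})

test_that("feature_ttest matches the closed-form Welch statistic", {
  cat <- random_catalog(1000, seed = 55)
  set.seed(56)
  s1 <- sample(cat$transcript_id, 500)
  s2 <- sample(cat$transcript_id, 500)
  tt <- feature_ttest(s1, s2, cat)
  # independent Welch computation for length
  v1 <- cat$length[match(s1, cat$transcript_id)]
  v2 <- cat$length[match(s2, cat$transcript_id)]
  se <- sqrt(stats::var(v1) / 500 + stats::var(v2) / 500)
  t_manual <- (mean(v1) - mean(v2)) / se
  df <- se^4 / ((stats::var(v1) / 500)^2 / 499 +
                  (stats::var(v2) / 500)^2 / 499)
  p_manual <- 2 * stats::pt(-abs(t_manual), df)
  expect_equal(tt$t[tt$feature == "length"], t_manual, tolerance = 1e-10)
  expect_equal(tt$p[tt$feature == "length"], p_manual, tolerance = 1e-10)

  # identical sets give t = 0, p = 1
  same <- feature_ttest(s1, s1, cat)
  expect_equal(same$t, c(0, 0))
  expect_equal(same$p, c(1, 1))
  expect_error(feature_ttest(c(s1, "ghost"), s2, cat), "unmapped.*ghost")
  expect_error(feature_ttest(character(0), s2, cat), "nonempty")
})

test_that("null feature_ttest rejects at close to nominal alpha", {
  cat <- random_catalog(400, seed = 57)
  set.seed(58)
  reps <- 200
  rej <- vapply(seq_len(reps), function(i) {
    s1 <- sample(cat$transcript_id, 100)
    s2 <- sample(cat$transcript_id, 100)
    any(feature_ttest(s1, s2, cat)$p[1] < 0.05)
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(rej), 0.05 + 2 * mc_se)
})
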