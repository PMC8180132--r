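test_that("PCA matches an independent eigendecomposition oracle", {
  ex <- small_experiment(seed = 40, n_transcripts = 50, n_cells = 10,
                         molecules_per_cell = 1500, keep_molecules = FALSE)
  pca <- run_pca(ex$em, k = 5)
  x <- t(ex$em$log_tpm)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(xc), symmetric = TRUE)
  for (j in 1:5) {
    v <- eig$vectors[, j]
    w <- pca$loadings[, j]
    # match up to sign
    if (sum(v * w) < 0) v <- -v
    expect_equal(unname(w), unname(v), tolerance = 1e-8)
    expect_equal(unname(pca$scores[, j]), unname(drop(xc %*% v)),
                 tolerance = 1e-8)
  }
  expect_equal(pca$sdev^2,
               eig$values[1:5], tolerance = 1e-8, ignore_attr = TRUE)
  # variance explained matches covariance eigenvalues, nonincreasing
  expect_equal(pca$var_explained, eig$values[1:5] / sum(eig$values),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-12)
  # orthonormal loadings; deterministic sign convention
  expect_equal(crossprod(pca$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in 1:5) {
    w <- pca$loadings[, j]
    expect_gt(w[which.max(abs(w))], 0)
  }
})

test_that("two perfectly correlated features put all variance on PC1", {
  counts <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  em <- make_em(counts, lengths = c(1, 1))
  # bypass compositional closure: decompose an exactly collinear layer
  em$log_tpm <- rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  colnames(em$log_tpm) <- colnames(counts)
  p <- run_pca(em, k = 2)
  expect_gt(p$var_explained[1], 1 - 1e-12)
  expect_error(run_pca(em, k = 10), "exceeds")
})

test_that("scores are equivariant under cell permutation", {
  ex <- small_experiment(seed = 41, n_transcripts = 40, n_cells = 8,
                         molecules_per_cell = 1000, keep_molecules = FALSE)
  p1 <- run_pca(ex$em, k = 3)
  set.seed(1); perm <- sample(ncol(ex$em$counts))
  em_p <- ex$em
  for (layer in c("counts", "tpm", "log_tpm")) {
    em_p[[layer]] <- em_p[[layer]][, perm, drop = FALSE]
  }
  em_p$cell_data <- ex$em$cell_data[perm, , drop = FALSE]
  p2 <- run_pca(em_p, k = 3)
  expect_equal(unname(p2$scores), unname(p1$scores[perm, ]),
               tolerance = 1e-8)
})

test_that("remove_cycle_effect regresses out a known covariate", {
  # constant score leaves matrix untouched
  counts <- matrix(rpois(40, 10), 4, 10,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  em <- make_em(counts, lengths = rep(100, 4))
  em$log_tpm <- matrix(rnorm(40), 4, 10, dimnames = dimnames(counts))
  em_const <- em
  em_const$log_tpm["g1", ] <- 5
  out <- remove_cycle_effect(em_const, "g1")
  expect_equal(out$log_tpm, em_const$log_tpm)

  # a feature equal to the cycle score becomes constant after removal
  em2 <- em
  out2 <- remove_cycle_effect(em2, "g1")
  score <- out2$cell_data$cycle_score
  # g1 standardized IS the score, so residuals are constant
  expect_lt(stats::sd(out2$log_tpm["g1", ]), 1e-10)
  expect_error(remove_cycle_effect(em, character(0)), "empty")
  expect_error(remove_cycle_effect(em, "nope"), "absent.*nope")
})

test_that("cycle removal erases cycle structure in simulated data", {
  ex <- small_experiment(seed = 43, n_transcripts = 300, n_cells = 40,
                         model = null_fixation_model(),
                         molecules_per_cell = 8000, cycle_amp = 2,
                         keep_molecules = FALSE)
  world <- ex$sim$world
  cycle_genes <- ex$catalog$transcript_id[world$cycle_transcripts]
  tercile <- cut(ex$em$cell_data$cycle_phase, 3, labels = FALSE)
  before <- run_pca(ex$em, k = 3)
  after_em <- remove_cycle_effect(ex$em, cycle_genes)
  after <- run_pca(after_em, k = 3)
  sil_before <- separation_score(before, tercile, components = 1:2)
  sil_after <- separation_score(after, tercile, components = 1:2)
  expect_lt(sil_after, 0.1)
  expect_lt(sil_after, sil_before)
})

test_that("separation_score equals a per-cell silhouette loop oracle", {
  ex <- small_experiment(seed = 44, n_transcripts = 100, n_cells = 20,
                         molecules_per_cell = 2000, keep_molecules = FALSE)
  pca <- run_pca(ex$em, k = 2)
  labels <- ex$em$cell_data$treatment
  got <- separation_score(pca, labels)

  x <- pca$scores[, 1:2, drop = FALSE]
  d <- as.matrix(stats::dist(x))
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(got, mean(sil), tolerance = 1e-12)
})

test_that("separation_score behaves at the extremes", {
  scores <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40), 20, 2))
  fake <- structure(list(scores = scores,
                         cell_data = data.frame(cell_id = 1:40)),
                    class = "pca_result")
  labs <- rep(c("a", "b"), each = 20)
  expect_lt(abs(separation_score(fake, labs)), 0.25)  # identical distributions
  far <- rbind(matrix(0, 20, 2), matrix(100, 20, 2)) +
    matrix(rnorm(80, sd = 1e-3), 40, 2)
  fake$scores <- far
  expect_gt(separation_score(fake, labs), 0.99)       # distant point masses
  expect_error(separation_score(fake, rep("a", 40)), "2 label")
  expect_error(separation_score(fake, c("b", rep("a", 39))), ">= 2 cells")
})

test_that("align_component finds the label-correlated PC", {
  set.seed(45)
  scores <- matrix(rnorm(40 * 4), 40, 4)
  fake <- structure(list(scores = scores,
                         cell_data = data.frame(cell_id = 1:40)),
                    class = "pca_result")
  # a binary label split on component 3's sign aligns with component 3
  labels <- ifelse(scores[, 3] > 0, "a", "b")
  expect_equal(align_component(fake, labels), 3)
  # a continuous covariate built from component 2 aligns with component 2
  covar <- 0.9 * scores[, 2] + 0.1 * rnorm(40)
  expect_equal(align_component(fake, covar), 2)
  # restricting the candidate set restricts the answer
  expect_equal(align_component(fake, labels, components = 1:2) %in% 1:2, TRUE)
})

test_that("cell type explains more variance than the fixation effect", {
  ex <- small_experiment(seed = 48, n_transcripts = 2000, n_cells = 50,
                         n_cell_types = 2, molecules_per_cell = 20000,
                         keep_molecules = FALSE)
  pca <- run_pca(ex$em, k = 5)
  ct_pc <- align_component(pca, ex$em$cell_data$cell_type)
  tr_pc <- align_component(pca, ex$em$cell_data$treatment)
  expect_false(ct_pc == tr_pc)
  expect_gt(pca$var_explained[ct_pc], pca$var_explained[tr_pc])
})

test_that("threshold sweep retains the full set at tau 0 and degenerates at k=1", {
  ex <- small_experiment(seed = 46, n_transcripts = 200, n_cells = 15,
                         molecules_per_cell = 4000, keep_molecules = FALSE)
  sw <- threshold_sweep_pca(ex$em, ex$catalog, k_bins = 5, top_n = 50)
  expect_equal(sw$summary$n_transcripts[1], 200)
  expect_equal(sw$summary$tau, 0:4)
  sw1 <- threshold_sweep_pca(ex$em, ex$catalog, k_bins = 1, top_n = 50)
  expect_equal(nrow(sw1$summary), 1)
  expect_equal(sw1$summary$n_transcripts, 200)
})

test_that("top_loadings ranks by absolute loading", {
  ex <- small_experiment(seed = 47, n_transcripts = 50, n_cells = 6,
                         molecules_per_cell = 1000, keep_molecules = FALSE)
  pca <- run_pca(ex$em, k = 2)
  tl <- top_loadings(pca, 1, 10)
  expect_equal(nrow(tl), 10)
  expect_true(all(diff(abs(tl$loading)) <= 1e-15))
  all_tl <- top_loadings(pca, 1, 1e6)
  expect_equal(nrow(all_tl), 50)
})
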