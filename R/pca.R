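#' Principal component analysis of an expression matrix
#'
#' Runs PCA on log2-TPM with features centered across cells (unit scaling
#' optional; log-TPM already compresses dynamic range). A deterministic sign
#' convention orients every component so that its largest-magnitude feature
#' loading is positive, making scores and loadings reproducible across
#' platforms.
#'
#' @param em An `expression_matrix`.
#' @param features Optional feature-id subset to run on.
#' @param k Number of components (default `min(10, cells - 1, features)`).
#' @param scale. Unit-scale features (default `FALSE`).
#' @param on Which layer to decompose (default `"log_tpm"`).
#' @return A `pca_result`: `scores` (cells x k), `loadings` (features x k),
#'   `var_explained` (fraction per component), `sdev`, `features`,
#'   `cell_data`.
#' @export
run_pca <- function(em, features = NULL, k = NULL, scale. = FALSE,
                    on = "log_tpm") {
  x <- em[[on]]
  if (!is.null(features)) {
    idx <- match(features, rownames(x))
    if (anyNA(idx)) stop("unknown features in subset")
    x <- x[idx, , drop = FALSE]
  }
  if (ncol(x) < 2 || nrow(x) < 2) stop("need >= 2 cells and >= 2 features")
  if (is.null(k)) k <- min(10L, ncol(x) - 1L, nrow(x))
  if (k > min(ncol(x), nrow(x))) {
    stop("k exceeds min(cells, features)")
  }
  # drop zero-variance features under scaling to keep prcomp defined
  if (scale.) {
    v <- apply(x, 1, stats::var)
    x <- x[v > 0, , drop = FALSE]
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = scale., rank. = k)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    w <- pc$rotation[, j]
    sign(w[which.max(abs(w))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  total_var <- sum(pc$sdev^2)
  structure(
    list(scores = scores, loadings = loadings,
         var_explained = pc$sdev[seq_len(k)]^2 / total_var,
         sdev = pc$sdev[seq_len(k)],
         features = rownames(x), cell_data = em$cell_data),
    class = "pca_result"
  )
}

#' @exportS3Method base::print
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "cells,", length(x$features),
      "features,", ncol(x$scores), "components\n")
  cat("variance explained:",
      paste0(round(100 * x$var_explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Top-loading feature set of a component
#'
#' @param pca A `pca_result`.
#' @param component Component index.
#' @param n Set size (default 500; truncated to the features used).
#' @return A data frame `(feature_id, loading)` ranked by decreasing
#'   absolute loading.
#' @export
top_loadings <- function(pca, component = 1, n = 500) {
  w <- pca$loadings[, component]
  ord <- order(abs(w), decreasing = TRUE)
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(feature_id = rownames(pca$loadings)[ord], loading = w[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove the cell-cycle effect from an expression matrix
#'
#' Scores each cell as the mean standardized log2-TPM over a cycle gene set,
#' then regresses every feature's log2-TPM on that score by ordinary least
#' squares and keeps the residuals plus the feature mean. A zero-variance
#' score (slope undefined) leaves the matrix unchanged. The per-cell score is
#' stored in `cell_data$cycle_score`.
#'
#' @param em An `expression_matrix`.
#' @param cycle_genes Nonempty character vector of cycle feature ids present
#'   in the matrix.
#' @return The corrected `expression_matrix` (only `log_tpm` is replaced).
#' @export
remove_cycle_effect <- function(em, cycle_genes) {
  if (length(cycle_genes) == 0) stop("cycle gene set is empty")
  miss <- setdiff(cycle_genes, rownames(em$log_tpm))
  if (length(miss) > 0) {
    stop("cycle genes absent from matrix: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  x <- em$log_tpm
  cg <- x[cycle_genes, , drop = FALSE]
  std <- t(scale(t(cg)))             # per-gene standardization across cells
  std[!is.finite(std)] <- 0          # constant cycle genes contribute 0
  score <- colMeans(std)
  vs <- stats::var(score)
  out <- em
  out$cell_data$cycle_score <- score
  if (vs > 0) {
    sc <- score - mean(score)
    beta <- (x %*% sc) / sum(sc^2)   # per-feature OLS slope
    out$log_tpm <- x - beta %*% t(sc)
  }
  out
}

#' Silhouette-based cluster separation score
#'
#' Mean silhouette coefficient of the given per-cell labels using Euclidean
#' distance in the selected component scores; quantifies the cluster
#' separation the source figures assess visually (1 = fully separated,
#' about 0 = intermixed).
#'
#' @param pca A `pca_result`.
#' @param labels Per-cell categories (>= 2 classes, each with >= 2 cells);
#'   defaults to the treatment annotation.
#' @param components Component indices to embed in (default `1:2`).
#' @return Mean silhouette width, in \[-1, 1\].
#' @export
separation_score <- function(pca, labels = NULL, components = 1:2) {
  if (is.null(labels)) labels <- pca$cell_data$treatment
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 label classes")
  if (any(table(labels) < 2)) stop("each label class needs >= 2 cells")
  components <- components[components <= ncol(pca$scores)]
  x <- pca$scores[, components, drop = FALSE]
  sil <- cluster::silhouette(as.integer(labels), stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Align components with a label
#'
#' Identifies which component a (binary or continuous) per-cell covariate
#' loads on, by maximal absolute correlation between component scores and the
#' covariate — PC indices are not assumed fixed across analyses.
#'
#' @param pca A `pca_result`.
#' @param labels Per-cell covariate; factors are converted to integer codes
#'   (point-biserial correlation for two classes).
#' @param components Candidate component indices (default all).
#' @return Index of the best-aligned component.
#' @export
align_component <- function(pca, labels, components = NULL) {
  if (is.null(components)) components <- seq_len(ncol(pca$scores))
  y <- if (is.numeric(labels)) labels else as.integer(as.factor(labels))
  cors <- abs(apply(pca$scores[, components, drop = FALSE], 2,
                    function(s) suppressWarnings(stats::cor(s, y))))
  cors[is.na(cors)] <- 0
  components[which.max(cors)]
}

#' Length/GC threshold-sweep PCA
#'
#' Bins transcripts into `k_bins` equal-size quintile-style bins per axis
#' (length and GC). For each threshold `tau = 0 .. k_bins - 1` it retains
#' transcripts whose length bin AND GC bin are both `>= tau`, reruns the PCA,
#' and records the PC1 treatment separation and the mean length and GC of the
#' `top_n` largest-|loading| transcripts. As `tau` grows the retained set is
#' increasingly long and GC-rich, so a fixation effect comes to dominate PC1.
#'
#' @param em Transcript-level `expression_matrix` with treatment labels.
#' @param catalog The transcript catalog.
#' @param k_bins Number of bins per axis (default 5).
#' @param top_n Loading-set size for the feature statistics (default 500;
#'   100 is the common alternative).
#' @param k Components per PCA (default 5).
#' @return A `threshold_sweep`: data frame `summary` with one row per
#'   threshold (`tau`, `n_transcripts`, `separation_pc1`, `var_explained_pc1`,
#'   `mean_length_top`, `mean_gc_top`) and list `pca` of the per-threshold
#'   `pca_result`s. Thresholds leaving < 2 transcripts are skipped with a
#'   warning.
#' @export
threshold_sweep_pca <- function(em, catalog, k_bins = 5, top_n = 500, k = 5) {
  grid <- quantile_grid(catalog, k_bins, k_bins)
  present <- intersect(rownames(em$log_tpm), catalog$transcript_id)
  rows <- list()
  pcas <- list()
  for (tau in 0:(k_bins - 1)) {
    keep <- grid$transcript_id[grid$length_bin >= tau & grid$gc_bin >= tau]
    keep <- intersect(keep, present)
    if (length(keep) < 2) {
      warning("threshold tau = ", tau, " leaves < 2 transcripts; skipped")
      next
    }
    pca <- run_pca(em, features = keep, k = min(k, length(keep)))
    top <- top_loadings(pca, 1, top_n)
    hit <- match(top$feature_id, catalog$transcript_id)
    sep <- separation_score(pca, em$cell_data$treatment, components = 1)
    rows[[length(rows) + 1]] <- data.frame(
      tau = tau, n_transcripts = length(keep),
      separation_pc1 = sep,
      var_explained_pc1 = pca$var_explained[1],
      mean_length_top = mean(catalog$length[hit]),
      mean_gc_top = mean(catalog$gc[hit])
    )
    pcas[[as.character(tau)]] <- pca
  }
  structure(list(summary = do.call(rbind, rows), pca = pcas),
            class = "threshold_sweep")
}
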