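#' Length-normalize counts to TPM and log2-TPM
#'
#' Computes, per cell, `tpm_i = (c_i / L_i) / sum_j(c_j / L_j) * 1e6` and
#' `log_tpm = log2(tpm + 1)`, the normalization used by every expression
#' diagnostic in the package. Cells with no counts at all yield all-zero TPM
#' with a warning.
#'
#' @param counts Nonnegative matrix, features x cells, rownames = feature ids.
#' @param catalog A transcript catalog supplying feature lengths; ignored
#'   when `lengths` is given.
#' @param lengths Optional explicit per-feature length vector (same order as
#'   rows of `counts`).
#' @param cell_data Optional data frame of cell annotations keyed by
#'   `cell_id` (must cover all columns); carried through to the result.
#' @return An `expression_matrix`: a list with `counts`, `tpm`, `log_tpm`
#'   (all features x cells) and `cell_data`.
#' @export
normalize_log_tpm <- function(counts, catalog = NULL, lengths = NULL,
                              cell_data = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(lengths)) {
    if (is.null(catalog)) stop("provide a catalog or explicit lengths")
    hit <- match(rownames(counts), catalog$transcript_id)
    if (anyNA(hit)) {
      stop("features absent from catalog: ",
           paste(utils::head(rownames(counts)[is.na(hit)], 5), collapse = ", "))
    }
    lengths <- catalog$length[hit]
  }
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " cell(s) with all-zero counts yield all-zero TPM")
  }
  scale <- ifelse(tot > 0, 1e6 / tot, 0)
  tpm <- sweep(rate, 2, scale, "*")
  em <- list(counts = counts, tpm = tpm, log_tpm = log2(tpm + 1),
             cell_data = check_cell_data(cell_data, colnames(counts)))
  class(em) <- "expression_matrix"
  em
}

check_cell_data <- function(cell_data, cell_ids) {
  if (is.null(cell_data)) {
    return(data.frame(cell_id = cell_ids, stringsAsFactors = FALSE))
  }
  stopifnot("cell_id" %in% names(cell_data))
  hit <- match(cell_ids, cell_data$cell_id)
  if (anyNA(hit)) stop("cell_data lacks annotation for some cells")
  if ("treatment" %in% names(cell_data) &&
      anyNA(cell_data$treatment[hit])) {
    stop("missing treatment labels")
  }
  cell_data[hit, , drop = FALSE]
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "features x",
      ncol(x$counts), "cells\n")
  if (!is.null(x$cell_data$treatment)) {
    print(table(x$cell_data$treatment))
  }
  invisible(x)
}

#' Number of detected features per cell
#'
#' @param em An `expression_matrix`.
#' @param threshold Detection calls use `tpm > threshold` when positive,
#'   `counts > 0` when `threshold = 0` and `on = "counts"`.
#' @param on `"counts"` or `"tpm"`.
#' @return Integer vector of per-cell detected-feature counts.
#' @export
detected_features <- function(em, threshold = 0, on = c("counts", "tpm")) {
  on <- match.arg(on)
  m <- if (on == "counts") em$counts else em$tpm
  colSums(m > threshold)
}

#' Filter cells by detected-gene count
#'
#' Retains cells in which strictly more than `min_genes` features have a
#' nonzero count ("more than" is strict: a cell detecting exactly
#' `min_genes` features is removed). The full-scale default of 4000 detected
#' genes matches deep full-length single-cell libraries; synthetic fixtures
#' use smaller values.
#'
#' @param em An `expression_matrix`.
#' @param min_genes Strict lower bound on detected features (default 4000).
#' @return The filtered `expression_matrix`.
#' @export
filter_cells <- function(em, min_genes = 4000) {
  stopifnot(min_genes >= 0)
  keep <- detected_features(em, 0, "counts") > min_genes
  if (!any(keep)) {
    stop("no cells exceed min_genes = ", min_genes,
         "; review the threshold for this dataset")
  }
  subset_cells(em, which(keep))
}

subset_cells <- function(em, idx) {
  out <- list(counts = em$counts[, idx, drop = FALSE],
              tpm = em$tpm[, idx, drop = FALSE],
              log_tpm = em$log_tpm[, idx, drop = FALSE],
              cell_data = em$cell_data[idx, , drop = FALSE])
  class(out) <- "expression_matrix"
  out
}

subset_features <- function(em, features) {
  idx <- match(features, rownames(em$counts))
  if (anyNA(idx)) stop("unknown features: ",
                       paste(utils::head(features[is.na(idx)], 5),
                             collapse = ", "))
  out <- list(counts = em$counts[idx, , drop = FALSE],
              tpm = em$tpm[idx, , drop = FALSE],
              log_tpm = em$log_tpm[idx, , drop = FALSE],
              cell_data = em$cell_data)
  class(out) <- "expression_matrix"
  out
}

#' Pairwise cell correlation and clustering
#'
#' Computes Pearson correlation on log2-TPM between every cell pair over all
#' features (zeros included), clusters the correlation-matrix rows by
#' Euclidean distance with average linkage, and quantifies how intermixed the
#' treatment labels are: the fraction of cells whose nearest neighbour in
#' correlation space carries the opposite treatment, normalized by the
#' label-frequency expectation (1 = as mixed as random labels, 0 = perfectly
#' separated; capped at 1).
#'
#' @param em An `expression_matrix` with >= 2 cells.
#' @param exclude_double_zero Drop, per pair, features undetected in both
#'   cells (default `FALSE`: all features enter, as in standard single-cell
#'   scatter comparisons).
#' @return A `correlation_result`: list with `r` (cells x cells), `hclust`,
#'   `order`, `labels` and `mixing`.
#' @export
correlation_analysis <- function(em, exclude_double_zero = FALSE) {
  x <- em$log_tpm
  if (ncol(x) < 2) stop("need >= 2 cells")
  sds <- apply(x, 2, stats::sd)
  if (exclude_double_zero) {
    n <- ncol(x)
    r <- diag(1, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        keep <- x[, i] > 0 | x[, j] > 0
        r[i, j] <- r[j, i] <-
          suppressWarnings(stats::cor(x[keep, i], x[keep, j]))
      }
    }
  } else {
    r <- suppressWarnings(stats::cor(x))
  }
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance cell(s); correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(colnames(x), colnames(x))
  hc <- stats::hclust(stats::dist(r), method = "average")

  labels <- em$cell_data$treatment
  mixing <- NA_real_
  if (!is.null(labels) && length(unique(labels)) == 2) {
    rr <- r
    diag(rr) <- -Inf
    nn <- max.col(rr, ties.method = "first")
    opp <- mean(labels[nn] != labels)
    tab <- table(labels)
    n <- length(labels)
    expect <- sum(vapply(labels, function(l) {
      (n - tab[[l]]) / (n - 1)
    }, numeric(1))) / n
    mixing <- min(1, opp / expect)
  }
  structure(list(r = r, hclust = hc, order = hc$order, labels = labels,
                 mixing = mixing),
            class = "correlation_result")
}

#' @exportS3Method base::print
print.correlation_result <- function(x, ...) {
  cat("correlation_result:", nrow(x$r), "cells; r in [",
      round(min(x$r[upper.tri(x$r)]), 3), ",",
      round(max(x$r[upper.tri(x$r)]), 3), "]; mixing =",
      round(x$mixing, 3), "\n")
  invisible(x)
}
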