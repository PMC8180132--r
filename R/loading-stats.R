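#' Compare per-feature mean expression between treatments
#'
#' For each feature in `feature_set`, computes the mean log2-TPM within live
#' and within fixed cells and classifies it as above the live-vs-fixed
#' diagonal (live > fixed), below it (fixed > live), or tied (exact
#' equality) — the scatter-plot summary used for loading sets and length
#' bins.
#'
#' @param em An `expression_matrix` with both treatments.
#' @param feature_set Nonempty character vector of feature ids.
#' @return A `group_comparison`: data frame `per_feature`
#'   (`feature_id`, `mean_live`, `mean_fixed`, `class`) plus counts
#'   `above`, `below`, `tied`.
#' @export
mean_expression_compare <- function(em, feature_set = rownames(em$counts)) {
  if (length(feature_set) == 0) stop("feature set is empty")
  tr <- em$cell_data$treatment
  if (!all(c("live", "fixed") %in% tr)) {
    stop("both treatment groups must be present")
  }
  x <- subset_features(em, feature_set)$log_tpm
  m_live <- rowMeans(x[, tr == "live", drop = FALSE])
  m_fixed <- rowMeans(x[, tr == "fixed", drop = FALSE])
  cls <- ifelse(m_live > m_fixed, "above",
                ifelse(m_fixed > m_live, "below", "tied"))
  structure(
    list(per_feature = data.frame(feature_id = feature_set,
                                  mean_live = m_live, mean_fixed = m_fixed,
                                  class = cls, row.names = NULL,
                                  stringsAsFactors = FALSE),
         above = sum(cls == "above"), below = sum(cls == "below"),
         tied = sum(cls == "tied")),
    class = "group_comparison"
  )
}

#' @exportS3Method base::print
print.group_comparison <- function(x, ...) {
  cat("group_comparison:", nrow(x$per_feature), "features;",
      "above (live-enriched):", x$above,
      " below (fixed-enriched):", x$below, " tied:", x$tied, "\n")
  invisible(x)
}

#' Coefficient of variation vs mean expression, per treatment
#'
#' Per feature and treatment, CV = sd / mean of TPM across cells (sample sd,
#' n - 1 denominator). Features with zero mean in a treatment have undefined
#' CV there and are reported as `NA`, with the exclusion count attached.
#'
#' @param em An `expression_matrix`; each treatment needs >= 2 cells.
#' @param feature_set Feature ids (default all).
#' @return A data frame `(feature_id, mean_live, cv_live, mean_fixed,
#'   cv_fixed)` with attribute `n_excluded` = number of feature/treatment
#'   pairs with zero mean.
#' @export
cv_vs_mean <- function(em, feature_set = rownames(em$counts)) {
  tr <- em$cell_data$treatment
  if (any(table(tr) < 2)) stop("each treatment needs >= 2 cells")
  x <- subset_features(em, feature_set)$tpm
  one <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    cv <- ifelse(mu > 0, sdv / mu, NA_real_)
    list(mean = mu, cv = cv)
  }
  live <- one(x[, tr == "live", drop = FALSE])
  fixed <- one(x[, tr == "fixed", drop = FALSE])
  out <- data.frame(feature_id = feature_set,
                    mean_live = live$mean, cv_live = live$cv,
                    mean_fixed = fixed$mean, cv_fixed = fixed$cv,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(is.na(out$cv_live)) + sum(is.na(out$cv_fixed))
  out
}

# Conventional significance tiers for figure legends.
p_stars <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 1e-4, "****",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Detected-feature counts under increasing expression thresholds
#'
#' For each threshold, a feature counts as detected in a cell when its TPM
#' strictly exceeds the threshold. Per-cell detected counts are compared
#' between treatments with a two-sided Welch t-test and mapped to the usual
#' significance tiers (ns p>0.05, * p<0.05, ** p<0.01, **** p<0.0001). A
#' threshold at which a test is undefined (e.g. all counts zero) is reported
#' as `ns` with `p = NA`.
#'
#' @param em An `expression_matrix` with both treatments.
#' @param thresholds Strictly ascending TPM thresholds (default
#'   `c(0, 1, 5, 10, 30, 100)`).
#' @return A `dropout_sweep`: data frame `summary` (`threshold`, `mean_live`,
#'   `mean_fixed`, `p`, `stars`) and matrix `counts` (cells x thresholds).
#' @export
dropout_threshold_sweep <- function(em,
                                    thresholds = c(0, 1, 5, 10, 30, 100)) {
  if (length(thresholds) < 1 || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  tr <- em$cell_data$treatment
  counts <- vapply(thresholds, function(th) colSums(em$tpm > th),
                   numeric(ncol(em$tpm)))
  colnames(counts) <- as.character(thresholds)
  rows <- lapply(seq_along(thresholds), function(i) {
    a <- counts[tr == "live", i]
    b <- counts[tr == "fixed", i]
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    data.frame(threshold = thresholds[i], mean_live = mean(a),
               mean_fixed = mean(b), p = p, stars = p_stars(p))
  })
  structure(list(summary = do.call(rbind, rows), counts = counts),
            class = "dropout_sweep")
}

#' Compare low- and high-abundance feature classes between treatments
#'
#' Classifies features by pooled (all cells) mean TPM into a low class
#' (mean < `low_cut`) and a high class (mean > `high_cut`) — boundaries are
#' strict — and runs [mean_expression_compare()] within each class. Under a
#' fixation effect the low class is typically live-enriched and the high
#' class fixed-enriched (TPM renormalization inflates surviving transcripts).
#'
#' @param em An `expression_matrix`.
#' @param low_cut,high_cut TPM cuts (defaults 5 and 30, `low_cut < high_cut`).
#' @return List with `low` and `high` `group_comparison`s (empty classes give
#'   `NULL` with a warning) and the class sizes.
#' @export
abundance_class_compare <- function(em, low_cut = 5, high_cut = 30) {
  if (low_cut >= high_cut) stop("low_cut must be < high_cut")
  pooled <- rowMeans(em$tpm)
  low_set <- rownames(em$tpm)[pooled < low_cut]
  high_set <- rownames(em$tpm)[pooled > high_cut]
  cmp <- function(set, label) {
    if (length(set) == 0) {
      warning("empty ", label, " abundance class")
      return(NULL)
    }
    mean_expression_compare(em, set)
  }
  list(low = cmp(low_set, "low"), high = cmp(high_set, "high"),
       n_low = length(low_set), n_high = length(high_set))
}

#' Compare transcript length and GC between two loading sets
#'
#' Welch t-tests (two-sided by default) comparing the transcript lengths and
#' GC fractions of two loading sets, typically the top-loading sets of two
#' principal components. Reports the effect direction via the group means.
#'
#' @param set1,set2 Character vectors of transcript ids (nonempty), or
#'   loading-set data frames from [top_loadings()].
#' @param catalog The transcript catalog; all ids must map.
#' @param alternative Passed to [stats::t.test()] with `set1` as `x`
#'   (default `"two.sided"`).
#' @return A data frame with one row per feature (`length`, `gc`): group
#'   means, t statistic, p-value.
#' @export
feature_ttest <- function(set1, set2, catalog,
                          alternative = "two.sided") {
  ids1 <- if (is.data.frame(set1)) set1$feature_id else set1
  ids2 <- if (is.data.frame(set2)) set2$feature_id else set2
  if (length(ids1) == 0 || length(ids2) == 0) stop("loading sets must be nonempty")
  h1 <- match(ids1, catalog$transcript_id)
  h2 <- match(ids2, catalog$transcript_id)
  if (anyNA(h1) || anyNA(h2)) {
    stop("unmapped features: ",
         paste(utils::head(c(ids1[is.na(h1)], ids2[is.na(h2)]), 10),
               collapse = ", "))
  }
  one <- function(v1, v2, what) {
    # constant-data degenerate case: no variance on either side
    tt <- tryCatch(stats::t.test(v1, v2, alternative = alternative),
                   error = function(e) {
                     list(statistic = 0,
                          p.value = if (mean(v1) == mean(v2)) 1 else 0)
                   })
    data.frame(feature = what, mean_set1 = mean(v1), mean_set2 = mean(v2),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }
  rbind(one(catalog$length[h1], catalog$length[h2], "length"),
        one(catalog$gc[h1], catalog$gc[h2], "gc"))
}
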