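# Depth records reindexed to distance from the 3' end: d = L - pos, so d = 0
# is the 3'-terminal base (transcript coordinates are 1-based, 5'->3').
distance_from_3p <- function(depth, catalog) {
  len <- catalog$length[match(depth$transcript_id, catalog$transcript_id)]
  len - depth$pos
}

#' Group coverage profiles by distance from the 3' end
#'
#' Pools per-base depth across the transcripts of each length group, bins it
#' by distance from the 3' end, and normalizes each group/treatment profile
#' to unit mass so coverage *shape* — not sequencing depth — is compared
#' between treatments. The support of a group runs to its longest
#' transcript.
#'
#' @param depth Named list of depth tables (`live`, `fixed`), as from
#'   [load_depth()] or [simulate_depth()].
#' @param catalog The transcript catalog.
#' @param bins A bin assignment from [bin_equal_size()] (by length, k = 10,
#'   computed from the catalog when omitted).
#' @param k Number of length groups when `bins` is omitted (default 10).
#' @param bin_width Distance-bin width in bases (default 50).
#' @return A `coverage_profiles` data frame: `group` (0-based length bin),
#'   `treatment`, `distance` (bin lower edge), `depth` (raw summed depth),
#'   `norm_depth` (sums to 1 within group x treatment). Groups with no
#'   covered transcript in a treatment are empty, with a warning.
#' @export
group_coverage_profiles <- function(depth, catalog, bins = NULL, k = 10,
                                    bin_width = 50) {
  stopifnot(is.list(depth), all(c("live", "fixed") %in% names(depth)))
  if (is.null(bins)) bins <- bin_equal_size(catalog, "length", k)
  out <- list()
  for (tr in c("live", "fixed")) {
    d <- depth[[tr]]
    if (nrow(d) == 0) {
      warning("no ", tr, " depth records"); next
    }
    dist3 <- distance_from_3p(d, catalog)
    grp <- bins$bin_index[match(d$transcript_id, bins$transcript_id)]
    db <- (dist3 %/% bin_width) * bin_width
    agg <- stats::aggregate(d$depth, by = list(group = grp, distance = db),
                            FUN = sum)
    names(agg)[3] <- "depth"
    agg$treatment <- tr
    out[[tr]] <- agg
  }
  prof <- do.call(rbind, out)
  covered <- unique(prof[, c("group", "treatment")])
  missing <- setdiff(
    paste(rep(sort(unique(bins$bin_index)), each = 2), c("live", "fixed")),
    paste(covered$group, covered$treatment)
  )
  if (length(missing) > 0) {
    warning("group(s) with no covered transcript: ",
            paste(missing, collapse = "; "))
  }
  split_key <- paste(prof$group, prof$treatment)
  tot <- tapply(prof$depth, split_key, sum)
  prof$norm_depth <- prof$depth / as.numeric(tot[split_key])
  rownames(prof) <- NULL
  class(prof) <- c("coverage_profiles", "data.frame")
  prof
}

#' Live-minus-fixed coverage difference curves
#'
#' Per group and distance bin, the difference of normalized depths
#' (`live - fixed`); curves are emitted per length group and, when a GC
#' binning is supplied instead, per GC group. Because profiles are
#' normalized per treatment, a uniform depth rescaling of one treatment
#' leaves the curve unchanged.
#'
#' @param profiles A `coverage_profiles` data frame holding both treatments
#'   under one binning scheme.
#' @return A data frame `(group, distance, diff)` where
#'   `diff = norm_live - norm_fixed` (bins absent from one treatment are
#'   treated as zero coverage there).
#' @export
coverage_difference <- function(profiles) {
  live <- profiles[profiles$treatment == "live", ]
  fixed <- profiles[profiles$treatment == "fixed", ]
  key <- function(df) paste(df$group, df$distance)
  all_keys <- union(key(live), key(fixed))
  gl <- live$norm_depth[match(all_keys, key(live))]
  gf <- fixed$norm_depth[match(all_keys, key(fixed))]
  gl[is.na(gl)] <- 0
  gf[is.na(gf)] <- 0
  parts <- do.call(rbind, strsplit(all_keys, " "))
  out <- data.frame(group = as.integer(parts[, 1]),
                    distance = as.numeric(parts[, 2]),
                    diff = gl - gf)
  out[order(out$group, out$distance), , drop = FALSE]
}

#' Per-transcript mapping-integrity ratio
#'
#' The fraction of a transcript's bases with read depth >= 1, in \[0, 1\];
#' transcripts absent from the depth table score 0. The result also flags
#' the top and bottom 10% of transcripts by length and by GC for the
#' integrity scatter comparison.
#'
#' @param depth A depth table for one treatment group.
#' @param catalog The transcript catalog.
#' @return A data frame `(transcript_id, ratio, length_decile, gc_decile)`
#'   with one row per catalog transcript; deciles are `"top10"`,
#'   `"bottom10"` or `"mid"`.
#' @export
mapping_integrity <- function(depth, catalog) {
  covered <- depth[depth$depth >= 1, c("transcript_id", "pos"), drop = FALSE]
  covered <- unique(covered)
  n_cov <- table(factor(covered$transcript_id,
                        levels = catalog$transcript_id))
  ratio <- as.numeric(n_cov) / catalog$length
  n <- nrow(catalog)
  decile_flag <- function(feature) {
    r <- rank_order(catalog, feature)
    rk <- r$rank[match(catalog$transcript_id, r$transcript_id)]
    cut_lo <- ceiling(n * 0.10)
    cut_hi <- n - cut_lo
    ifelse(rk <= cut_lo, "bottom10", ifelse(rk > cut_hi, "top10", "mid"))
  }
  data.frame(transcript_id = catalog$transcript_id, ratio = ratio,
             length_decile = decile_flag("length"),
             gc_decile = decile_flag("gc"),
             stringsAsFactors = FALSE)
}

#' Length-by-GC integrity-quotient grid
#'
#' Per transcript, the log2 quotient of live over fixed mapping-integrity
#' ratios, `q = log2((ratio_live + eps) / (ratio_fixed + eps))` with a
#' pseudocount `eps` making zero ratios well defined; per grid cell (an
#' equal-size length-by-GC binning), the mean quotient. Positive cells mark
#' transcript classes mapped more completely in live cells. Axes are ordered
#' by increasing length and GC; cells without transcripts are `NA`.
#'
#' @param ratio_live,ratio_fixed Outputs of [mapping_integrity()] for the
#'   two treatments (matched to the same catalog).
#' @param catalog The transcript catalog.
#' @param k_length,k_gc Grid resolution (defaults 100 x 100; coarser grids
#'   for desk-scale catalogs).
#' @param eps Pseudocount (default 0.01).
#' @return An `integrity_grid`: list with `q` (per-transcript data frame),
#'   `grid` (matrix `k_length` x `k_gc` of mean quotients, rows = length
#'   bins), and `n` (cell occupancy).
#' @export
integrity_quotient_heatmap <- function(ratio_live, ratio_fixed, catalog,
                                       k_length = 100, k_gc = 100,
                                       eps = 0.01) {
  rl <- ratio_live$ratio[match(catalog$transcript_id,
                               ratio_live$transcript_id)]
  rf <- ratio_fixed$ratio[match(catalog$transcript_id,
                                ratio_fixed$transcript_id)]
  q <- log2((rl + eps) / (rf + eps))
  grid <- quantile_grid(catalog, k_length, k_gc)
  fl <- factor(grid$length_bin, levels = 0:(k_length - 1))
  fg <- factor(grid$gc_bin, levels = 0:(k_gc - 1))
  qm <- tapply(q, list(fl, fg), mean)        # NA where a cell is empty
  nm <- as.matrix(table(fl, fg))
  dimnames(qm) <- dimnames(nm) <-
    list(paste0("len", 0:(k_length - 1)), paste0("gc", 0:(k_gc - 1)))
  structure(
    list(q = data.frame(transcript_id = catalog$transcript_id, q = q,
                        length_bin = grid$length_bin, gc_bin = grid$gc_bin,
                        stringsAsFactors = FALSE),
         grid = qm, n = nm),
    class = "integrity_grid"
  )
}
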