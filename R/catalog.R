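#' Build a transcript feature catalog from a transcriptome FASTA
#'
#' Reads a (multi-line, case-insensitive) transcriptome FASTA and computes the
#' per-transcript features every downstream bias diagnostic is stratified on:
#' transcript length in bases and GC fraction. Ambiguous `N` bases are excluded
#' from both the numerator and the denominator of the GC fraction, so a
#' sequence of only `N`s has GC `NaN`.
#'
#' @param fasta_source Path to a FASTA file of transcript sequences.
#' @param gene_map Optional data frame with columns `transcript_id` and
#'   `gene_id` assigning transcripts to genes. Transcripts absent from the map
#'   keep `gene_id = transcript_id`.
#' @param keep_sequence Keep the sequences in the `sequence` column
#'   (default `FALSE`; lengths and GC are always computed from them).
#'
#' @return A `transcript_catalog`: a data frame with columns `transcript_id`,
#'   `gene_id`, `length`, `gc` (and `sequence` if requested).
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "ATGC", ">t2", "GGGGCC"), fa)
#' load_catalog(fa)
#' @export
load_catalog <- function(fasta_source, gene_map = NULL, keep_sequence = FALSE) {
  seqs <- Biostrings::readBStringSet(fasta_source)
  if (length(seqs) == 0L) {
    stop("no records in FASTA '", fasta_source, "'")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  }
  chr <- toupper(as.character(seqs))
  bad <- regexpr("[^ACGTN]", chr)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(
      "invalid character '", substr(chr[i], bad[i], bad[i]),
      "' in record '", ids[i], "' at position ", bad[i]
    )
  }
  catalog_from_sequences(ids, chr, gene_map = gene_map,
                         keep_sequence = keep_sequence)
}

# Shared constructor: computes length/gc from explicit sequences.
catalog_from_sequences <- function(ids, sequences, gene_map = NULL,
                                   keep_sequence = FALSE) {
  freq <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(sequences), baseOnly = TRUE
  )
  acgt <- freq[, "A", drop = TRUE] + freq[, "C", drop = TRUE] +
    freq[, "G", drop = TRUE] + freq[, "T", drop = TRUE]
  gc <- (freq[, "G", drop = TRUE] + freq[, "C", drop = TRUE]) / acgt
  cat <- data.frame(
    transcript_id = ids,
    gene_id = ids,
    length = nchar(sequences),
    gc = as.numeric(gc),
    stringsAsFactors = FALSE
  )
  if (keep_sequence) cat$sequence <- sequences
  if (!is.null(gene_map)) {
    stopifnot(all(c("transcript_id", "gene_id") %in% names(gene_map)))
    hit <- match(cat$transcript_id, gene_map$transcript_id)
    cat$gene_id[!is.na(hit)] <- gene_map$gene_id[hit[!is.na(hit)]]
  }
  class(cat) <- c("transcript_catalog", "data.frame")
  cat
}

#' Validate a transcript catalog
#'
#' Checks the invariants a catalog must satisfy: unique transcript ids,
#' lengths at least 1, GC fractions in \[0, 1\] (NaN allowed for all-`N`
#' sequences), and length/GC consistency with the `sequence` column when
#' present.
#'
#' @param catalog A catalog as returned by [load_catalog()].
#' @return The catalog, invisibly; errors describe the first violation.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  need <- c("transcript_id", "gene_id", "length", "gc")
  miss <- setdiff(need, names(catalog))
  if (length(miss) > 0L) stop("catalog lacks column(s): ",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(catalog$transcript_id) > 0L) {
    stop("duplicate transcript_id: ",
         catalog$transcript_id[anyDuplicated(catalog$transcript_id)])
  }
  if (any(catalog$length < 1L)) stop("length must be >= 1")
  ok <- is.nan(catalog$gc) | (catalog$gc >= 0 & catalog$gc <= 1)
  if (!all(ok)) stop("gc must lie in [0, 1]")
  if (!is.null(catalog$sequence)) {
    if (!all(nchar(catalog$sequence) == catalog$length)) {
      stop("length column disagrees with sequence lengths")
    }
  }
  invisible(catalog)
}

#' Write / read a catalog as tab-delimited text
#'
#' The interchange format is a four-column TSV with header
#' `transcript_id`, `gene_id`, `length`, `gc`; sequences are not exported.
#'
#' @param catalog A transcript catalog.
#' @param path File path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` a catalog.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(
    catalog[, c("transcript_id", "gene_id", "length", "gc")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  cat <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "integer", "numeric"))
  class(cat) <- c("transcript_catalog", "data.frame")
  validate_catalog(cat)
  cat
}

#' Rank transcripts by a feature
#'
#' Orders transcripts by increasing feature value and assigns ranks 1..N.
#' Ties are broken by `transcript_id` lexicographic order (C locale) so the
#' ranking is deterministic and platform-independent.
#'
#' @param catalog A transcript catalog.
#' @param feature `"length"` or `"gc"`.
#' @return A data frame `(transcript_id, value, rank)` sorted by rank,
#'   suitable for rank-order plots highlighting a transcript subset.
#' @export
rank_order <- function(catalog, feature = c("length", "gc")) {
  feature <- match.arg(feature)
  if (nrow(catalog) == 0L) stop("catalog is empty")
  value <- catalog[[feature]]
  ord <- order(value, ordered_ids(catalog$transcript_id))
  data.frame(
    transcript_id = catalog$transcript_id[ord],
    value = value[ord],
    rank = seq_len(nrow(catalog)),
    stringsAsFactors = FALSE
  )
}

# Locale-independent id ordering (C collation) used by every tie break.
ordered_ids <- function(ids) {
  factor(ids, levels = sort(unique(ids), method = "radix"))
}

#' Split transcripts into equal-size bins by a feature
#'
#' Sorts by the feature (ties broken by transcript id as in [rank_order()])
#' and cuts into `k` contiguous bins. When `N = q * k + r`, the first `r`
#' bins — those holding the smallest feature values — receive `q + 1`
#' transcripts and the rest `q`, so any two bin sizes differ by at most one.
#' Bin indices are 0-based with bin 0 holding the smallest values.
#'
#' @param catalog A transcript catalog.
#' @param feature `"length"` or `"gc"`.
#' @param k Number of bins, `1 <= k <= nrow(catalog)`.
#' @return A data frame `(transcript_id, bin_index, scheme, k)`, one row per
#'   transcript, in catalog order.
#' @export
bin_equal_size <- function(catalog, feature = c("length", "gc"), k) {
  feature <- match.arg(feature)
  n <- nrow(catalog)
  if (k <= 0L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds number of transcripts (", n, ")")
  ro <- rank_order(catalog, feature)
  q <- n %/% k
  r <- n %% k
  sizes <- rep(q, k) + c(rep(1L, r), rep(0L, k - r))
  bin_sorted <- rep(seq_len(k) - 1L, times = sizes)
  idx <- match(catalog$transcript_id, ro$transcript_id)
  data.frame(
    transcript_id = catalog$transcript_id,
    bin_index = bin_sorted[idx],
    scheme = paste0("equal_size_by_", feature),
    k = k,
    stringsAsFactors = FALSE
  )
}

#' Two-dimensional equal-size length-by-GC grid
#'
#' Bins transcripts independently on each axis with [bin_equal_size()] and
#' returns the 2-D cell index. Because length and GC content correlate in
#' real transcriptomes, grid cells may be empty or unevenly populated even
#' though each axis's marginal bins are equal-sized.
#'
#' @param catalog A transcript catalog.
#' @param k_length,k_gc Bin counts for the length and GC axes.
#' @return A data frame `(transcript_id, length_bin, gc_bin)`; bins 0-based.
#' @export
quantile_grid <- function(catalog, k_length, k_gc) {
  bl <- bin_equal_size(catalog, "length", k_length)
  bg <- bin_equal_size(catalog, "gc", k_gc)
  data.frame(
    transcript_id = catalog$transcript_id,
    length_bin = bl$bin_index,
    gc_bin = bg$bin_index[match(catalog$transcript_id, bg$transcript_id)],
    stringsAsFactors = FALSE
  )
}

#' Sum transcript-level counts to gene level
#'
#' Aggregates a transcript-by-cell count matrix to genes using the catalog's
#' `gene_id` assignment; counts of a gene's transcripts are summed per cell.
#'
#' @param counts Matrix, transcripts in rows (rownames are transcript ids).
#' @param catalog A transcript catalog covering all rownames.
#' @return A gene-by-cell matrix with gene ids as rownames.
#' @export
aggregate_genes <- function(counts, catalog) {
  hit <- match(rownames(counts), catalog$transcript_id)
  if (anyNA(hit)) {
    stop("transcripts absent from catalog: ",
         paste(utils::head(rownames(counts)[is.na(hit)], 5L), collapse = ", "))
  }
  gene <- catalog$gene_id[hit]
  out <- rowsum(counts, group = gene)
  out[order(rownames(out), method = "radix"), , drop = FALSE]
}
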