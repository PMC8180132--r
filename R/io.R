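#' Dense and sparse expression-matrix I/O
#'
#' Dense matrices travel as tab-delimited text with a header row of cell ids
#' and feature ids in the first column. Sparse matrices use MatrixMarket
#' triplets plus sidecar feature/cell id lists (`<stem>.mtx`,
#' `<stem>.features.txt`, `<stem>.cells.txt`).
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path (dense) or stem (sparse).
#' @return The written path(s), invisibly; readers return the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_matrix_tsv
#' @export
write_matrix_sparse <- function(m, path) {
  sm <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(sm, paste0(path, ".mtx"))
  writeLines(rownames(m), paste0(path, ".features.txt"))
  writeLines(colnames(m), paste0(path, ".cells.txt"))
  invisible(paste0(path, c(".mtx", ".features.txt", ".cells.txt")))
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_sparse <- function(path) {
  m <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
  rownames(m) <- readLines(paste0(path, ".features.txt"))
  colnames(m) <- readLines(paste0(path, ".cells.txt"))
  m
}

#' Read a per-base depth table (samtools-depth dialect)
#'
#' Parses three-column whitespace/tab-delimited records
#' `(reference id, 1-based position, depth)`. Records naming transcripts
#' absent from the catalog are dropped with a warning listing the ids;
#' positions beyond the catalog length are an error, as are malformed lines
#' and negative depths.
#'
#' @param depth_source Path to a depth file.
#' @param catalog A transcript catalog used for validation.
#' @return A data frame `(transcript_id, pos, depth)`.
#' @export
load_depth <- function(depth_source, catalog) {
  lines <- readLines(depth_source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(transcript_id = character(), pos = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    stop("malformed depth line ", which(nf != 3L)[1],
         ": expected 3 fields, got ", nf[nf != 3L][1])
  }
  flat <- unlist(parts, use.names = FALSE)
  id <- flat[c(TRUE, FALSE, FALSE)]
  pos <- suppressWarnings(as.integer(flat[c(FALSE, TRUE, FALSE)]))
  depth <- suppressWarnings(as.integer(flat[c(FALSE, FALSE, TRUE)]))
  if (anyNA(pos) || anyNA(depth)) {
    stop("malformed depth line ", which(is.na(pos) | is.na(depth))[1],
         ": non-numeric position or depth")
  }
  if (any(depth < 0)) {
    stop("negative depth at line ", which(depth < 0)[1])
  }
  known <- id %in% catalog$transcript_id
  if (!all(known)) {
    warning("dropping records for transcripts absent from catalog: ",
            paste(unique(id[!known]), collapse = ", "))
  }
  id <- id[known]; pos <- pos[known]; depth <- depth[known]
  len <- catalog$length[match(id, catalog$transcript_id)]
  if (any(pos < 1L) || any(pos > len)) {
    bad <- which(pos < 1L | pos > len)[1]
    stop("position ", pos[bad], " outside [1, ", len[bad],
         "] for transcript ", id[bad])
  }
  data.frame(transcript_id = id, pos = pos, depth = depth,
             stringsAsFactors = FALSE)
}

#' Write a depth table in the samtools-depth dialect
#'
#' @param depth A data frame `(transcript_id, pos, depth)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
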