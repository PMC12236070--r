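#' Read an expression matrix
#'
#' Accepts either a MatrixMarket triplet (`.mtx` plus `features`/`barcodes`
#' sidecar TSVs, genes as rows) or a dense CSV/TSV with a header row of cell
#' ids and gene ids in the first column. Matrices are genes x cells everywhere
#' in pathcell; pass `transpose = TRUE` if the file stores cells as rows.
#'
#' @param path matrix path (`.mtx`, `.csv`, `.tsv`/`.txt`).
#' @param features,barcodes sidecar paths for the MTX form; default to
#'   `features.tsv` / `barcodes.tsv` next to the matrix.
#' @param transpose flip orientation after reading.
#' @return A genes x cells matrix (sparse `dgCMatrix` for MTX input, base
#'   matrix for dense input) with unique dimnames.
#' @export
read_matrix <- function(path, features = NULL, barcodes = NULL, transpose = FALSE) {
  if (!file.exists(path)) abort(sprintf("matrix file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    features <- features %||% file.path(dirname(path), "features.tsv")
    barcodes <- barcodes %||% file.path(dirname(path), "barcodes.tsv")
    for (f in c(features, barcodes))
      if (!file.exists(f)) abort(sprintf("sidecar file not found: %s", f))
    m <- Matrix::readMM(path)
    genes <- read.delim(features, header = FALSE)[[1]]
    cells <- read.delim(barcodes, header = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      abort(sprintf("MTX is %d x %d but sidecars declare %d genes, %d cells",
                    nrow(m), ncol(m), length(genes), length(cells)))
    dimnames(m) <- list(genes, cells)
    m <- methods::as(m, "CsparseMatrix")
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     row.names = NULL)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
  }
  if (transpose) m <- t(m)
  as_expression_matrix(m)
}

# validate orientation-agnostic invariants shared by every entry point
as_expression_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort("expression matrix needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(m)))
    abort(sprintf("duplicate gene id(s): %s",
                  paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
  if (anyDuplicated(colnames(m))) abort("duplicate cell ids")
  if (nrow(m) < 1L || ncol(m) < 1L) abort("matrix must have >= 1 gene and >= 1 cell")
  m
}

#' Write an expression or score matrix
#'
#' `write_matrix_tsv()` writes a dense TSV (row ids in the first column,
#' header of column ids). `write_matrix_mtx()` writes a MatrixMarket bundle
#' with `features.tsv`/`barcodes.tsv` sidecars.
#'
#' @param m matrix with dimnames.
#' @param path output TSV path, or the `.mtx` path for the bundle.
#' @return The main output path, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.matrix(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
write_matrix_mtx <- function(m, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as.matrix(m), sparse = TRUE), "generalMatrix"), "CsparseMatrix"), path)
  writeLines(rownames(m), file.path(dirname(path), "features.tsv"))
  writeLines(colnames(m), file.path(dirname(path), "barcodes.tsv"))
  invisible(path)
}

#' Read a score matrix written by [write_matrix_tsv()]
#' @param path TSV path (sets x cells, first column of set ids).
#' @return A numeric matrix of class `aucell_scores`.
#' @export
read_scores_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  structure(m, class = c("aucell_scores", "matrix", "array"))
}

# library-size normalisation: counts -> per-cell scaling to `scale` then log1p
normalize_libsize_log1p <- function(expr, scale = 1e4) {
  cs <- Matrix::colSums(expr)
  cs[cs == 0] <- 1
  out <- as.matrix(expr) * rep(scale / cs, each = nrow(expr))
  dimnames(out) <- dimnames(expr)
  log1p(out)
}
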