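#' Read a cells x features matrix
#'
#' Reads a delimited text matrix (CSV/TSV with a header row of feature ids and
#' a first column of cell ids) or a MatrixMarket coordinate file with sidecar
#' id files (`<stem>.rows.txt`, one cell id per line, and `<stem>.cols.txt`,
#' one feature id per line).
#'
#' @param path Path to the matrix file.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`. Defaults to the file
#'   extension.
#' @return A numeric matrix (dense for csv/tsv, `dgCMatrix` for mtx) with cell
#'   ids as rownames and feature ids as colnames.
#' @export
read_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext == "h5ad")
      stop("h5ad input is not supported by this build; export to csv/tsv/mtx")
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension: ", ext))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    stem <- sub("\\.mtx$", "", path)
    rf <- paste0(stem, ".rows.txt"); cf <- paste0(stem, ".cols.txt")
    if (file.exists(rf)) {
      ids <- readLines(rf)
      if (length(ids) != nrow(m))
        stop("row id sidecar has ", length(ids), " ids but matrix has ",
             nrow(m), " rows: ", rf)
      rownames(m) <- ids
    } else rownames(m) <- paste0("cell_", seq_len(nrow(m)) - 1L)
    if (file.exists(cf)) {
      ids <- readLines(cf)
      if (length(ids) != ncol(m))
        stop("column id sidecar has ", length(ids), " ids but matrix has ",
             ncol(m), " columns: ", cf)
      colnames(m) <- ids
    } else colnames(m) <- paste0("feat_", seq_len(ncol(m)) - 1L)
    m <- methods::as(m, "CsparseMatrix")
    check_feature_matrix(m)
    return(m)
  }
  sep <- if (format == "csv") "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  dat <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, colClasses = "character")
  nfeat <- length(header) - 1L
  if (ncol(dat) != nfeat)
    stop("header names ", nfeat, " features but data rows have ", ncol(dat),
         " values (line 2 onwards): ", path)
  x <- suppressWarnings(matrix(as.numeric(as.matrix(dat)), nrow = nrow(dat),
                               dimnames = dimnames(dat)))
  if (anyNA(x)) stop("non-numeric or missing entries in ", path)
  check_feature_matrix(x)
  x
}

#' Write a cells x features matrix
#'
#' Inverse of [read_matrix()]. Numeric values are written with 17 significant
#' digits so a read/write round trip is lossless.
#'
#' @param x Matrix with cell ids as rownames and feature ids as colnames.
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"mtx"` (writes id sidecars).
#' @export
write_matrix <- function(x, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(x), paste0(stem, ".rows.txt"))
    writeLines(colnames(x), paste0(stem, ".cols.txt"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  xm <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cell_id", colnames(xm)), collapse = sep), con)
  body <- apply(format(xm, digits = 17, trim = TRUE, scientific = FALSE),
                1L, paste, collapse = sep)
  writeLines(paste(rownames(xm), body, sep = sep), con)
  invisible(path)
}

# n_cells >= 2, >= 1 feature, finite entries
check_feature_matrix <- function(x) {
  if (nrow(x) < 2L) stop("need at least 2 cells, got ", nrow(x))
  if (ncol(x) < 1L) stop("need at least 1 feature")
  vals <- if (methods::is(x, "sparseMatrix")) x@x else x
  if (any(!is.finite(vals))) stop("matrix contains non-finite entries")
  invisible(TRUE)
}

#' Write a weighted edge list as TSV
#'
#' @param edges Data frame with columns `source`, `target`, `weight` (and
#'   optionally more, e.g. `multiplier` for directed graphs).
#' @param path Output path.
#' @param comment Optional `# `-prefixed header comment lines (e.g. seed).
#' @export
write_edge_list <- function(edges, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV edge list written by [write_edge_list()]
#' @param path Path to the TSV file.
#' @return Data frame of edges.
#' @export
read_edge_list <- function(path) {
  e <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         check.names = FALSE)
  # node ids are labels, not numbers
  for (col in intersect(c("source", "target"), names(e)))
    e[[col]] <- as.character(e[[col]])
  e
}

#' Read a walk/pipeline configuration from JSON
#'
#' Unknown keys are ignored; missing keys take package defaults.
#' @param path JSON file with any of the [walk_config()] / pipeline fields.
#' @return Named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
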