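#' Expression matrix container
#'
#' A genes x samples numeric matrix with an explicit scale tag. All
#' downstream operations in this package assume genes in rows and samples
#' in columns; the scale tag records whether values are raw counts,
#' depth-normalized expression, or log2 intensities, so that transforms are
#' applied exactly once.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param scale one of `"counts"`, `"normalized"`, `"log2"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids` and `scale`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2"))), scale = "counts")
#' dim(m)
#' @export
expression_matrix <- function(values, scale = c("counts", "normalized", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))])[1:3],
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))])[1:3],
               collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (scale == "counts" && any(values < 0))
    stop("counts-scale matrix contains negative values")
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 scale = scale),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x an `ExpressionMatrix`.
#' @param genes,samples character, integer or logical indices; `NULL` keeps all.
#' @return An `ExpressionMatrix` on the same scale.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, scale = x$scale)
}

#' Read an expression matrix from TSV/CSV or matrix-market files
#'
#' Delimited input must have genes in rows with ids in the first column and a
#' header of sample ids (orientation is auto-corrected when a gene list is
#' supplied and matches the columns better than the rows). Matrix-market
#' input (`*.mtx`) requires sibling name files `<base>.rownames.txt` and
#' `<base>.colnames.txt`, one id per line.
#'
#' @param path path to a `.tsv`/`.csv`/`.txt` table or a `.mtx` file.
#' @param scale scale tag to record (`"counts"`, `"normalized"`, `"log2"`).
#' @param genes optional character vector of known gene ids used to
#'   auto-detect orientation of delimited input.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("counts", "normalized", "log2"),
                            genes = NULL) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    return(.read_expression_mm(path, scale))
  }
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("parse error: fewer than 2 columns in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  num <- df[, -1, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop("parse error: non-numeric cells in column(s): ",
         paste(names(num)[bad], collapse = ", "))
  v <- as.matrix(num)
  rownames(v) <- ids
  # orientation: if a supplied gene list matches column names better than
  # row names, the file was written samples x genes
  if (!is.null(genes)) {
    hit_rows <- mean(rownames(v) %in% genes)
    hit_cols <- mean(colnames(v) %in% genes)
    if (hit_cols > hit_rows) v <- t(v)
  }
  expression_matrix(v, scale = scale)
}

.read_expression_mm <- function(path, scale) {
  base <- sub("\\.mtx$", "", path)
  rfile <- paste0(base, ".rownames.txt")
  cfile <- paste0(base, ".colnames.txt")
  if (!file.exists(rfile) || !file.exists(cfile))
    stop("matrix-market input requires name files ", rfile, " and ", cfile)
  m <- as.matrix(Matrix::readMM(path))
  rn <- readLines(rfile)
  cn <- readLines(cfile)
  if (length(rn) != nrow(m))
    stop(sprintf("row name file has %d entries but matrix has %d rows",
                 length(rn), nrow(m)))
  if (length(cn) != ncol(m))
    stop(sprintf("column name file has %d entries but matrix has %d columns",
                 length(cn), ncol(m)))
  dimnames(m) <- list(rn, cn)
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix as TSV (or matrix-market triplets)
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path; a `.mtx` extension selects matrix-market output
#'   with sibling `.rownames.txt` / `.colnames.txt` files.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (grepl("\\.mtx$", path)) {
    base <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    writeLines(rownames(x$values), paste0(base, ".rownames.txt"))
    writeLines(colnames(x$values), paste0(base, ".colnames.txt"))
    return(invisible(path))
  }
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a counts or normalized matrix
#'
#' Applies `log2(value + offset)` and retags the scale. Refuses to transform
#' data already on log2 scale unless `force = TRUE`, so accidental double
#' transformation cannot occur.
#'
#' @param x an `ExpressionMatrix` on counts or normalized scale.
#' @param offset pseudo-value added before the log; default 1.
#' @param force transform even if already log2 (rarely sensible).
#' @return An `ExpressionMatrix` on log2 scale.
#' @export
log2_transform <- function(x, offset = 1, force = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale == "log2" && !force)
    stop("matrix is already on log2 scale (use force = TRUE to override)")
  v <- log2(x$values + offset)
  expression_matrix(v, scale = "log2")
}
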