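#' Signature set container
#'
#' Holds named gene modules together with a direction sign per module:
#' +1 for programs induced after injury, -1 for steady-state programs
#' suppressed after injury. The canonical set has six signatures C1..C6
#' with C1-C3 induced and C4-C6 suppressed.
#'
#' @param genes named list of character vectors, one per signature. Lists
#'   must be pairwise disjoint unless `strict = FALSE`.
#' @param signs numeric vector of +1/-1, one per signature. Default: first
#'   half +1, second half -1, matching the C1-C3 / C4-C6 convention.
#' @param strict error (TRUE) or warn (FALSE) on overlapping gene lists.
#' @return An object of class `SignatureSet` with elements `names`, `genes`,
#'   `signs`.
#' @examples
#' ss <- signature_set(list(C1 = c("A", "B"), C2 = c("C", "D")),
#'                     signs = c(1, -1))
#' @export
signature_set <- function(genes, signs = NULL, strict = TRUE) {
  if (!is.list(genes) || length(genes) == 0)
    stop("'genes' must be a non-empty named list of gene vectors")
  if (is.null(names(genes)) || any(names(genes) == ""))
    stop("every signature needs a name")
  if (any(lengths(genes) == 0)) stop("empty signature gene list")
  if (is.null(signs)) {
    k <- length(genes)
    signs <- rep(c(1, -1), c(ceiling(k / 2), floor(k / 2)))
  }
  if (length(signs) != length(genes))
    stop("length of 'signs' must match number of signatures")
  if (!all(signs %in% c(1, -1))) stop("signs must be +1 or -1")
  genes <- lapply(genes, as.character)
  all_genes <- unlist(genes, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    msg <- paste("overlapping signature gene lists:",
                 paste(utils::head(unique(all_genes[duplicated(all_genes)]), 5),
                       collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  names(signs) <- names(genes)
  structure(list(names = names(genes), genes = genes, signs = signs),
            class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet: %d signatures, %d genes\n",
              length(x$genes), length(unlist(x$genes))))
  for (nm in x$names)
    cat(sprintf("  %s [%+d] %d genes\n", nm, x$signs[[nm]],
                length(x$genes[[nm]])))
  invisible(x)
}

#' @export
length.SignatureSet <- function(x) length(x$genes)

#' Read a signature set from a GMT file
#'
#' GMT dialect: `name <tab> description <tab> gene1 <tab> gene2 ...` per line.
#' A `+1` or `-1` token in the description field sets the signature sign;
#' otherwise the first half of the signatures default to +1 (induced) and the
#' second half to -1 (suppressed).
#'
#' @param path path to a GMT file.
#' @param strict error on overlapping gene lists (default) or just warn.
#' @return A [signature_set()].
#' @export
read_gmt <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3
  if (any(bad))
    stop("GMT line(s) with no genes: ", paste(which(bad), collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- nm
  signs <- rep(NA_real_, length(nm))
  signs[grepl("(^|\\s)\\+1(\\s|$)", desc)] <- 1
  signs[grepl("(^|\\s)-1(\\s|$)", desc)] <- -1
  if (anyNA(signs)) {
    k <- length(nm)
    default <- rep(c(1, -1), c(ceiling(k / 2), floor(k / 2)))
    signs[is.na(signs)] <- default[is.na(signs)]
  }
  signature_set(genes, signs = signs, strict = strict)
}

#' Write a signature set as GMT
#'
#' The sign is stored as a `+1`/`-1` token in the description field so a
#' round trip through [read_gmt()] preserves it.
#'
#' @param x a `SignatureSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "SignatureSet"))
  lines <- vapply(x$names, function(nm) {
    paste(c(nm, sprintf("%+d", x$signs[[nm]]), x$genes[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
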