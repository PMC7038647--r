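# Expression matrices are plain numeric matrices, samples in rows, features in
# columns, both dimensions named. Helpers here validate that contract and read
# and write the on-disk TSV dialect (first column = sample id, header = feature
# ids; a transposed dialect is accepted via `transposed`).

#' Validate an expression matrix
#'
#' Checks that `x` is a numeric matrix of non-negative, finite values with
#' unique sample (row) and feature (column) identifiers, and returns it
#' unchanged. All preprocessing and modelling functions in the package call
#' this on entry.
#'
#' @param x A numeric matrix, samples in rows and features in columns, with
#'   both `rownames` and `colnames` set.
#' @param what Label used in error messages.
#' @return `x`, invisibly validated (returned visibly for piping).
#' @export
validate_expression <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (samples x features)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must carry sample ids (rownames) and feature ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop(what, ": duplicated sample ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop(what, ": duplicated feature ids", call. = FALSE)
  if (any(!is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  if (any(x < 0)) stop(what, " contains negative values", call. = FALSE)
  x
}

#' Read an expression matrix from TSV/CSV
#'
#' @param path Path to a delimited text file. The first column holds sample
#'   identifiers and the header row holds feature identifiers, unless
#'   `transposed = TRUE` in which case rows are features and columns samples.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @param transposed Set `TRUE` if the file stores features in rows.
#' @return A validated numeric matrix, samples x features.
#' @export
read_expression <- function(path, sep = "\t", transposed = FALSE) {
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  if (transposed) x <- t(x)
  validate_expression(x)
}

#' Write an expression matrix to TSV
#'
#' @param x Samples x features numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: `set_id TAB description TAB gene TAB gene ...`.
#' Duplicate gene ids within a line are dropped.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors of
#'   member gene ids, with a `descriptions` attribute (named character
#'   vector) and class `"gene_set_collection"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop("GMT line(s) ", paste(which(bad), collapse = ", "),
         " have fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(setNames(members, ids), descriptions = setNames(desc, ids))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (member gene ids per set).
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique set ids", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty", call. = FALSE)
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions[names(sets)],
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "sets, member counts ",
      paste(range(lengths(x)), collapse = "-"), "\n")
  invisible(x)
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
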