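#' Gene-by-sample expression matrix with a processing-stage tag
#'
#' A light container for a genes x samples numeric matrix that records how
#' far along the preprocessing chain the values are: raw \code{"counts"},
#' library-size-normalized log-scale \code{"normalized"}, or gene-wise
#' z-scored \code{"standardized"}. Downstream scoring functions check the
#' stage tag so that, e.g., a risk score is never computed on raw counts.
#'
#' @param values numeric matrix, genes as rows and samples as columns; both
#'   dimnames must be present and unique.
#' @param stage one of \code{"counts"}, \code{"normalized"},
#'   \code{"standardized"}.
#' @return An object of class \code{expression_matrix}: a list with elements
#'   \code{values} and \code{stage}.
#' @examples
#' m <- matrix(rpois(12, 10), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, "counts")
#' @export
expression_matrix <- function(values,
                              stage = c("counts", "normalized", "standardized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (!is.numeric(values))
    abort("expression values must be numeric", "invalid_input")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("expression matrix needs gene rownames and sample colnames",
          "invalid_input")
  if (anyDuplicated(rownames(values)))
    abort("duplicate gene ids", "invalid_input")
  if (anyDuplicated(colnames(values)))
    abort("duplicate sample ids", "invalid_input")
  if (stage != "counts" && anyNA(values))
    abort(sprintf("missing values not allowed at stage '%s'", stage),
          "invalid_input")
  structure(list(values = values, stage = stage), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, stage = %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an \code{expression_matrix}.
#' @return character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

assert_stage <- function(x, stage, arg = deparse(substitute(x))) {
  if (!inherits(x, "expression_matrix"))
    abort(sprintf("%s must be an expression_matrix", arg), "invalid_input")
  if (!x$stage %in% stage)
    abort(sprintf("%s must be at stage %s (got '%s')", arg,
                  paste(sQuote(stage), collapse = " or "), x$stage),
          "invalid_input")
  invisible(x)
}

#' Read / write expression matrices as TSV
#'
#' Plain-text interchange format: tab-separated, genes as rows, first column
#' \code{gene_id}, remaining column names are sample ids.
#'
#' @param path file path.
#' @param stage processing-stage tag to attach on read.
#' @return \code{read_expression_tsv} returns an \code{expression_matrix};
#'   \code{write_expression_tsv} returns \code{path} invisibly.
#' @export
read_expression_tsv <- function(path, stage = "normalized") {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "file_not_found")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, stage)
}

#' @rdname read_expression_tsv
#' @param x an \code{expression_matrix}.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
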