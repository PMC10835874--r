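#' Prognostic gene signature
#'
#' A signature is a set of genes with per-gene weights (log hazard ratios
#' from a training meta-analysis) whose sign encodes the risk direction:
#' positive weight = expression associated with increased risk, negative =
#' reduced risk. Weights of zero are not allowed - a gene with no direction
#' carries no prognostic information and must not enter a score.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param weight numeric vector of non-zero per-gene log hazard ratios.
#' @param name signature label used in reports.
#' @return A \code{signature} object: a data.frame with columns
#'   \code{gene_id}, \code{weight}, \code{direction} and a \code{name}
#'   attribute.
#' @examples
#' sig <- signature_def(c("g1", "g2"), c(0.5, -0.3), name = "toy")
#' @export
signature_def <- function(gene_id, weight, name = "signature") {
  gene_id <- as.character(gene_id)
  weight <- as.numeric(weight)
  if (length(gene_id) == 0L)
    abort("a signature needs at least one gene", "empty_signature")
  if (length(gene_id) != length(weight))
    abort("gene_id and weight lengths differ", "invalid_input")
  if (anyDuplicated(gene_id))
    abort("duplicate gene ids in signature", "invalid_input")
  if (any(!is.finite(weight) | weight == 0))
    abort("signature weights must be finite and non-zero", "invalid_input")
  out <- data.frame(gene_id = gene_id, weight = weight,
                    direction = sign(weight), stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("signature", "data.frame")
  out
}

signature_name <- function(sig) attr(sig, "name") %||% "signature"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> '%s': %d genes (%d risk, %d protective)\n",
              signature_name(x), nrow(x),
              sum(x$direction > 0), sum(x$direction < 0)))
  invisible(x)
}

#' Read / write signatures as TSV
#'
#' Format: tab-separated with columns \code{gene_id}, \code{weight},
#' \code{direction} (direction is recomputed from the weight sign on read).
#'
#' @param path file path.
#' @param name signature label; defaults to the file base name.
#' @export
read_signature_tsv <- function(path, name = NULL) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "file_not_found")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  signature_def(df$gene_id, df$weight,
                name = name %||% sub("\\.tsv$", "", basename(path)))
}

#' @rdname read_signature_tsv
#' @param sig a \code{signature}.
#' @export
write_signature_tsv <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
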