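#' Construct an expression matrix
#'
#' The universal currency of the pipeline: a genes x samples numeric matrix
#' with HGNC symbols as row names and sample identifiers as column names.
#' Values are log2-scale unless flagged otherwise; linear-scale matrices occur
#' only on the way into the non-negative factorization.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimnames must be set.
#' @param scale_flag `"log2"` (default) or `"linear"`.
#' @return a numeric matrix of class `ExpressionMatrix` with a `scale_flag`
#'   attribute.
#' @export
expression_matrix <- function(values, scale_flag = c("log2", "linear")) {
  scale_flag <- match.arg(scale_flag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one gene and one sample")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  structure(values, scale_flag = scale_flag,
            class = c("ExpressionMatrix", class(values)))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale_flag")))
  invisible(x)
}

#' Test for the ExpressionMatrix class
#' @param x object
#' @return logical scalar
#' @export
is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

em_scale <- function(x) {
  s <- attr(x, "scale_flag")
  if (is.null(s)) "log2" else s
}

#' Convert an expression matrix to the linear scale
#'
#' Log2 values are exponentially transformed (`2^x`) ahead of non-negative
#' matrix factorization; linear input is returned unchanged.
#'
#' @param expr `ExpressionMatrix`
#' @return linear-scale `ExpressionMatrix`
#' @export
as_linear <- function(expr) {
  stopifnot(is_expression_matrix(expr))
  if (em_scale(expr) == "linear") return(expr)
  expression_matrix(2^unclass(expr), scale_flag = "linear")
}

#' Convert an expression matrix to the log2 scale
#' @param expr `ExpressionMatrix`
#' @param offset added before taking logs (default 0; the simulator uses 1)
#' @return log2-scale `ExpressionMatrix`
#' @export
as_log2 <- function(expr, offset = 0) {
  stopifnot(is_expression_matrix(expr))
  if (em_scale(expr) == "log2") return(expr)
  expression_matrix(log2(unclass(expr) + offset), scale_flag = "log2")
}

#' Extract the plain numeric matrix of an expression matrix
#'
#' Drops the class and scale attributes, returning the bare genes x samples
#' matrix — convenient when subsetting before rebuilding with
#' [expression_matrix()].
#'
#' @param expr `ExpressionMatrix`
#' @return numeric matrix
#' @export
em_values <- function(expr) {
  x <- unclass(expr)
  attr(x, "scale_flag") <- NULL
  x
}
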