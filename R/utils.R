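#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert expression values to linear scale
#'
#' Log2 tables are exponentiated base 2; linear tables pass through.
#' @param x an `expression_table`
#' @return numeric matrix (samples x features) on the linear scale
#' @keywords internal
linear_values <- function(x) {
  stopifnot(inherits(x, "expression_table"))
  if (x$scale == "log2") 2^x$values else x$values
}

#' Convert expression values to log2 scale
#' @param x an `expression_table`
#' @param pseudo pseudo-count added before taking log2 of linear values
#' @keywords internal
log2_values <- function(x, pseudo = 0) {
  stopifnot(inherits(x, "expression_table"))
  if (x$scale == "log2") x$values else log2(x$values + pseudo)
}

tei_log <- function(..., level = "info") {
  opt <- getOption("teisig.verbose", TRUE)
  if (isTRUE(opt)) message("[teisig] ", ...)
  invisible(NULL)
}
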