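#' @useDynLib rvexpress, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Derive a per-gene RNG seed from the root seed and the gene id, so results do
# not depend on the order genes are iterated. Stays inside 32-bit integer range.
deriveSeed <- function(seed, id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 31 + b) %% 2147483647L
  as.integer((as.numeric(seed) * 2654435769 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
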