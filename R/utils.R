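#' @importFrom stats median pbinom dbinom pchisq pnorm rbinom rexp rgeom rlnorm
#'   rnorm rpois runif setNames complete.cases kruskal.test wilcox.test sd
#'   quantile uniroot rbeta cor
#' @importFrom utils read.delim write.table
NULL

# internal: stop with a plain message, no call
abort <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_prob <- function(p, what) {
  if (!is_scalar_number(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1], got %s",
                  what, format(p)))
  }
  invisible(p)
}

# run `expr` under a temporary RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), expr)
}
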