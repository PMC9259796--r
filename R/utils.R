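#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rexp runif rnorm plogis qlogis sd var median
#'   pchisq pnorm kmeans quantile integrate uniroot predict coef
#' @importFrom utils write.table read.table head modifyList
#' @importFrom Rcpp sourceCpp
#' @useDynLib aesubtype, .registration = TRUE
NULL

# Derive a stage-specific sub-seed from a global seed so that adding a stage
# never perturbs the random stream of earlier stages. Kept below 2^31 - 1.
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435769 + h * 97) %% 2147483629L)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483629L), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

format_num <- function(x) formatC(x, digits = 10, format = "g")
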