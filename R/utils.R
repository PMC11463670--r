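#' @importFrom methods as is new
#' @importFrom stats cor phyper pnorm rbinom rgamma rlnorm rmultinom rnbinom
#'   rnorm rpois runif sd setNames var quantile prcomp
#' @importFrom utils head read.table write.table combn
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Stage-granularity logging: every filter reports records in/out so the
# survivorship bookkeeping is reproducible from the console transcript.
log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Derive a per-stage seed from the pipeline seed so stages are independently
# reproducible; kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) %% 1000L
  (as.integer(seed) * 1009L + offs) %% .Machine$integer.max
}

# Deciles (1..10) of x, safe for heavy ties / constant vectors.
decile_bin <- function(x, n_bins = 10L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                        na.rm = TRUE, names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}
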