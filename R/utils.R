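# Internal helpers shared across modules.

#' @importFrom stats pnorm qnorm runif rnorm rlnorm rexp median coef lm optim
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

# Classed input error so callers can distinguish bad arguments from bugs.
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("tonewheel_input_error", "error")))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_input(...)
  invisible(TRUE)
}

# Gauss error function via the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Per-trial seeds derived from a session seed by counter, kept within the
# 32-bit signed range R's set.seed() accepts.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(counter)) %% 2147483647L)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
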