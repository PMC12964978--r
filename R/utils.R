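#' @importFrom rlang .data abort %||%
#' @importFrom stats quantile rbinom rexp rlnorm runif rbeta rgamma qnorm
#'   pnorm pbinom pchisq glm binomial coef fitted wilcox.test median var
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit seed for a named substream, so each stage/parameter
# owns its own reproducible stream and adding one does not perturb others.
derive_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000000007
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Median and quartiles under the documented convention: linear interpolation
# between order statistics (R quantile type 7).
iqr_summary <- function(x) {
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3])
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "pneumocea_config_error")
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "pneumocea_input_error")
}
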