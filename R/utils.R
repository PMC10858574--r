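#' Inverse logit
#'
#' @param x Numeric vector on the linear-predictor scale.
#' @return Probabilities `exp(x) / (1 + exp(x))`.
#' @keywords internal
expit <- function(x) stats::plogis(x)

#' Logit
#'
#' @param p Numeric vector of probabilities in (0, 1).
#' @return Log odds `log(p / (1 - p))`.
#' @keywords internal
logit <- function(p) stats::qlogis(p)

# Deterministic named-stream seed splitter. All randomness in the package
# flows from a single user seed; substreams for conceptually independent
# draws (covariates, outcomes, chains, syntheses, replicates) are derived
# by hashing (seed, label) so each component is reproducible in isolation.
# Values stay below 2^31 - 1 (R integer range).
seed_stream <- function(seed, ...) {
  label <- paste(..., sep = "/")
  m <- 2147483647
  h <- (as.double(seed) %% m) + 1
  for (k in utf8ToInt(label)) {
    h <- (h * 69069 + k) %% m
  }
  as.integer(h)
}

# Apply the link function named by `link` to a mean.
apply_link <- function(mu, link = c("logit", "identity", "log")) {
  link <- match.arg(link)
  switch(link,
    logit = logit(mu),
    identity = mu,
    log = log(mu)
  )
}

# Stop with a classed error condition (callers can catch by class).
stop_mim <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mim_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
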