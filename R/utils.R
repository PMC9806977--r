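# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a classed condition so callers can distinguish configuration
# errors (bad inputs/config) from validation errors (bad data values).
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("trialcea_config_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("trialcea_validation_error", "error")))
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(what, " must be in [0, 1]")
  }
  invisible(x)
}

# Deterministic 32-bit FNV-1a hash of an R object (via serialization) or of
# raw bytes; used for manifest digests without adding a digest dependency.
fnv1a32 <- function(x) {
  bytes <- if (is.raw(x)) x else serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    lo <- h %% 256 # xor only touches the low byte since b < 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by the FNV prime 16777619 via 16-bit split,
    # keeping every intermediate below 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Derive a per-stream 31-bit seed from a master seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647)
}

# Expected value of clamp(round(Z), lo, hi) for Z ~ N(mu, sd): the exact mean
# of a discretized, bounded Likert response given its latent normal. Closed
# form; used by ground_truth so no simulation enters the truth computation.
discretized_normal_mean <- function(mu, sd, lo, hi) {
  ks <- lo:hi
  p <- vapply(ks, function(k) {
    upper <- if (k == hi) Inf else k + 0.5
    lower <- if (k == lo) -Inf else k - 0.5
    stats::pnorm(upper, mu, sd) - stats::pnorm(lower, mu, sd)
  }, numeric(1))
  sum(ks * p)
}

# Inverse of discretized_normal_mean in mu: the latent mean whose rounded,
# clamped response has expectation `target`. Lets configured trajectory means
# be stated on the observed item scale and hit exactly in expectation.
latent_from_item_mean <- function(target, sd, lo, hi) {
  if (target <= lo || target >= hi) {
    stop_config("target item mean must lie strictly inside [", lo, ", ", hi, "]")
  }
  stats::uniroot(function(mu) discretized_normal_mean(mu, sd, lo, hi) - target,
                 lower = lo - 10 * sd, upper = hi + 10 * sd,
                 tol = 1e-10)$root
}
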