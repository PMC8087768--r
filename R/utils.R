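# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All generator randomness funnels through
# this so that cohorts are reproducible independent of evaluation order.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed and counters (subject index, trial
# index, ...). Plain integer hashing keeps streams reproducible no matter in
# which order trials are generated; result stays below 2^31.
child_seed <- function(seed, ...) {
  counters <- c(...)
  h <- (seed %% 2147483647) + 1
  for (k in seq_along(counters)) {
    h <- (h * 48271 + counters[k] * 8191 + k * 131) %% 2147483647
  }
  as.integer(h)
}

# Cubic smoothstep: 0 at u <= 0, 1 at u >= 1, C^1 monotone in between.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Unwrap a phase-angle series (radians) so finite differences see a
# continuous signal rather than +/- pi jumps.
unwrap_angle <- function(phi) {
  d <- diff(phi)
  jumps <- round(d / (2 * pi))
  phi - c(0, cumsum(jumps)) * 2 * pi
}

# Truncated-normal draw by rejection; falls back to clamping if the window
# is extremely improbable (degenerate specs).
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0 || lower == upper) return(rep((lower + upper) / 2, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- rnorm(1, mean, sd)
    tries <- 0
    while ((x < lower || x > upper) && tries < 200) {
      x <- rnorm(1, mean, sd)
      tries <- tries + 1
    }
    out[i] <- min(max(x, lower), upper)
  }
  out
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
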