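#' Specify a zero-lag Butterworth low-pass filter
#'
#' Gait labs conventionally report a "fourth-order zero-lag Butterworth"
#' filter, meaning a second-order pass run forward and then backward so that
#' the net magnitude response is fourth order and the phase shift cancels.
#' That convention is the default here; set `order_per_pass = "full"` to run
#' the stated order in each direction instead.
#'
#' @param order Total filter order (even). Default 4.
#' @param cutoff Low-pass cutoff frequency in Hz.
#' @param zero_lag Apply forward-backward (zero phase)? Default `TRUE`.
#' @param order_per_pass `"half"` (default, order/2 per direction) or
#'   `"full"` (the stated order per direction).
#' @return A `filter_spec` list understood by [zero_lag_butterworth()].
#' @examples
#' filter_spec(4, 6)   # kinematic smoothing
#' filter_spec(4, 100) # force-plate smoothing
#' @export
filter_spec <- function(order = 4, cutoff, zero_lag = TRUE,
                        order_per_pass = c("half", "full")) {
  order_per_pass <- match.arg(order_per_pass)
  if (order %% 2 != 0 || order < 2) abort("`order` must be a positive even integer.")
  stopifnot_scalar_pos(cutoff, "cutoff")
  structure(
    list(order = as.integer(order), cutoff = cutoff, kind = "lowpass",
         zero_lag = isTRUE(zero_lag), order_per_pass = order_per_pass),
    class = "filter_spec"
  )
}

# Single IIR pass with steady-state initial conditions: the signal is
# modelled as constant at its first sample before t = 0, which together with
# odd-reflection end padding suppresses startup transients (the MATLAB
# filtfilt convention). Vectorized through stats::filter.
iir_pass <- function(b, a, x) {
  nb <- length(b)
  na <- length(a)
  # moving-average part, assuming x was constant before the first sample
  xp <- c(rep(x[1], nb - 1), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb - 1 + seq_along(x)]
  if (na > 1) {
    y <- stats::filter(u, -a[-1], method = "recursive", init = rep(x[1], na - 1))
    y <- as.numeric(y)
  } else {
    y <- u
  }
  y
}

#' Zero-lag Butterworth low-pass filtering
#'
#' Applies the filter described by a [filter_spec()] to a uniformly sampled
#' series. The forward-backward pass has zero phase shift (a symmetric pulse
#' keeps its peak location) and unit DC gain (a constant series is returned
#' unchanged). Ends are handled by odd reflection about the end points with
#' steady-state initial conditions, so short series do not acquire edge
#' transients.
#'
#' @param x Numeric series, uniformly sampled.
#' @param rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered numeric series, same length as `x`.
#' @export
zero_lag_butterworth <- function(x, rate, spec) {
  if (!inherits(spec, "filter_spec")) abort("`spec` must come from filter_spec().")
  stopifnot_scalar_pos(rate, "rate")
  if (spec$cutoff >= rate / 2) {
    abort(sprintf("Cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz.",
                  spec$cutoff, rate / 2))
  }
  if (anyNA(x) || !all(is.finite(x))) abort("`x` must be finite.")
  n <- length(x)
  min_len <- 3L * spec$order
  if (n < min_len) {
    abort(sprintf("Series too short for filtering: length %d < minimum %d (3 x order).",
                  n, min_len))
  }
  n_pass <- if (spec$zero_lag && spec$order_per_pass == "half") spec$order %/% 2L else spec$order
  bf <- signal::butter(n_pass, spec$cutoff / (rate / 2), type = "low")
  b <- bf$b
  a <- bf$a
  pad <- min(3L * (max(length(a), length(b)) - 1L) * 3L, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_pass(b, a, xp)
  if (spec$zero_lag) {
    y <- rev(iir_pass(b, a, rev(y)))
  }
  y[pad + seq_len(n)]
}

#' Downsample a force-plate series to the kinematic rate
#'
#' Force platforms are commonly sampled at an integer multiple of the camera
#' rate; synchronization keeps every k-th sample starting from the first so
#' the retained samples fall exactly on kinematic frame times. An
#' anti-aliasing low-pass (normally the 100 Hz force filter) can be applied
#' first; pass `antialias = NULL` to decimate raw samples.
#'
#' @param x Numeric series sampled at `rate_in`.
#' @param rate_in,rate_out Source and target rates in Hz; `rate_in` must be
#'   an integer multiple of `rate_out`.
#' @param antialias A [filter_spec()] applied before decimation, or `NULL`.
#' @return Numeric series of length `ceiling(length(x) / k)`.
#' @examples
#' downsample_force(c(1, 2, 3, 4), 1000, 500, antialias = NULL)  # 1, 3
#' @export
downsample_force <- function(x, rate_in, rate_out, antialias = NULL) {
  stopifnot_scalar_pos(rate_in, "rate_in")
  stopifnot_scalar_pos(rate_out, "rate_out")
  k <- rate_in / rate_out
  if (abs(k - round(k)) > 1e-9) {
    abort(sprintf("rate_in (%g) must be an integer multiple of rate_out (%g).",
                  rate_in, rate_out))
  }
  k <- as.integer(round(k))
  if (!is.null(antialias)) x <- zero_lag_butterworth(x, rate_in, antialias)
  x[seq(1, length(x), by = k)]
}

#' Acceleration by second-order finite differences
#'
#' Interior frames use the central stencil
#' `a_i = (x[i+1] - 2 x[i] + x[i-1]) * rate^2`; the end frames use one-sided
#' second-order stencils. The scheme is exact for quadratic trajectories.
#'
#' @param x Position series (m), uniformly sampled.
#' @param rate Sampling rate (Hz).
#' @return Acceleration series (m/s^2), same length as `x`.
#' @export
finite_diff_accel <- function(x, rate) {
  n <- length(x)
  if (n < 3) abort("Need at least 3 samples for second differences.")
  stopifnot_scalar_pos(rate, "rate")
  a <- numeric(n)
  i <- 2:(n - 1)
  a[i] <- (x[i + 1] - 2 * x[i] + x[i - 1]) * rate^2
  if (n >= 4) {
    a[1] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) * rate^2
    a[n] <- (2 * x[n] - 5 * x[n - 1] + 4 * x[n - 2] - x[n - 3]) * rate^2
  } else {
    a[1] <- a[2]
    a[n] <- a[2]
  }
  a
}

#' Velocity by central differences
#'
#' First derivative companion to [finite_diff_accel()]: central differences
#' inside, one-sided second-order stencils at the ends. Exact on quadratics.
#'
#' @inheritParams finite_diff_accel
#' @return Velocity series (m/s), same length as `x`.
#' @export
finite_diff_velocity <- function(x, rate) {
  n <- length(x)
  if (n < 3) abort("Need at least 3 samples for central differences.")
  v <- numeric(n)
  i <- 2:(n - 1)
  v[i] <- (x[i + 1] - x[i - 1]) * rate / 2
  v[1] <- (-3 * x[1] + 4 * x[2] - x[3]) * rate / 2
  v[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) * rate / 2
  v
}

#' Detect support (stance) phases from vertical ground reaction force
#'
#' A stance phase is a maximal run of frames with `fz >= threshold`; runs
#' shorter than `min_duration` are discarded as force-plate chatter. The
#' returned intervals are half-open frame ranges `[start_frame, end_frame)`,
#' disjoint and sorted.
#'
#' @param fz Vertical GRF series (N).
#' @param rate Sampling rate (Hz).
#' @param threshold Contact threshold (N), default 20.
#' @param min_duration Minimum stance duration (s), default 0.05.
#' @return A tibble with columns `start_frame`, `end_frame`, `n_frames`,
#'   `duration`, `threshold`. Zero rows when no stance is found.
#' @export
detect_stance <- function(fz, rate, threshold = 20, min_duration = 0.05) {
  if (anyNA(fz) || !all(is.finite(fz))) abort("`fz` must be finite.")
  stopifnot_scalar_pos(threshold, "threshold")
  stopifnot_scalar_pos(rate, "rate")
  on <- fz >= threshold
  if (!any(on)) {
    return(tibble(start_frame = integer(), end_frame = integer(),
                  n_frames = integer(), duration = numeric(),
                  threshold = numeric()))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rate >= min_duration)
  tibble(
    start_frame = starts[keep],
    end_frame = ends[keep] + 1L,          # half-open
    n_frames = r$lengths[keep],
    duration = (r$lengths[keep] - 1L) / rate,
    threshold = threshold
  )
}

#' Trapezoid-rule integral over a stance window
#'
#' Composite trapezoid rule over the frames of a half-open stance window
#' (or the whole series when `window` is `NULL`). Linear in `y`.
#'
#' @param y Integrand series.
#' @param rate Sampling rate (Hz).
#' @param window Either `NULL`, a one-row tibble from [detect_stance()], or
#'   an integer vector `c(start_frame, end_frame)` (half-open).
#' @return The integral (units of `y` times seconds).
#' @export
trapz_integral <- function(y, rate, window = NULL) {
  stopifnot_scalar_pos(rate, "rate")
  idx <- window_frames(window, length(y))
  yw <- y[idx]
  if (length(yw) < 2) return(0)
  pracma::trapz(seq_along(yw) / rate, yw)
}

# Resolve a stance window to frame indices; errors when out of bounds.
window_frames <- function(window, n) {
  if (is.null(window)) return(seq_len(n))
  if (is.data.frame(window)) {
    if (nrow(window) != 1) abort("`window` must be a single stance interval.")
    s <- window$start_frame
    e <- window$end_frame
  } else {
    s <- window[1]
    e <- window[2]
  }
  if (s < 1 || e > n + 1 || e <= s) {
    abort(sprintf("Stance window [%d, %d) is out of bounds for a series of length %d.",
                  s, e, n))
  }
  seq.int(s, e - 1L)
}
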