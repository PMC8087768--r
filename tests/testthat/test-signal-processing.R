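test_that("zero-lag filter has unit DC gain and zero phase shift", {
  spec <- filter_spec(4, 6)
  x <- rep(3.7, 120)
  expect_equal(zero_lag_butterworth(x, 500, spec), x, tolerance = 1e-10)

  # symmetric pulse keeps its peak frame
  pulse <- c(rep(0, 150), dnorm(seq(-3, 3, length.out = 101)), rep(0, 150))
  y <- zero_lag_butterworth(pulse, 500, spec)
  expect_equal(which.max(y), which.max(pulse))
})

test_that("(4th order, 6 Hz) separates 1 Hz from 50 Hz at 500 Hz", {
  t <- seq(0, 2, by = 1 / 500)
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 50 * t)
  y <- zero_lag_butterworth(x, 500, filter_spec(4, 6))
  amp <- function(s, f) 2 * abs(mean(s * exp(-2i * pi * f * t)))
  expect_lt(20 * log10(amp(y, 50)), -40)          # stopband: > 40 dB down
  expect_lt(abs(amp(y, 1) - 1), 0.02)             # passband within 2%
})

test_that("filter is linear (superposition) on random series pairs", {
  spec <- filter_spec(4, 6)
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(200); y <- rnorm(200)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    lhs <- zero_lag_butterworth(a * x + b * y, 500, spec)
    rhs <- a * zero_lag_butterworth(x, 500, spec) +
      b * zero_lag_butterworth(y, 500, spec)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("filter rejects too-short and non-finite input", {
  expect_error(zero_lag_butterworth(rnorm(5), 500, filter_spec(4, 6)), "too short")
  expect_error(zero_lag_butterworth(c(rnorm(50), NA), 500, filter_spec(4, 6)), "finite")
  expect_error(filter_spec(3, 6), "even")
  expect_error(zero_lag_butterworth(rnorm(100), 10, filter_spec(4, 6)), "Nyquist")
})

test_that("force downsampling decimates onto kinematic frames", {
  expect_equal(downsample_force(c(1, 2, 3, 4), 1000, 500, antialias = NULL), c(1, 3))
  x <- rep(2.5, 101)
  expect_equal(downsample_force(x, 1000, 500, antialias = filter_spec(4, 100)),
               rep(2.5, 51), tolerance = 1e-9)
  expect_error(downsample_force(1:10, 1000, 300), "integer multiple")

  # passband sinusoid survives the anti-alias filter + decimation
  t <- seq(0, 1, by = 1e-3)
  x <- sin(2 * pi * 30 * t)
  y <- downsample_force(x, 1000, 500, antialias = filter_spec(4, 100))
  t2 <- t[seq(1, length(t), 2)]
  amp <- 2 * abs(mean(y * exp(-2i * pi * 30 * t2)))
  expect_lt(abs(amp - 1), 0.05)
})

test_that("second differences are exact on quadratics and accurate on sinusoids", {
  set.seed(7)
  t <- seq(0, 1, by = 1 / 500)
  for (i in 1:5) {
    cf <- rnorm(3)
    x <- cf[1] + cf[2] * t + cf[3] * t^2
    expect_equal(finite_diff_accel(x, 500), rep(2 * cf[3], length(t)),
                 tolerance = 1e-6)
    v <- finite_diff_velocity(x, 500)
    expect_equal(v, cf[2] + 2 * cf[3] * t, tolerance = 1e-6)
  }
  x <- sin(2 * pi * t)
  a <- finite_diff_accel(x, 500)
  expect_lt(max(abs(a - (-4 * pi^2 * sin(2 * pi * t)))), 1e-3)
  expect_error(finite_diff_accel(c(1, 2), 500), "3 samples")
})

test_that("stance detection finds maximal supra-threshold runs", {
  expect_equal(nrow(detect_stance(rep(0, 1000), 1000)), 0)

  t <- seq(0, 0.3, by = 1e-3)
  lobe <- 800 * sin(pi * t / 0.3)^2
  s <- detect_stance(c(rep(0, 100), lobe, rep(0, 100)), 1000, threshold = 20)
  expect_equal(nrow(s), 1)
  # interval is half-open and supra-threshold strictly inside
  fz <- c(rep(0, 100), lobe, rep(0, 100))
  inside <- fz[s$start_frame:(s$end_frame - 1)]
  expect_true(all(inside >= 20))
  expect_lt(fz[s$start_frame - 1], 20)
  expect_lt(fz[s$end_frame], 20)

  # two lobes separated by a flight phase -> two disjoint sorted intervals
  two <- c(rep(0, 50), lobe, rep(0, 200), lobe, rep(0, 50))
  s2 <- detect_stance(two, 1000, threshold = 20)
  expect_equal(nrow(s2), 2)
  expect_true(s2$end_frame[1] <= s2$start_frame[2])

  # sub-50 ms chatter is discarded
  blip <- c(rep(0, 100), rep(100, 20), rep(0, 100))
  expect_equal(nrow(detect_stance(blip, 1000, threshold = 20)), 0)
})

test_that("trapezoid integration matches closed forms", {
  expect_equal(trapz_integral(rep(10, 251), 500), 5)            # 10 N x 0.5 s
  y <- sin(seq(-1, 1, length.out = 201))                        # antisymmetric
  expect_equal(trapz_integral(y, 100), 0, tolerance = 1e-12)
  # half-sine of peak P over duration T integrates to 2PT/pi
  Td <- 0.4; P <- 1200
  t <- seq(0, Td, by = 1 / 2000)
  expect_equal(trapz_integral(P * sin(pi * t / Td), 2000), 2 * P * Td / pi,
               tolerance = 1e-3 * 2 * P * Td / pi)
  expect_error(trapz_integral(1:10, 100, c(5, 15)), "out of bounds")
})
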