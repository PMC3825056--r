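test_that("discrete Hilbert transform of a cosine is the sine", {
  rate <- 1000; f <- 50; n <- 400          # integer number of periods
  x <- cos(2 * pi * f * (0:(n - 1)) / rate)
  a <- analytic_signal(hl_signal(x, rate))
  expect_equal(a$real_part, x, tolerance = 1e-12)
  expect_lt(max(abs(a$imag_part - sin(2 * pi * f * (0:(n - 1)) / rate))),
            1e-10)
})

test_that("constant signal has no quadrature component", {
  a <- analytic_signal(hl_signal(rep(2.5, 64), 100))
  expect_lt(max(abs(a$imag_part)), 1e-12)
  expect_error(analytic_signal(hl_signal(1, 100)), "at least 2")
})

test_that("analytic signal matches the literal DFT oracle for odd and even lengths", {
  set.seed(21)
  for (R in c(8L, 9L, 32L, 33L)) {
    x <- rnorm(R)
    a <- analytic_signal(hl_signal(x, 100))
    z <- oracle_analytic(x)
    expect_lt(max(abs(a$real_part - Re(z))), 1e-10)
    expect_lt(max(abs(a$imag_part - Im(z))), 1e-10)
  }
})

test_that("envelope of a tone equals its amplitude; zero maps to zero", {
  rate <- 8000; n <- 8000
  for (A in c(1, 0.3)) {
    e <- hilbert_envelope(make_tone(100, rate, n, amp = A))
    expect_lt(max(abs(e$values - A)), 1e-6 * A)
  }
  e0 <- hilbert_envelope(hl_signal(numeric(100), 100))
  expect_true(all(e0$values == 0))
})

test_that("envelope tracks amplitude modulation", {
  rate <- 8000; n <- 4 * rate
  t <- (0:(n - 1)) / rate
  am <- 1 + 0.5 * cos(2 * pi * 2 * t)      # f_m = 2 Hz << f_c = 500 Hz
  x <- am * cos(2 * pi * 500 * t)
  e <- hilbert_envelope(hl_signal(x, rate))
  interior <- 4000:(n - 4000)
  expect_lt(max(abs(e$values[interior] - am[interior]) / am[interior]), 0.02)
})

test_that("instantaneous phase is arctan2 and unwraps linearly for a tone", {
  a <- structure(list(real_part = c(1, 0), imag_part = c(0, 1),
                      rate = 1, n = 2L), class = "hl_analytic")
  expect_equal(instantaneous_phase(a), c(0, pi / 2))

  rate <- 1000; f <- 40; n <- 500
  tone <- make_tone(f, rate, n)
  ph <- instantaneous_phase(analytic_signal(tone))
  expect_true(all(ph > -pi & ph <= pi))
  unwrapped <- ph + 2 * pi * cumsum(c(0, diff(ph) < -pi))
  interior <- 50:450
  fit <- lm(unwrapped[interior] ~ interior)
  expect_equal(unname(coef(fit)[2]), 2 * pi * f / rate, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("smoothing passes slow structure and kills fast ripple per its response", {
  rate <- 2000; n <- 3 * rate
  t <- (0:(n - 1)) / rate
  bump <- 1.5 + sin(2 * pi * 2 * t)
  ripple <- 0.2 * sin(2 * pi * 100 * t)
  env <- structure(list(values = bump + ripple, rate = rate, n = n,
                        smoothed = FALSE), class = "hl_envelope")
  sm <- smooth_envelope(env, cutoff_hz = 15)
  interior <- 1000:(n - 1000)
  resid_ripple <- sm$values[interior] - bump[interior] *
    Mod(sos_response(butter_lowpass(5, 15, rate), 2, zerophase = TRUE))
  # ripple RMS cut by >= 95 %
  expect_lt(sqrt(mean(resid_ripple^2)) / sqrt(mean(ripple[interior]^2)), 0.05)
  # 2 Hz bump amplitude preserved within 5 %
  expect_equal(max(sm$values[interior]), max(bump), tolerance = 0.05)

  const <- structure(list(values = rep(3, 500), rate = 500, n = 500L,
                          smoothed = FALSE), class = "hl_envelope")
  smc <- smooth_envelope(const, cutoff_hz = 15)
  expect_lt(max(abs(smc$values - 3)), 1e-6)
  expect_true(smc$smoothed)
  expect_error(smooth_envelope(smc), "already smoothed")
  expect_true(all(sm$values >= 0))
})

test_that("envelope dominance and Parseval consistency hold", {
  set.seed(33)
  # dominance on random signals
  for (i in 1:5) {
    x <- rnorm(257)
    e <- hilbert_envelope(hl_signal(x, 100))
    expect_true(all(e$values >= abs(x) - 1e-12))
  }
  # sum(env^2) ~ 2 sum(x^2) for a zero-mean band-limited tone
  tone <- make_tone(100, 8000, 8000)
  e <- hilbert_envelope(tone)
  expect_equal(sum(e$values^2) / (2 * sum(tone$samples^2)), 1,
               tolerance = 0.01)
})

test_that("even and odd record lengths agree for a tapered tone", {
  # taper the ends so neither record length has a circular discontinuity
  # (a raw truncated tone leaks spectrally at BOTH lengths, so agreement
  # would measure leakage, not the even/odd Nyquist-bin handling)
  rate <- 8000
  tukey <- function(n, frac = 0.25) {
    w <- rep(1, n); L <- floor(frac * n / 2)
    ramp <- 0.5 * (1 - cos(pi * (0:(L - 1)) / L))
    w[1:L] <- ramp; w[(n - L + 1):n] <- rev(ramp); w
  }
  x1 <- cos(2 * pi * 100 * (0:4095) / rate) * tukey(4096)
  x2 <- cos(2 * pi * 100 * (0:4096) / rate) * tukey(4097)
  e1 <- hilbert_envelope(hl_signal(x1, rate))$values
  e2 <- hilbert_envelope(hl_signal(x2, rate))$values
  interior <- 1500:2600
  expect_lt(max(abs(e1[interior] - e2[interior])), 1e-6)
})
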