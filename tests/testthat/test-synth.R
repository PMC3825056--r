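test_that("heart-sound generator emits the expected labelled segments", {
  hs <- synth_heart_sound(heart_sound_spec(duration = 4), seed = 1)
  expect_equal(nrow(hs$truth), 10L)                 # 5 cycles x {S1, S2}
  expect_setequal(unique(hs$labels), c("S1", "S2"))

  hs3 <- synth_heart_sound(
    heart_sound_spec(duration = 4, components = c("S1", "S2", "S3")),
    seed = 1)
  expect_equal(nrow(hs3$truth), 15L)
  expect_equal(sum(hs3$labels == "S3"), 5L)

  # deterministic per seed, different across seeds
  again <- synth_heart_sound(heart_sound_spec(duration = 4), seed = 1)
  expect_identical(hs$signal$samples, again$signal$samples)
  other <- synth_heart_sound(heart_sound_spec(duration = 4), seed = 2)
  expect_false(identical(hs$signal$samples, other$signal$samples))
})

test_that("S1 spectral centroid sits in the cardiac 20-150 Hz band", {
  hs <- synth_heart_sound(heart_sound_spec(duration = 4), seed = 3)
  s1 <- hs$truth[hs$labels == "S1", ][1, ]
  seg <- hs$signal$samples[s1$start:(s1$end - 1)]
  spec <- Mod(fft(seg))^2
  freqs <- (seq_along(spec) - 1) * hs$signal$rate / length(spec)
  half <- freqs <= hs$signal$rate / 2
  centroid <- sum(freqs[half] * spec[half]) / sum(spec[half])
  expect_gt(centroid, 20); expect_lt(centroid, 150)
})

test_that("lung sound is low-frequency dominated, band-limited and stochastic", {
  ls <- synth_lung_sound(duration = 6, seed = 5)
  spec <- Mod(fft(ls$samples))^2
  n <- length(spec)
  freqs <- (seq_len(n) - 1) * ls$rate / n
  half <- freqs <= ls$rate / 2
  frac_below_200 <- sum(spec[half & freqs < 200]) / sum(spec[half])
  expect_gte(frac_below_200, 0.60)
  frac_above_1800 <- sum(spec[half & freqs > 1800]) / sum(spec[half])
  expect_lt(frac_above_1800, 0.01)

  ls2 <- synth_lung_sound(duration = 6, seed = 6)
  expect_false(identical(ls$samples, ls2$samples))
  expect_error(synth_lung_sound(duration = 2, breath_period_s = 4),
               "breath")

  # abnormal variant carries a tonal wheeze near 400 Hz
  lsa <- synth_lung_sound(duration = 6, abnormal = TRUE, seed = 5)
  speca <- Mod(fft(lsa$samples))^2
  band <- function(s, lo, hi) sum(s[half & freqs >= lo & freqs <= hi])
  expect_gt(band(speca, 380, 420) / band(speca, 300, 360),
            band(spec, 380, 420) / band(spec, 300, 360))
})

test_that("convolutive mixing honors the norm contracts", {
  hs <- synth_heart_sound(heart_sound_spec(duration = 4), seed = 8)
  ls <- synth_lung_sound(duration = 4, breath_period_s = 4, seed = 9)

  mx <- convolutive_mix(hs$signal, ls,
                        mixture_spec("medium", "normal-normal", seed = 10))
  expect_equal(sqrt(sum(mx$b^2)), 1, tolerance = 1e-12)
  expect_gte(mx$a_norm, 0.81); expect_lte(mx$a_norm, 3.10)
  expect_equal(sqrt(sum(mx$a^2)), mx$a_norm, tolerance = 1e-12)

  # identity taps reduce mixing to plain addition
  mi <- convolutive_mix(hs$signal, ls,
                        mixture_spec("low", "normal-normal", seed = 11),
                        a_taps = c(1, 0, 0, 0), b_taps = c(1, 0, 0, 0))
  expect_equal(mi$signal$samples, hs$signal$samples + ls$samples)

  short <- hl_signal(rnorm(100), 8000)
  expect_error(convolutive_mix(hs$signal, short,
                               mixture_spec("low", "normal-normal")),
               "equal length")
  expect_error(mixture_spec("medium", "normal-normal", a_norm = 5),
               "outside")
  expect_error(flow_norm_range("normal-normal", "torrential"))
})

test_that("table of norm ranges matches the flow strata and orders them", {
  expect_equal(flow_norm_range("normal-normal", "low"), c(0.10, 0.80))
  expect_equal(flow_norm_range("normal-normal", "medium"), c(0.81, 3.10))
  expect_equal(flow_norm_range("normal-abnormal", "medium"), c(0.91, 3.30))
  expect_equal(flow_norm_range("abnormal-normal", "low"), c(0.10, 1.58))
  expect_equal(flow_norm_range("abnormal-abnormal", "high"), c(3.35, 6.70))
  for (mt in c("normal-normal", "normal-abnormal",
               "abnormal-normal", "abnormal-abnormal")) {
    lo <- flow_norm_range(mt, "low"); md <- flow_norm_range(mt, "medium")
    hi <- flow_norm_range(mt, "high")
    expect_lte(lo[2], md[1] + 0.01); expect_lte(md[2], hi[1] + 0.01)
  }
})

test_that("lung-to-heart power ratio grows with flow and truth passes through mixing", {
  ratios <- sapply(c("low", "medium", "high"), function(fl) {
    mean(sapply(1:5, function(s) {
      mix <- synth_mixture(fl, "normal-normal", duration = 6, seed = s)
      ls_part <- mix$signal$samples -
        stats::filter(c(0, 0, 0, mix$hs$samples), mix$b,
                      method = "convolution", sides = 1)[4:(mix$signal$n + 3)]
      sum(ls_part^2) / sum((mix$signal$samples - ls_part)^2)
    }))
  })
  expect_true(all(diff(ratios) > 0))

  mix <- synth_mixture("high", "abnormal-abnormal", duration = 6, seed = 4)
  expect_s3_class(mix$truth, "hl_segments")
  expect_equal(nrow(mix$truth), length(mix$labels))
  expect_true(all(diff(mix$truth$start) > 0))
  expect_setequal(unique(mix$labels), c("S1", "S2", "S3", "S4"))

  # end-to-end reproducibility of the convenience wrapper
  m1 <- synth_mixture("medium", "normal-abnormal", duration = 6, seed = 12)
  m2 <- synth_mixture("medium", "normal-abnormal", duration = 6, seed = 12)
  expect_identical(m1$signal$samples, m2$signal$samples)
})

test_that("truth CSV round-trips", {
  mix <- synth_mixture("low", "normal-normal", duration = 6, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(mix$truth, mix$labels, tmp)
  back <- read_truth_csv(tmp, n = mix$signal$n)
  expect_equal(back$truth$start, mix$truth$start)
  expect_equal(back$truth$end, mix$truth$end)
  expect_equal(back$labels, mix$labels)
})
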