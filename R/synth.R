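# Synthetic cardiopulmonary sounds and convolutive mixtures with exact
# ground-truth labels. The generator stands in for recorded data: heart
# sounds are amplitude-windowed tone bursts with physiological timing and
# spectra (S1/S2 in every cycle; S3/S4 and a systolic murmur in the
# "abnormal" variant), lung sounds are breathing-modulated shaped noise,
# and mixing follows the convolutive model: random 4-tap FIR filters with
# the heart-path norm fixed at 1 and the lung-path norm drawn from the
# flow-rate table.

# evaluate code under a given seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

# per-cycle component timing (seconds within one 0.8 s cycle) and tone
# parameters; S4 precedes S1, S3 follows S2, all inside the cardiac band
hs_component_table <- function(cycle_s = 0.8) {
  sc <- cycle_s / 0.8      # stretch timing proportionally for other rates
  data.frame(
    name  = c("S4", "S1", "S2", "S3"),
    onset = c(0.02, 0.10, 0.42, 0.55) * sc,
    dur   = c(0.060, 0.120, 0.090, 0.070),
    freq  = c(40, 60, 85, 35),
    amp   = c(0.30, 1.00, 0.75, 0.35),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic heart-sound signal
#'
#' @param rate Sampling rate in Hz (default 8000).
#' @param duration Record length in seconds.
#' @param cycle_s Cardiac period in seconds (default 0.8, i.e. 75 bpm).
#' @param components Subset of `c("S1","S2","S3","S4")`.
#' @param murmur If `TRUE`, add a band-limited (200--600 Hz) systolic
#'   murmur burst between S1 and S2 in every cycle (pathological case;
#'   not part of the ground truth, which labels S1--S4 only).
#' @return Object of class `hl_hs_spec`.
#' @export
heart_sound_spec <- function(rate = 8000, duration = 6, cycle_s = 0.8,
                             components = c("S1", "S2"), murmur = FALSE) {
  components <- match.arg(components, c("S1", "S2", "S3", "S4"),
                          several.ok = TRUE)
  tab <- hs_component_table(cycle_s)
  tab <- tab[tab$name %in% components, , drop = FALSE]
  if (any(tab$onset + tab$dur >= cycle_s))
    stop("component extends beyond the cardiac cycle", call. = FALSE)
  o <- order(tab$onset)
  if (any(diff(c(rbind(tab$onset[o], tab$onset[o] + tab$dur[o]))) < 0))
    stop("components overlap within a cycle", call. = FALSE)
  structure(list(rate = rate, duration = duration, cycle_s = cycle_s,
                 components = tab, murmur = murmur),
            class = "hl_hs_spec")
}

#' Synthesize a heart-sound signal with ground truth
#'
#' Each component instance is a Hann-windowed sinusoid at its center
#' frequency (S1 60 Hz / 120 ms, S2 85 Hz / 90 ms, S3 35 Hz / 70 ms, S4
#' 40 Hz / 60 ms by default -- all inside the 20--150 Hz cardiac band),
#' placed once per cycle with a random phase and a mild (+/-10%)
#' amplitude jitter. The waveform is peak-normalized to 1. Ground truth
#' marks each instance's nominal support `[onset, onset + dur)`.
#'
#' @param spec An [heart_sound_spec()].
#' @param seed Integer seed (deterministic output per seed).
#' @return List with `signal` (an [hl_signal()]), `truth` (an
#'   [hl_segments()] of true component extents) and `labels` (parallel
#'   component names).
#' @export
synth_heart_sound <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "hl_hs_spec"))
  with_seed(seed, {
    rate <- spec$rate
    n <- round(spec$duration * rate)
    x <- numeric(n)
    n_cycles <- floor(spec$duration / spec$cycle_s)
    starts <- integer(0); ends <- integer(0); labels <- character(0)
    for (cy in seq_len(n_cycles)) {
      t0_cycle <- (cy - 1) * spec$cycle_s
      for (r in seq_len(nrow(spec$components))) {
        comp <- spec$components[r, ]
        t0 <- t0_cycle + comp$onset
        i0 <- floor(t0 * rate) + 1L
        L <- round(comp$dur * rate)
        if (i0 + L - 1L > n) next
        k <- seq_len(L) - 1L
        w <- 0.5 * (1 - cos(2 * pi * k / (L - 1)))
        ph <- stats::runif(1, 0, 2 * pi)
        aj <- comp$amp * stats::runif(1, 0.9, 1.1)
        x[i0:(i0 + L - 1L)] <- x[i0:(i0 + L - 1L)] +
          aj * w * sin(2 * pi * comp$freq * k / rate + ph)
        starts <- c(starts, i0); ends <- c(ends, i0 + L)
        labels <- c(labels, comp$name)
      }
      if (spec$murmur) {
        tab <- hs_component_table(spec$cycle_s)
        s1 <- tab[tab$name == "S1", ]; s2 <- tab[tab$name == "S2", ]
        m0 <- t0_cycle + s1$onset + s1$dur + 0.02
        mdur <- max(0.05, s2$onset - s1$onset - s1$dur - 0.04)
        i0 <- floor(m0 * rate) + 1L
        L <- round(mdur * rate)
        if (i0 + L - 1L <= n && L > 8L) {
          noise <- stats::rnorm(L)
          bp <- sos_filtfilt(butter_lowpass(3, 600, rate), noise) -
                sos_filtfilt(butter_lowpass(3, 200, rate), noise)
          k <- seq_len(L) - 1L
          w <- 0.5 * (1 - cos(2 * pi * k / (L - 1)))
          bp <- bp / max(abs(bp))
          x[i0:(i0 + L - 1L)] <- x[i0:(i0 + L - 1L)] + 0.25 * w * bp
        }
      }
    }
    M <- max(abs(x))
    if (M > 0) x <- x / M
    ordr <- order(starts)
    list(signal = hl_signal(x, rate),
         truth = hl_segments(start = starts[ordr], end = ends[ordr],
                             peak = (starts[ordr] + ends[ordr]) %/% 2L,
                             area = rep(NA_real_, length(starts)), n = n),
         labels = labels[ordr])
  })
}

#' Synthesize a lung-sound signal
#'
#' Gaussian noise shaped to the respiratory band (high-pass 20 Hz,
#' low-pass 200 Hz with a gentle 2nd-order roll-off extending energy
#' toward 1600 Hz, so most energy sits below 200 Hz), amplitude-modulated
#' by a breathing envelope of period `breath_period_s`. The abnormal
#' variant adds a wheeze-like 400 Hz tone gated to expiration. Output is
#' peak-normalized to 1.
#'
#' @param rate Sampling rate (Hz).
#' @param duration Length in seconds (>= one breath period).
#' @param breath_period_s Breathing period (default 4 s, 15 breaths/min).
#' @param abnormal Add wheeze if `TRUE`.
#' @param seed Integer seed.
#' @return An [hl_signal()].
#' @export
synth_lung_sound <- function(rate = 8000, duration = 6,
                             breath_period_s = 4, abnormal = FALSE,
                             seed = NULL) {
  if (duration < breath_period_s)
    stop("duration must cover at least one breath period", call. = FALSE)
  with_seed(seed, {
    n <- round(duration * rate)
    t <- (seq_len(n) - 1) / rate
    noise <- stats::rnorm(n)
    shaped <- sos_filtfilt(butter_lowpass(2, 200, rate), noise)
    hp <- sos_filtfilt(butter_lowpass(2, 20, rate), shaped)
    shaped <- shaped - hp
    m <- 0.2 + 0.8 * sin(pi * t / breath_period_s)^2
    x <- shaped * m
    if (abnormal) {
      gate <- pmax(0, -sin(2 * pi * t / breath_period_s))
      x <- x + 0.3 * stats::sd(shaped) * gate *
        sin(2 * pi * 400 * t + stats::runif(1, 0, 2 * pi))
    }
    hl_signal(x / max(abs(x)), rate)
  })
}

#' Table of lung-path filter-norm ranges by mixture type and flow
#'
#' The empirical flow-rate strata: the norm of the 4-tap lung-sound
#' filter vector controls the lung-to-heart amplitude ratio. `"high"`
#' cells are open-ended above; draws use `(L, 2L]`.
#'
#' @param mixture_type One of `"normal-normal"`, `"normal-abnormal"`,
#'   `"abnormal-normal"`, `"abnormal-abnormal"` (lung type - heart type).
#' @param flow One of `"low"`, `"medium"`, `"high"`.
#' @return Numeric `c(lo, hi)` range for the norm.
#' @export
flow_norm_range <- function(mixture_type, flow) {
  mixture_type <- match.arg(mixture_type,
    c("normal-normal", "normal-abnormal",
      "abnormal-normal", "abnormal-abnormal"))
  flow <- match.arg(flow, c("low", "medium", "high"))
  ranges <- list(
    "normal-normal"     = list(low = c(0.10, 0.80),
                               medium = c(0.81, 3.10), high = c(3.10, 6.20)),
    "normal-abnormal"   = list(low = c(0.10, 0.90),
                               medium = c(0.91, 3.30), high = c(3.30, 6.60)),
    "abnormal-normal"   = list(low = c(0.10, 1.58),
                               medium = c(1.59, 3.28), high = c(3.28, 6.56)),
    "abnormal-abnormal" = list(low = c(0.10, 1.96),
                               medium = c(1.97, 3.35), high = c(3.35, 6.70)))
  ranges[[mixture_type]][[flow]]
}

#' Specification of a convolutive mixture
#'
#' @inheritParams flow_norm_range
#' @param seed Integer seed for the random filter taps.
#' @param a_norm Optional fixed norm for the lung-path filter; when
#'   `NULL` it is drawn uniformly from the flow cell's range. Supplied
#'   values must lie in that range.
#' @return Object of class `hl_mix_spec`.
#' @export
mixture_spec <- function(flow, mixture_type, seed = NULL, a_norm = NULL) {
  rng <- flow_norm_range(mixture_type, flow)
  if (!is.null(a_norm) && (a_norm < rng[1] || a_norm > rng[2]))
    stop("a_norm ", a_norm, " outside the [", rng[1], ", ", rng[2],
         "] range for ", mixture_type, " / ", flow, " flow", call. = FALSE)
  structure(list(flow = flow, mixture_type = mixture_type,
                 a_norm = a_norm, seed = seed),
            class = "hl_mix_spec")
}

# causal 4-tap FIR, output trimmed to input length
fir4 <- function(x, taps) {
  xp <- c(0, 0, 0, x)
  v <- stats::filter(xp, taps, method = "convolution", sides = 1)
  as.numeric(v)[4:(length(x) + 3L)]
}

#' Convolutive mixing of heart and lung sounds
#'
#' Draws two random 4-tap FIR filter vectors (standard normal taps): the
#' heart-path vector `b` is rescaled to unit norm and the lung-path
#' vector `a` to a norm drawn from the flow cell's range. The mixture is
#' `filter(ls, a) + filter(hs, b)`. Ground-truth labels pass through
#' unchanged (the <= 3-sample FIR group delay is absorbed by evaluation
#' tolerances).
#'
#' @param hs Heart-sound [hl_signal()] (e.g. from [synth_heart_sound()]).
#' @param ls Lung-sound [hl_signal()], same rate and length.
#' @param spec An [mixture_spec()].
#' @param a_taps,b_taps Optional fixed 4-tap vectors overriding the random
#'   draw (used verbatim, no rescaling); e.g. identity taps `c(1,0,0,0)`
#'   for both reduce mixing to plain addition.
#' @return List with `signal` (the mixture), `a`, `b` (tap vectors) and
#'   `a_norm` (the drawn/fixed lung-path norm).
#' @export
convolutive_mix <- function(hs, ls, spec, a_taps = NULL, b_taps = NULL) {
  stopifnot(inherits(spec, "hl_mix_spec"))
  hs <- as_hl_signal(hs); ls <- as_hl_signal(ls)
  if (hs$rate != ls$rate)
    stop("heart and lung signals must share a sampling rate", call. = FALSE)
  if (hs$n != ls$n)
    stop("heart and lung signals must have equal length", call. = FALSE)
  with_seed(spec$seed, {
    rng <- flow_norm_range(spec$mixture_type, spec$flow)
    a_norm <- if (is.null(spec$a_norm)) stats::runif(1, rng[1], rng[2])
              else spec$a_norm
    b <- if (is.null(b_taps)) { b <- stats::rnorm(4); b / sqrt(sum(b^2)) }
         else as.numeric(b_taps)
    a <- if (is.null(a_taps)) {
      a <- stats::rnorm(4); a / sqrt(sum(a^2)) * a_norm
    } else as.numeric(a_taps)
    if (!is.null(a_taps)) a_norm <- sqrt(sum(a^2))
    mix <- fir4(ls$samples, a) + fir4(hs$samples, b)
    list(signal = hl_signal(mix, hs$rate), a = a, b = b, a_norm = a_norm)
  })
}

#' One-call synthetic mixture with ground truth
#'
#' Convenience wrapper used by the test suites and the CLI: generates a
#' heart sound (normal: S1+S2; abnormal: S1--S4 plus murmur), a lung
#' sound (abnormal: wheeze), and mixes them convolutively at the
#' requested flow rate. All randomness derives from `seed`.
#'
#' @inheritParams flow_norm_range
#' @param duration Seconds (default 6).
#' @param rate Hz (default 8000).
#' @param cycle_s Cardiac period (default 0.8 s).
#' @param breath_period_s Breathing period (default 4 s).
#' @param seed Integer seed.
#' @return List with `signal`, `truth` (an [hl_segments()]), `labels`,
#'   `a`, `b`, `a_norm`, `hs`, `ls`.
#' @export
synth_mixture <- function(flow, mixture_type, duration = 6, rate = 8000,
                          cycle_s = 0.8, breath_period_s = 4,
                          seed = NULL) {
  mixture_type <- match.arg(mixture_type,
    c("normal-normal", "normal-abnormal",
      "abnormal-normal", "abnormal-abnormal"))
  parts <- strsplit(mixture_type, "-")[[1]]
  ls_abnormal <- parts[1] == "abnormal"
  hs_abnormal <- parts[2] == "abnormal"
  comps <- if (hs_abnormal) c("S1", "S2", "S3", "S4") else c("S1", "S2")
  hspec <- heart_sound_spec(rate = rate, duration = duration,
                            cycle_s = cycle_s, components = comps,
                            murmur = hs_abnormal)
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
           else as.list(seed * 3L + 0:2)
  hs <- synth_heart_sound(hspec, seed = seeds[[1]])
  ls <- synth_lung_sound(rate = rate, duration = duration,
                         breath_period_s = breath_period_s,
                         abnormal = ls_abnormal, seed = seeds[[2]])
  mx <- convolutive_mix(hs$signal, ls,
                        mixture_spec(flow, mixture_type, seed = seeds[[3]]))
  list(signal = mx$signal, truth = hs$truth, labels = hs$labels,
       a = mx$a, b = mx$b, a_norm = mx$a_norm,
       hs = hs$signal, ls = ls)
}

#' Write a ground-truth segment table as CSV
#'
#' Columns `start_sample,end_sample,label` (0-based, exclusive end).
#'
#' @param truth An `hl_segments`.
#' @param labels Parallel component labels.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_csv <- function(truth, labels, path) {
  utils::write.csv(data.frame(start_sample = truth$start - 1L,
                              end_sample = truth$end - 1L,
                              label = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth CSV
#'
#' @param path CSV with `start_sample,end_sample[,label]` (0-based).
#' @param n Record length in samples.
#' @return List with `truth` (an [hl_segments()]) and `labels`.
#' @export
read_truth_csv <- function(path, n) {
  df <- utils::read.csv(path)
  segs <- hl_segments(start = df$start_sample + 1L,
                      end = df$end_sample + 1L,
                      peak = df$start_sample + 1L,
                      area = rep(NA_real_, nrow(df)), n = n)
  labels <- if ("label" %in% names(df)) as.character(df$label)
            else rep(NA_character_, nrow(df))
  list(truth = segs, labels = labels)
}
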