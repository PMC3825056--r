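# Independent oracles used across the suite. These re-derive expected
# values by brute force or closed form and must stay independent of the
# package's own implementation paths.

# literal DFT-definition analytic signal: O(n^2) double loop, with the
# even/odd spectral weighting written out explicitly
oracle_analytic <- function(x) {
  R <- length(x)
  m <- 0:(R - 1)
  Y <- vapply(m, function(mm) {
    sum(x * exp(-2i * pi * mm * (0:(R - 1)) / R))
  }, complex(1))
  h <- numeric(R)
  if (R %% 2 == 0) {
    h[1] <- 1; h[R / 2 + 1] <- 1
    if (R > 2) h[2:(R / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((R + 1) / 2)] <- 2
  }
  Z <- Y * h
  vapply(0:(R - 1), function(nn) {
    sum(Z * exp(2i * pi * m * nn / R)) / R
  }, complex(1))
}

# polygon (shoelace) area from triangle vertices
oracle_shoelace <- function(v) {
  abs((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])) / 2
}

# two-pass population variance
oracle_variance <- function(x) {
  mu <- sum(x) / length(x)
  sum((x - mu)^2) / length(x)
}

# elementwise-loop confusion counts
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# all-window scan for extrema with the plateau rule: an interior run of
# equal values strictly above (below) both neighbours is one MAX (MIN) at
# the run's first sample
oracle_extrema <- function(v) {
  n <- length(v)
  idx <- integer(0); kind <- character(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (j <= n - 1L) {
      left <- v[i - 1L]; right <- v[j + 1L]
      if (v[i] > left && v[i] > right) {
        idx <- c(idx, i); kind <- c(kind, "MAX")
      } else if (v[i] < left && v[i] < right) {
        idx <- c(idx, i); kind <- c(kind, "MIN")
      }
    }
    i <- j + 1L
  }
  data.frame(index = idx, kind = kind, value = v[idx],
             stringsAsFactors = FALSE)
}

make_tone <- function(freq, rate, n, amp = 1, phase = 0) {
  hl_signal(amp * cos(2 * pi * freq * (0:(n - 1)) / rate + phase), rate)
}

# write a small stereo PCM16 WAV by hand (the package only writes mono)
write_stereo_wav <- function(left, right, rate, path) {
  ints <- as.integer(round(as.vector(rbind(left, right)) * 32767))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
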