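# Extrema detection on the smoothed envelope and assembly of candidate
# events as (minimum, maximum, minimum) triples. Indices are 1-based R
# sample positions throughout; the CSV writers convert to 0-based.

#' Locate alternating minima and maxima of a smoothed envelope
#'
#' Extrema are sign changes of the first difference: `-` to `+` is a
#' minimum, `+` to `-` a maximum. A flat run at a summit (or trough)
#' yields one extremum at the run's first sample. The record endpoints are
#' appended as boundary minima when needed so that every maximum has a
#' flanking minimum on both sides; a final pass collapses any same-kind
#' neighbours to the more extreme one so kinds strictly alternate.
#'
#' @param env An `hl_envelope` (smoothed) or numeric vector.
#' @return Object of class `hl_extrema`: data frame with columns `index`,
#'   `kind` (`"MIN"`/`"MAX"`) and `value`.
#' @export
find_extrema <- function(env) {
  v <- if (inherits(env, "hl_envelope")) env$values else as.numeric(env)
  n <- length(v)
  if (n < 3L)
    stop("envelope too short for extrema detection (need >= 3 samples)",
         call. = FALSE)
  d <- diff(v)
  idx <- integer(0); kind <- character(0)
  prev_sign <- 0; prev_pos <- 0L
  for (i in seq_along(d)) {
    s <- sign(d[i])
    if (s == 0) next
    if (prev_sign != 0 && s != prev_sign) {
      idx <- c(idx, prev_pos + 1L)                 # first sample of plateau
      kind <- c(kind, if (prev_sign > 0) "MAX" else "MIN")
    }
    prev_sign <- s
    prev_pos <- i
  }
  # boundary minima so every MAX is flanked
  if (length(idx) && kind[1] == "MAX") {
    idx <- c(1L, idx); kind <- c("MIN", kind)
  }
  if (length(idx) && kind[length(kind)] == "MAX") {
    idx <- c(idx, n); kind <- c(kind, "MIN")
  }
  ex <- data.frame(index = idx, kind = kind, value = v[idx],
                   stringsAsFactors = FALSE)
  ex <- collapse_same_kind(ex)
  class(ex) <- c("hl_extrema", "data.frame")
  ex
}

# enforce strict MIN/MAX alternation: runs of the same kind collapse to
# the single most extreme member (lowest MIN / highest MAX, first on ties)
collapse_same_kind <- function(ex) {
  if (nrow(ex) < 2L) return(ex)
  keep <- rep(TRUE, nrow(ex))
  i <- 1L
  while (i < nrow(ex)) {
    j <- i
    while (j < nrow(ex) && ex$kind[j + 1L] == ex$kind[i]) j <- j + 1L
    if (j > i) {
      run <- i:j
      best <- if (ex$kind[i] == "MAX") run[which.max(ex$value[run])]
              else run[which.min(ex$value[run])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j + 1L
  }
  ex <- ex[keep, , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

#' Assemble candidate peaks from an extrema sequence
#'
#' One candidate event per maximum: the triple (left minimum, maximum,
#' right minimum) of three consecutive extrema. Consecutive peaks share
#' their boundary minimum.
#'
#' @param extrema An `hl_extrema` from [find_extrema()].
#' @return Object of class `hl_peaks`: data frame with one row per peak,
#'   columns `left_idx`, `left_val`, `max_idx`, `max_val`, `right_idx`,
#'   `right_val`.
#' @export
form_peaks <- function(extrema) {
  stopifnot(inherits(extrema, "hl_extrema") || is.data.frame(extrema))
  maxima <- which(extrema$kind == "MAX")
  out <- data.frame(left_idx = integer(0), left_val = numeric(0),
                    max_idx = integer(0), max_val = numeric(0),
                    right_idx = integer(0), right_val = numeric(0))
  for (m in maxima) {
    if (m == 1L || m == nrow(extrema)) next   # unflanked (shouldn't occur)
    out[nrow(out) + 1L, ] <- list(
      extrema$index[m - 1L], extrema$value[m - 1L],
      extrema$index[m],      extrema$value[m],
      extrema$index[m + 1L], extrema$value[m + 1L])
  }
  class(out) <- c("hl_peaks", "data.frame")
  out
}
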