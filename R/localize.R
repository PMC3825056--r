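# Peak selection by adaptive variance thresholding of the Heron area
# vector, boundary estimation from flanking minima, and the end-to-end
# localization pipeline.

#' Construct a heart-sound segment set
#'
#' Ordered, non-overlapping half-open intervals `[start, end)` in 1-based
#' sample indices, each with the sample index of its event maximum and the
#' peak's Heron area (merged segments keep the largest member area and the
#' highest member peak).
#'
#' @param start,end Integer vectors, `start <= peak < end`.
#' @param peak Peak sample indices.
#' @param area Heron areas.
#' @param n Total record length in samples.
#' @return Object of class `hl_segments`: data frame with attribute `n`.
#' @export
hl_segments <- function(start = integer(0), end = integer(0),
                        peak = integer(0), area = numeric(0), n) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   peak = as.integer(peak), area = as.numeric(area))
  if (nrow(df)) {
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
    if (any(df$start < 1L) || any(df$end > n + 1L))
      stop("segments out of record range", call. = FALSE)
    if (any(df$end <= df$start))
      stop("segments must satisfy start < end", call. = FALSE)
    if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)]))
      stop("segments must not overlap", call. = FALSE)
    if (any(df$peak < df$start | df$peak >= df$end))
      stop("peak must lie inside its segment", call. = FALSE)
  }
  attr(df, "n") <- as.integer(n)
  class(df) <- c("hl_segments", "data.frame")
  df
}

#' @export
print.hl_segments <- function(x, ...) {
  cat(sprintf("<hl_segments> %d segment(s) over %d samples\n",
              nrow(x), attr(x, "n")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Adaptive threshold from the area vector
#'
#' The selection threshold is `scale` times the population (1/N) variance
#' of the Heron areas: loud cardiac events inflate the spread of the area
#' population, so the threshold adapts to the record.
#'
#' @param areas Numeric vector of peak areas (nonempty).
#' @param scale Positive multiplier (default 1).
#' @return Nonnegative threshold.
#' @export
adaptive_threshold <- function(areas, scale = 1.0) {
  areas <- as.numeric(areas)
  if (length(areas) == 0L)
    stop("cannot threshold an empty area vector", call. = FALSE)
  scale * mean((areas - mean(areas))^2)
}

#' Select heart-sound peaks by area
#'
#' Peak `i` is selected iff `areas[i] > threshold` (strict, so a
#' zero-variance all-equal area vector still selects positive-area
#' peaks).
#'
#' @param peaks An `hl_peaks` data frame.
#' @param areas Areas from [area_vector()], same length.
#' @param threshold Nonnegative threshold.
#' @return Integer indices of selected peaks, in order.
#' @export
select_hs_peaks <- function(peaks, areas, threshold) {
  if (nrow(peaks) != length(areas))
    stop("peaks and areas length mismatch", call. = FALSE)
  which(areas > threshold)
}

#' Boundaries of the selected peaks
#'
#' Each selected peak spans its flanking minima: `[left_idx,
#' right_idx + 1)`. Adjacent selected peaks that share a minimum merge
#' into one segment spanning both.
#'
#' @param peaks An `hl_peaks`.
#' @param selected Indices from [select_hs_peaks()].
#' @param areas Areas aligned with `peaks`.
#' @param n Record length in samples.
#' @return An [hl_segments()].
#' @export
estimate_boundaries <- function(peaks, selected, areas, n) {
  if (length(selected) == 0L) return(hl_segments(n = n))
  sel <- peaks[selected, , drop = FALSE]
  ar <- areas[selected]
  start <- sel$left_idx[1]; end <- sel$right_idx[1]
  pk <- sel$max_idx[1]; pa <- ar[1]
  out <- list()
  if (nrow(sel) > 1L) for (i in 2:nrow(sel)) {
    if (sel$left_idx[i] <= end) {        # shared minimum: merge
      end <- max(end, sel$right_idx[i])
      if (ar[i] > pa) { pa <- ar[i]; pk <- sel$max_idx[i] }
    } else {
      out[[length(out) + 1L]] <- c(start, end, pk, pa)
      start <- sel$left_idx[i]; end <- sel$right_idx[i]
      pk <- sel$max_idx[i]; pa <- ar[i]
    }
  }
  out[[length(out) + 1L]] <- c(start, end, pk, pa)
  m <- do.call(rbind, out)
  hl_segments(start = m[, 1], end = m[, 2] + 1L, peak = m[, 3],
              area = m[, 4], n = n)
}

#' Localize heart-sound components in a mixed recording
#'
#' The full pipeline: amplitude normalization, low-pass heart-sound
#' enhancement, Hilbert envelope, envelope smoothing, extrema/peak
#' detection, Heron-area scoring, adaptive variance thresholding and
#' boundary estimation. Deterministic for a fixed input and
#' configuration. An all-zero (silent) input yields an empty segment set.
#'
#' @param signal An [hl_signal()].
#' @param config An [run_config()] (defaults used when omitted).
#' @return An [hl_segments()] over the input record.
#' @examples
#' mix <- synth_mixture(flow = "low", mixture_type = "normal-normal",
#'                      duration = 6, seed = 1)
#' seg <- localize_hs(mix$signal)
#' nrow(seg)
#' @export
localize_hs <- function(signal, config = run_config()) {
  signal <- as_hl_signal(signal)
  stopifnot(inherits(config, "hl_config"))
  n <- signal$n
  if (all(signal$samples == 0)) return(hl_segments(n = n))
  min_len <- ceiling(3 * signal$rate / config$smooth_cutoff_hz)
  if (n < min_len)
    stop("signal too short for smoothing cutoff ", config$smooth_cutoff_hz,
         " Hz: need >= ", min_len, " samples, got ", n, call. = FALSE)

  norm <- normalize_amplitude(signal)
  filt <- lowpass_hs_enhance(norm, cutoff_hz = config$hs_filter_cutoff_hz,
                             order = config$hs_filter_order,
                             mode = config$filter_mode)
  env <- hilbert_envelope(filt)
  env <- smooth_envelope(env, cutoff_hz = config$smooth_cutoff_hz,
                         order = config$smooth_order,
                         mode = config$filter_mode)
  ex <- find_extrema(env)
  peaks <- form_peaks(ex)
  if (nrow(peaks) == 0L) return(hl_segments(n = n))
  xs <- if (is.null(config$x_scale)) 1 / signal$rate else config$x_scale
  areas <- area_vector(peaks, x_scale = xs, y_scale = config$y_scale)
  thr <- adaptive_threshold(areas, scale = config$threshold_scale)
  sel <- select_hs_peaks(peaks, areas, thr)
  estimate_boundaries(peaks, sel, areas, n)
}

#' Write a segment set as CSV
#'
#' Columns `start_sample,end_sample,start_sec,end_sec,peak_sample,area`.
#' Sample columns are 0-based with exclusive end, matching the half-open
#' convention; an empty set writes the header only.
#'
#' @param segs An `hl_segments`.
#' @param path Output path.
#' @param rate Sampling rate used for the seconds columns.
#' @return Invisibly, `path`.
#' @export
write_segments_csv <- function(segs, path, rate) {
  df <- data.frame(start_sample = segs$start - 1L,
                   end_sample = segs$end - 1L,
                   start_sec = (segs$start - 1L) / rate,
                   end_sec = (segs$end - 1L) / rate,
                   peak_sample = segs$peak - 1L,
                   area = segs$area)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a segment CSV back into an `hl_segments`
#'
#' Accepts the output of [write_segments_csv()] or any CSV with at least
#' `start_sample` and `end_sample` (0-based, exclusive end).
#'
#' @param path CSV path.
#' @param n Record length in samples.
#' @return An [hl_segments()].
#' @export
read_segments_csv <- function(path, n) {
  df <- utils::read.csv(path)
  if (!all(c("start_sample", "end_sample") %in% names(df)))
    stop("segment CSV needs start_sample and end_sample columns",
         call. = FALSE)
  pk <- if ("peak_sample" %in% names(df)) df$peak_sample + 1L
        else df$start_sample + 1L
  ar <- if ("area" %in% names(df)) df$area else rep(NA_real_, nrow(df))
  hl_segments(start = df$start_sample + 1L, end = df$end_sample + 1L,
              peak = pk, area = ar, n = n)
}
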