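# Scoring a candidate peak by the area of the scalene triangle joining
# its three extrema. The area separates cardiac events (tall, wide
# envelope bumps) from residual lung-sound bumps (short, narrow).

#' Triangle geometry of a candidate peak
#'
#' Vertices are the peak's extrema in (time, envelope) coordinates:
#' `(index * x_scale, value * y_scale)` for left minimum, maximum and
#' right minimum. Sides are Euclidean distances (`c` the base joining the
#' two minima, `a`/`b` the lateral sides) and the interior angles come
#' from the law of cosines. Collinear vertices are flagged degenerate,
#' not an error.
#'
#' @param peak One-row data frame (a row of an `hl_peaks`) or list with
#'   `left_idx`, `left_val`, `max_idx`, `max_val`, `right_idx`,
#'   `right_val`.
#' @param x_scale Horizontal units per sample (e.g. `1/rate` for
#'   seconds; default 1, sample units).
#' @param y_scale Vertical scale for envelope values (default 1).
#' @return Object of class `hl_triangle`: list with sides `a`, `b`, `c`,
#'   angles `alpha`, `beta`, `gamma` (radians, opposite `a`, `b`, `c`),
#'   `vertices` (3x2 matrix) and logical `degenerate`.
#' @export
triangle_from_peak <- function(peak, x_scale = 1, y_scale = 1) {
  p1 <- c(peak$left_idx  * x_scale, peak$left_val  * y_scale)
  p2 <- c(peak$max_idx   * x_scale, peak$max_val   * y_scale)
  p3 <- c(peak$right_idx * x_scale, peak$right_val * y_scale)
  d <- function(u, v) sqrt(sum((u - v)^2))
  a <- d(p1, p2)      # left lateral side
  b <- d(p2, p3)      # right lateral side
  cc <- d(p1, p3)     # base
  cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
           (p3[1] - p1[1]) * (p2[2] - p1[2])
  degenerate <- abs(cross) < 1e-12 * max(a, b, cc, 1)^2
  ang <- function(opp, s1, s2) {
    if (s1 == 0 || s2 == 0) return(NA_real_)
    acos(min(1, max(-1, (s1^2 + s2^2 - opp^2) / (2 * s1 * s2))))
  }
  structure(list(a = a, b = b, c = cc,
                 alpha = ang(a, b, cc), beta = ang(b, a, cc),
                 gamma = ang(cc, a, b),
                 vertices = rbind(p1, p2, p3, deparse.level = 0),
                 degenerate = degenerate),
            class = "hl_triangle")
}

#' Heron's formula for triangle area
#'
#' Two steps: semiperimeter `h = (u + v + w) / 2`, then
#' `area = sqrt(h (h - u) (h - v) (h - w))`. A negative radicand (floating
#' noise on near-degenerate triangles) clamps to 0.
#'
#' @param tri An `hl_triangle`, or a numeric vector of three side lengths.
#' @return Nonnegative area.
#' @export
heron_area_of <- function(tri) {
  s <- if (inherits(tri, "hl_triangle")) c(tri$a, tri$b, tri$c)
       else as.numeric(tri)
  stopifnot(length(s) == 3, all(is.finite(s)))
  h <- sum(s) / 2
  rad <- h * (h - s[1]) * (h - s[2]) * (h - s[3])
  sqrt(max(rad, 0))
}

#' Heron areas of a list of peaks
#'
#' @param peaks An `hl_peaks` data frame (temporal order).
#' @inheritParams triangle_from_peak
#' @return Numeric vector of nonnegative areas, one per peak, in order.
#' @export
area_vector <- function(peaks, x_scale = 1, y_scale = 1) {
  if (nrow(peaks) == 0L) return(numeric(0))
  vapply(seq_len(nrow(peaks)), function(i) {
    heron_area_of(triangle_from_peak(peaks[i, ], x_scale, y_scale))
  }, numeric(1))
}
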