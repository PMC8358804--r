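#' Spiral-bundle trace
#'
#' The ordered polyline drawn along the spiral bundle of a reconstructed
#' organ-of-Corti surface preparation, from apex to base, in image
#' coordinates (um, y down). Its arc length is the measured cochlear
#' length.
#'
#' @param points two-column matrix or data.frame of (x, y) um coordinates,
#'   ordered from apex to base, >= 2 rows, consecutive points distinct.
#' @return object of class `spiral_trace` with `points`, per-segment
#'   lengths `seg`, cumulative arc `arc`, and total `length` (um).
#' @export
spiral_trace <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2 || nrow(pts) < 2)
    stop_eq("`points` must be an n x 2 matrix with n >= 2")
  if (!all(is.finite(pts))) stop_eq("coordinates must be finite")
  seg <- sqrt(rowSums(diff(pts)^2))
  if (any(seg == 0)) stop_eq("consecutive trace points must be distinct")
  structure(list(points = pts, seg = seg, arc = c(0, cumsum(seg)),
                 length = sum(seg)),
            class = "spiral_trace")
}

#' Measured cochlear length of a trace
#'
#' Sum of Euclidean segment lengths of the spiral-bundle polyline.
#'
#' @param t a [spiral_trace()].
#' @return length in um.
#' @export
trace_length <- function(t) {
  if (!inherits(t, "spiral_trace")) stop_eq("`t` must be a `spiral_trace`")
  t$length
}

#' Greenwood-form cochlear place-frequency map
#'
#' Maps fractional position along the cochlea, measured from the apex
#' (x = 0, low frequency) to the base (x = 1, high frequency), to
#' characteristic frequency:
#' \deqn{F(x) = A (10^{a x} - k)}
#' The defaults span the rat audible range (about 0.5 kHz at the apex to
#' 55 kHz at the base) so that all six standard analysis frequencies (2.8,
#' 8, 11.3, 16, 32, 45.2 kHz) fall inside the cochlea; they are fitted
#' range anchors, not physiological constants, and every one is
#' configurable.
#'
#' @param A scale in kHz.
#' @param a exponent coefficient (per unit fractional length), > 0.
#' @param k additive constant, `0 <= k < 1` so that F(0) > 0.
#' @param reference_length reference cochlear length in um (default 9400,
#'   the literature value for the rat basilar membrane); used only as a
#'   simulation default, never in place of a measured trace length.
#' @return object of class `place_frequency_map`.
#' @export
place_frequency_map <- function(A = 3.6, a = 1.21, k = 0.85,
                                reference_length = 9400) {
  check_number(A, "A", lower = .Machine$double.eps)
  check_number(a, "a", lower = .Machine$double.eps)
  check_number(k, "k", lower = 0, upper = 1 - 1e-12)
  check_number(reference_length, "reference_length", lower = 1)
  structure(list(A = A, a = a, k = k,
                 reference_length = reference_length),
            class = "place_frequency_map")
}

#' @export
print.place_frequency_map <- function(x, ...) {
  cat(sprintf(
    "Place-frequency map F(x) = %.4g (10^(%.4g x) - %.4g): %.3g-%.3g kHz\n",
    x$A, x$a, x$k, place_to_frequency(0, x), place_to_frequency(1, x)))
  invisible(x)
}

#' Convert fractional place (from apex) to frequency
#'
#' @param x fraction of cochlear length from the apex, in `[0, 1]`.
#' @param m a [place_frequency_map()].
#' @return frequency in kHz (vectorized over `x`).
#' @export
place_to_frequency <- function(x, m) {
  if (!inherits(m, "place_frequency_map"))
    stop_eq("`m` must be a `place_frequency_map`")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_eq("`x` must lie in [0, 1]")
  m$A * (10^(m$a * x) - m$k)
}

#' Convert frequency to fractional place (from apex)
#'
#' Closed-form inverse of [place_to_frequency()]:
#' `x = log10(f/A + k) / a`.
#'
#' @param f frequency in kHz, within the map's range.
#' @param m a [place_frequency_map()].
#' @return fraction from apex in `[0, 1]` (vectorized over `f`).
#' @export
frequency_to_place <- function(f, m) {
  if (!inherits(m, "place_frequency_map"))
    stop_eq("`m` must be a `place_frequency_map`")
  lo <- place_to_frequency(0, m); hi <- place_to_frequency(1, m)
  if (any(!is.finite(f)) || any(f < lo - 1e-9) || any(f > hi + 1e-9))
    stop_eq(sprintf("`f` outside map range [%.4g, %.4g] kHz", lo, hi))
  pmin(1, pmax(0, log10(f / m$A + m$k) / m$a))
}

## Point at arc distance s along the polyline (linear interpolation; an
## exact vertex hit resolves to the earlier segment).
trace_point_at <- function(t, s) {
  s <- min(max(s, 0), t$length)
  i <- findInterval(s, t$arc, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(t$points) - 1L)
  w <- (s - t$arc[i]) / t$seg[i]
  t$points[i, ] + w * (t$points[i + 1, ] - t$points[i, ])
}

#' Place frequency-analysis frames along a traced cochlea
#'
#' Converts each requested frequency to a fractional place, scales by the
#' *measured* trace length (frequency assignment is scale-invariant: it
#' depends only on the fraction of the cochlea traversed), interpolates the
#' frame center on the polyline, and lays an axis-aligned square frame of
#' side `frame_size` um around it.
#'
#' @param t a [spiral_trace()] (apex first).
#' @param freqs frequencies in kHz, e.g. the six standard regions
#'   `c(2.8, 8, 11.3, 16, 32, 45.2)`.
#' @param m a [place_frequency_map()].
#' @param frame_size frame side in um (default 50).
#' @param image_bounds optional `c(xmin, ymin, xmax, ymax)` um; frames
#'   extending beyond are clipped with a warning.
#' @return data.frame, one row per frequency: `frequency_khz`,
#'   `fraction_from_apex`, `arc_um`, `center_x`, `center_y`, `xmin`,
#'   `ymin`, `xmax`, `ymax`, `clipped`.
#' @export
locate_frequency_frames <- function(t, freqs = c(2.8, 8, 11.3, 16, 32, 45.2),
                                    m = place_frequency_map(),
                                    frame_size = 50,
                                    image_bounds = NULL) {
  if (!inherits(t, "spiral_trace")) stop_eq("`t` must be a `spiral_trace`")
  check_number(frame_size, "frame_size", lower = .Machine$double.eps)
  x <- frequency_to_place(freqs, m)
  arc <- x * t$length
  ctr <- t(vapply(arc, function(s) trace_point_at(t, s), numeric(2)))
  h <- frame_size / 2
  out <- data.frame(
    frequency_khz = freqs, fraction_from_apex = x, arc_um = arc,
    center_x = ctr[, 1], center_y = ctr[, 2],
    xmin = ctr[, 1] - h, ymin = ctr[, 2] - h,
    xmax = ctr[, 1] + h, ymax = ctr[, 2] + h,
    clipped = FALSE)
  if (!is.null(image_bounds)) {
    b <- image_bounds
    clip <- out$xmin < b[1] | out$ymin < b[2] |
      out$xmax > b[3] | out$ymax > b[4]
    if (any(clip)) {
      warning(sum(clip), " frame(s) extend beyond the image and were ",
              "clipped", call. = FALSE)
      out$xmin <- pmax(out$xmin, b[1]); out$ymin <- pmax(out$ymin, b[2])
      out$xmax <- pmin(out$xmax, b[3]); out$ymax <- pmin(out$ymax, b[4])
      out$clipped <- clip
    }
  }
  out[order(out$arc_um), , drop = FALSE]
}
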