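#' Construct a grayscale analysis frame
#'
#' One x40 field of an organ-of-Corti surface preparation: an 8-bit gray
#' matrix (dark immunoreaction product on a light background), the pixel
#' pitch, and an optional mask restricting analysis to the outer-hair-cell
#' (OHC) region. The default pitch of 0.2 um/pixel gives the standard
#' digital resolution of 25 pixels per um^2.
#'
#' @param pixels numeric matrix, values in `[0, 255]` (rows = y, image
#'   convention y down).
#' @param pixel_pitch um per pixel (default 0.2).
#' @param frequency optional frequency label in kHz.
#' @param mask optional logical matrix, same dim, TRUE = analyze.
#' @return object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_pitch = 0.2, frequency = NA_real_,
                        mask = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_eq("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop_eq("gray values must lie in [0, 255]")
  check_number(pixel_pitch, "pixel_pitch", lower = .Machine$double.eps)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(pixels)))
      stop_eq("`mask` must be a logical matrix matching `pixels`")
  }
  structure(list(pixels = pixels, pixel_pitch = pixel_pitch,
                 frequency = frequency, mask = mask),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_frame %d x %d px (%.1f x %.1f um), pitch %.2f um/px",
              d[2], d[1], d[2] * x$pixel_pitch, d[1] * x$pixel_pitch,
              x$pixel_pitch))
  if (!is.na(x$frequency)) cat(", region", x$frequency, "kHz")
  cat("\n")
  invisible(x)
}

frame_area_um2 <- function(frame) {
  length(frame$pixels) * frame$pixel_pitch^2
}

## Pixels per um^2; snapped to the exact integer when the pitch implies
## one (0.2 um/pixel -> exactly 25 px/um^2), so pixel counts convert to
## areas without floating-point residue.
px_per_um2 <- function(pitch) {
  inv <- 1 / pitch^2
  if (abs(inv - round(inv)) < 1e-9) round(inv) else inv
}

#' Fit the gray-level to optical-density calibration curve
#'
#' Builds a monotone piecewise-linear interpolant from a stepped-density
#' filter table (11 levels in the standard protocol). The measured table is
#' authoritative; the analytic relation OD = log10(I0/I) only supplies the
#' packaged default curve. Queries outside the calibrated gray range are
#' clamped to the end values with a warning.
#'
#' @param steps data.frame with columns `gray` (strictly monotone) and `od`
#'   (non-negative), >= 2 rows.
#' @return object of class `calibration_curve`.
#' @seealso [gray_to_od()], [default_calibration()]
#' @export
fit_gray_to_od <- function(steps) {
  if (!all(c("gray", "od") %in% names(steps)))
    stop_eq("`steps` must have columns `gray` and `od`")
  if (nrow(steps) < 2) stop_eq("need >= 2 calibration steps")
  o <- order(steps$gray)
  g <- steps$gray[o]; od <- steps$od[o]
  if (any(diff(g) <= 0)) stop_eq("`gray` values must be strictly monotone")
  if (any(od < 0)) stop_eq("`od` must be non-negative")
  structure(list(gray = g, od = od), class = "calibration_curve")
}

#' Default 11-step calibration curve
#'
#' Eleven (gray, OD) knots in uniform optical-density steps — the
#' geometry of a real stepped density filter — following
#' OD = log10(255 / gray) from 0 to 1.2 OD. Stands in for a measured
#' filter table when none is supplied.
#'
#' @return a [fit_gray_to_od()] curve.
#' @export
default_calibration <- function() {
  od <- seq(0, 1.2, length.out = 11)
  fit_gray_to_od(data.frame(gray = 255 * 10^(-od), od = od))
}

#' Convert gray levels to optical density through a calibration curve
#'
#' @param gray numeric vector of gray levels.
#' @param cal a [calibration_curve][fit_gray_to_od()]; default
#'   [default_calibration()].
#' @return OD values, same length.
#' @export
gray_to_od <- function(gray, cal = default_calibration()) {
  if (!inherits(cal, "calibration_curve"))
    stop_eq("`cal` must be a `calibration_curve`")
  if (any(gray < min(cal$gray) - 1e-9) || any(gray > max(cal$gray) + 1e-9))
    warning("gray values outside the calibrated range were clamped",
            call. = FALSE)
  stats::approx(cal$gray, cal$od, xout = gray, rule = 2)$y
}

#' Otsu threshold with a contrast guard
#'
#' Classic Otsu threshold over the 256-bin gray histogram, returning the
#' gray level that maximizes between-class variance. Otsu presumes a
#' bimodal histogram; on a frame with no dark foreground it would split the
#' background noise in half, so the threshold is only accepted when the
#' maximal between-class variance explains at least `eta_min` of the total
#' variance (a pure Gaussian background tops out near 0.64). Otherwise
#' `NA` is returned: no foreground.
#'
#' @param pixels numeric matrix or vector of gray values in `[0, 255]`.
#' @param eta_min minimal explained-variance fraction (default 0.8).
#' @return threshold gray level (pixels strictly darker are foreground),
#'   or `NA` when the frame has no separable dark phase.
#' @export
otsu_threshold <- function(pixels, eta_min = 0.8) {
  g <- floor(as.numeric(pixels))
  h <- tabulate(g + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  sigma_b2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b2[!is.finite(sigma_b2)] <- 0
  sigma_t2 <- sum(p * lev^2) - mu_t^2
  if (sigma_t2 <= 0) return(NA_real_)
  k <- which.max(sigma_b2)
  if (sigma_b2[k] / sigma_t2 < eta_min) return(NA_real_)
  ## foreground = pixels <= lev[k]; report as strict "darker than" cut
  lev[k] + 1
}

## 8-connected labeling of a logical mask via run-length encoding plus
## union-find: vertical runs are extracted per column, runs in adjacent
## columns are unioned when they overlap within +/- 1 row (the diagonal
## reach of 8-connectivity), and final roots are compressed to labels
## 1..K. Exact and fast: cost scales with the number of runs, not with
## object diameter.
label_components <- function(mask) {
  d <- dim(mask)
  run_col <- integer(0); run_s <- integer(0); run_e <- integer(0)
  col_first <- integer(d[2]); col_n <- integer(d[2])
  for (j in seq_len(d[2])) {
    v <- mask[, j]
    s <- which(v & !c(FALSE, v[-d[1]]))
    col_first[j] <- length(run_col) + 1L
    col_n[j] <- length(s)
    if (length(s)) {
      e <- which(v & !c(v[-1], FALSE))
      run_col <- c(run_col, rep.int(j, length(s)))
      run_s <- c(run_s, s); run_e <- c(run_e, e)
    }
  }
  n <- length(run_s)
  lab <- matrix(0, d[1], d[2])
  if (n == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in 2:d[2]) {
    na <- col_n[j - 1L]; nb <- col_n[j]
    if (na == 0L || nb == 0L) next
    a0 <- col_first[j - 1L]; b0 <- col_first[j]
    ia <- 0L; ib <- 0L
    while (ia < na && ib < nb) {
      a <- a0 + ia; b <- b0 + ib
      if (run_s[a] <= run_e[b] + 1L && run_s[b] <= run_e[a] + 1L) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
      if (run_e[a] < run_e[b]) ia <- ia + 1L else ib <- ib + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  for (r in seq_len(n))
    lab[run_s[r]:run_e[r], run_col[r]] <- labels[r]
  lab
}

#' Segment immunoreactive terminal buttons by density thresholding
#'
#' Pixels darker than the threshold are grouped into 8-connected
#' components; components outside the area limits are discarded. Area
#' follows the pixel pitch exactly: at the default 0.2 um/pixel, 25 pixels
#' make 1 um^2.
#'
#' @param frame an [image_frame()].
#' @param threshold gray cutoff (pixels with gray < threshold are
#'   foreground) or `"auto"` for [otsu_threshold()].
#' @param area_limits `c(min, max)` component area in um^2 retained
#'   (default `c(0.5, 50)`).
#' @return data.frame, one row per button: `id`, `area_um2`, `n_pixels`,
#'   `mean_gray`, `equiv_diam_um`, `centroid_x`, `centroid_y` (um, y
#'   down). Attributes: `labels` (the full label matrix before area
#'   filtering), `threshold`.
#' @export
segment_buttons <- function(frame, threshold = "auto",
                            area_limits = c(0.5, 50)) {
  if (!inherits(frame, "image_frame"))
    stop_eq("`frame` must be an `image_frame`")
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(frame$pixels)
  } else {
    check_number(threshold, "threshold", lower = 0, upper = 255)
  }
  empty <- data.frame(id = integer(), area_um2 = numeric(),
                      n_pixels = integer(), mean_gray = numeric(),
                      equiv_diam_um = numeric(), centroid_x = numeric(),
                      centroid_y = numeric())
  if (is.na(threshold)) {
    return(structure(empty, labels = matrix(0, nrow(frame$pixels),
                                            ncol(frame$pixels)),
                     threshold = NA_real_))
  }
  mask <- frame$pixels < threshold
  if (!is.null(frame$mask)) mask <- mask & frame$mask
  lab <- label_components(mask)
  if (max(lab) == 0)
    return(structure(empty, labels = lab, threshold = threshold))
  idx <- which(lab > 0)
  comp <- lab[idx]
  npx <- tabulate(comp)
  gsum <- rowsum(frame$pixels[idx], comp)[, 1]
  rc <- arrayInd(idx, dim(lab))
  ysum <- rowsum(rc[, 1] - 0.5, comp)[, 1]
  xsum <- rowsum(rc[, 2] - 0.5, comp)[, 1]
  out <- data.frame(
    id = seq_along(npx),
    area_um2 = npx / px_per_um2(frame$pixel_pitch),
    n_pixels = npx,
    mean_gray = gsum / npx,
    equiv_diam_um = 2 * sqrt(npx / px_per_um2(frame$pixel_pitch) / pi),
    centroid_x = xsum / npx * frame$pixel_pitch,
    centroid_y = ysum / npx * frame$pixel_pitch)
  keep <- out$area_um2 >= area_limits[1] & out$area_um2 <= area_limits[2]
  structure(out[keep, , drop = FALSE], labels = lab,
            threshold = threshold)
}

#' Button count normalized to surface area
#'
#' @param segments a [segment_buttons()] table (or anything with rows).
#' @param frame_area analyzed surface in um^2.
#' @return buttons per 10,000 um^2.
#' @export
button_density <- function(segments, frame_area) {
  check_number(frame_area, "frame_area", lower = .Machine$double.eps)
  NROW(segments) * 1e4 / frame_area
}

#' Optical-density statistics of the whole field
#'
#' Converts every masked pixel to OD through the calibration curve and
#' returns the field mean and SD (population convention: the field *is*
#' the whole population of pixels). These two numbers anchor the
#' normalized-OD statistic.
#'
#' @param frame an [image_frame()].
#' @param cal a calibration curve.
#' @param mask optional logical matrix overriding `frame$mask`; default
#'   whole frame.
#' @return list of class `field_stats`: `mean_od`, `sd_od`, `n`.
#' @export
field_od_stats <- function(frame, cal = default_calibration(),
                           mask = NULL) {
  if (!inherits(frame, "image_frame"))
    stop_eq("`frame` must be an `image_frame`")
  mask <- mask %||% frame$mask %||%
    matrix(TRUE, nrow(frame$pixels), ncol(frame$pixels))
  if (!any(mask)) stop_eq("empty field mask")
  od <- gray_to_od(frame$pixels[mask], cal)
  m <- mean(od)
  s <- sqrt(mean((od - m)^2))          # population SD
  structure(list(mean_od = m, sd_od = s, n = length(od)),
            class = "field_stats")
}

#' Field-normalized optical density
#'
#' The densitometric z-style statistic: the field mean OD (entire OHC
#' region) is subtracted from the button's OD and the result divided by the
#' field SD.
#'
#' @param button_od OD value(s) of immunoreactive buttons.
#' @param field a [field_od_stats()] result.
#' @return dimensionless normalized OD; `NA` with a warning when the field
#'   SD is zero (undefined normalization).
#' @export
normalized_od <- function(button_od, field) {
  if (!inherits(field, "field_stats"))
    stop_eq("`field` must be `field_stats`")
  if (field$sd_od == 0) {
    warning("field SD is zero: normalized OD undefined", call. = FALSE)
    return(rep(NA_real_, length(button_od)))
  }
  (button_od - field$mean_od) / field$sd_od
}

#' Seeded random subset of buttons for densitometry
#'
#' The manual selection of 30 buttons per field in the bench protocol has
#' no reproducible rule; this seeded uniform sample is its documented
#' stand-in. When fewer than `n` buttons exist, all are taken with a
#' warning.
#'
#' @param segments a [segment_buttons()] table.
#' @param n buttons to sample (default 30).
#' @param seed RNG seed.
#' @return the sampled subset (rows of `segments`).
#' @export
sample_buttons_for_densitometry <- function(segments, n = 30,
                                            seed = NULL) {
  if (nrow(segments) <= n) {
    if (nrow(segments) < n)
      warning("only ", nrow(segments), " buttons available; taking all",
              call. = FALSE)
    return(segments)
  }
  idx <- with_seed(seed, sample.int(nrow(segments), n))
  segments[sort(idx), , drop = FALSE]
}

#' Measure a frame end-to-end (morphometry + densitometry)
#'
#' Convenience wrapper chaining segmentation, field OD statistics, button
#' OD conversion (on each button's *mean gray*, matching the bench
#' protocol, not per-pixel OD averaging), normalization, and density.
#'
#' @inheritParams segment_buttons
#' @param cal calibration curve.
#' @param n_densitometry buttons sampled for densitometry (default 30).
#' @param seed seed for the densitometry sample.
#' @return list: `buttons` (segments + `od`, `norm_od`),
#'   `densitometry_sample` (the seeded subset), `field`
#'   (`field_stats`), `density_per_10k_um2`.
#' @export
measure_frame <- function(frame, threshold = "auto",
                          area_limits = c(0.5, 50),
                          cal = default_calibration(),
                          n_densitometry = 30, seed = NULL) {
  seg <- segment_buttons(frame, threshold, area_limits)
  field <- field_od_stats(frame, cal)
  seg$od <- gray_to_od(seg$mean_gray, cal)
  seg$norm_od <- normalized_od(seg$od, field)
  list(buttons = seg,
       densitometry_sample =
         sample_buttons_for_densitometry(seg, n_densitometry, seed),
       field = field,
       density_per_10k_um2 = button_density(seg, frame_area_um2(frame)))
}

#' Count and classify free immune cells in a frame
#'
#' Candidate cells are segmented on a 3x3 box-smoothed copy of the frame:
#' the cut sits `k_mad` scaled MADs below the median of the *non-dark*
#' phase (pixels at or above the Otsu dark cut), so faint
#' background-contrast cells are captured however many strongly stained
#' objects the frame holds, while smoothing suppresses single-pixel
#' noise. The box filter dilates dark objects by about one pixel, so the
#' mask is eroded by one pixel before labeling.
#'
#' Candidates are classified by equivalent diameter and immunoreactivity.
#' A component is immunoreactive when it has a strongly stained core (its
#' minimum smoothed gray falls below the frame's Otsu dark cut) — the
#' operational form of the qualitative "intensely immunoreactive vs not
#' immunopositive" distinction: immunoreactive cells of 10-20 um count as
#' macrophages, non-immunoreactive cells of 5-10 um as monocytes.
#' Terminal buttons match neither rule (too small for macrophages,
#' immunoreactive so never monocytes). Class bounds are widened by
#' `diam_tol` to absorb the ~1-pixel smoothing/erosion bias.
#'
#' @param frame an [image_frame()].
#' @param analyzed_length cochlear length represented by the analyzed
#'   material, in um (used for the per-1,000-um rates).
#' @param cal calibration curve (used to report candidate mean OD).
#' @param rules list with `macrophage_diam_um` and `monocyte_diam_um`
#'   (length-2 um ranges).
#' @param diam_tol tolerance (um) widening each class range (default 1).
#' @param k_mad robust threshold depth (default 4).
#' @return list of class `immune_counts`: `ir_macrophages`, `monocytes`,
#'   `per_1000um` (named rates), `analyzed_length_um`, `candidates`
#'   (data.frame of all candidate components with class labels).
#' @export
count_immune_cells <- function(frame, analyzed_length,
                               cal = default_calibration(),
                               rules = list(
                                 macrophage_diam_um = c(10, 20),
                                 monocyte_diam_um = c(5, 10)),
                               diam_tol = 1, k_mad = 4) {
  if (!inherits(frame, "image_frame"))
    stop_eq("`frame` must be an `image_frame`")
  check_number(analyzed_length, "analyzed_length",
               lower = .Machine$double.eps)
  sm <- box_smooth3(frame$pixels)
  dark_cut <- otsu_threshold(frame$pixels)
  bg <- if (is.na(dark_cut)) sm else sm[frame$pixels >= dark_cut]
  cut <- stats::median(bg) - k_mad * stats::mad(bg)
  mask <- erode3(sm < cut)
  lab <- label_components(mask)
  macro <- 0L; mono <- 0L
  cand <- data.frame(equiv_diam_um = numeric(), mean_od = numeric(),
                     immunoreactive = logical(), class = character())
  if (max(lab) > 0) {
    idx <- which(lab > 0)
    comp <- lab[idx]
    npx <- tabulate(comp)
    gmean <- rowsum(frame$pixels[idx], comp)[, 1] / npx
    gmin_sm <- vapply(split(sm[idx], factor(comp, seq_along(npx))),
                      min, numeric(1))
    diam <- 2 * sqrt(npx / px_per_um2(frame$pixel_pitch) / pi)
    od <- gray_to_od(gmean, cal)
    ir <- if (is.na(dark_cut)) rep(FALSE, length(diam)) else
      gmin_sm < dark_cut
    mr <- rules$macrophage_diam_um + c(-diam_tol, diam_tol)
    nr <- rules$monocyte_diam_um + c(-diam_tol, diam_tol)
    is_macro <- ir & diam >= mr[1] & diam <= mr[2]
    is_mono <- !ir & diam >= nr[1] & diam <= nr[2]
    macro <- sum(is_macro); mono <- sum(is_mono)
    cls <- rep("other", length(diam))
    cls[is_macro] <- "ir_macrophage"; cls[is_mono] <- "monocyte"
    cand <- data.frame(equiv_diam_um = diam, mean_od = od,
                       immunoreactive = ir, class = cls)
  }
  structure(list(
    ir_macrophages = macro, monocytes = mono,
    per_1000um = c(ir_macrophages = macro * 1000 / analyzed_length,
                   monocytes = mono * 1000 / analyzed_length),
    analyzed_length_um = analyzed_length,
    candidates = cand), class = "immune_counts")
}

#' @export
print.immune_counts <- function(x, ...) {
  cat(sprintf(
    "immune cells: %d IR macrophages, %d monocytes over %.0f um\n",
    x$ir_macrophages, x$monocytes, x$analyzed_length_um))
  cat(sprintf("  rates per 1,000 um: %.3f / %.3f\n",
              x$per_1000um[1], x$per_1000um[2]))
  invisible(x)
}

## Morphological erosion with a 3x3 structuring element (edges eroded).
erode3 <- function(mask) {
  d <- dim(mask)
  padded <- matrix(FALSE, d[1] + 2, d[2] + 2)
  padded[1 + seq_len(d[1]), 1 + seq_len(d[2])] <- mask
  out <- matrix(TRUE, d[1], d[2])
  for (dr in 0:2) for (dc in 0:2)
    out <- out & padded[dr + seq_len(d[1]), dc + seq_len(d[2])]
  out
}

## 3x3 box filter with edge replication.
box_smooth3 <- function(m) {
  d <- dim(m)
  padded <- m[c(1, seq_len(d[1]), d[1]), c(1, seq_len(d[2]), d[2])]
  acc <- matrix(0, d[1], d[2])
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + padded[dr + seq_len(d[1]), dc + seq_len(d[2])]
  acc / 9
}
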