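#' Configuration for the cochlear surface-image simulator
#'
#' Describes how synthetic x40 fields of the outer-hair-cell region are
#' rendered: dark elliptical ChAT-immunoreactive terminal buttons on a
#' light DAB-like background, with button size following a Gaussian
#' cochleotopic profile over log-frequency (peaking at 11.3 kHz in sham
#' animals) and optional free immune cells in two size classes
#' (immunoreactive 10-20 um macrophages rendered dark, 5-10 um monocytes
#' at background contrast only).
#'
#' The default frame is 250 x 250 pixels at 0.2 um/pixel (50 x 50 um,
#' 2,500 um^2; 25 pixels per um^2). The default button density of 160 per
#' 10,000 um^2 yields an expected 40 buttons per frame. Buttons are
#' rejection-sampled to be non-touching (bounding circles separated by
#' `min_gap_px` pixels) so count ground truth is unambiguous;
#' `allow_overlap` lifts that.
#'
#' @param cochlea_length reference cochlear length in um (default 9400).
#' @param pixel_pitch um/pixel (default 0.2).
#' @param frame_size `c(rows, cols)` in pixels.
#' @param size_profile list: `peak_khz`, `peak_area_um2`, `base_area_um2`,
#'   `sigma_log2` (Gaussian width in octaves), `area_sd_um2` (per-button
#'   SD around the profile mean).
#' @param od_profile list: `mean_gray`, `sd_gray` — button mean gray level
#'   (flat across frequency by default; staining effects shift it).
#' @param area_scale multiplies the size profile (group/timepoint size
#'   effects).
#' @param gray_shift added to button mean gray (staining-depletion
#'   effects: lighter buttons = lower OD).
#' @param button_density expected buttons per 10,000 um^2 (default 160).
#' @param immune_cell_rate named numeric, cells per 1,000 um of cochlear
#'   length: `macrophage`, `monocyte` (default 0, 0).
#' @param immune_gray mean gray of each class (`macrophage` dark,
#'   `monocyte` just below background).
#' @param field_background `c(mean, sd)` background gray.
#' @param min_gap_px minimal bounding-circle gap between objects, pixels.
#' @param allow_overlap allow touching/overlapping objects.
#' @param max_place_attempts rejection-sampling attempts per object before
#'   a generation error.
#' @param seed RNG seed.
#' @return object of class `cochlea_sim_config`.
#' @export
cochlea_sim_config <- function(cochlea_length = 9400,
                               pixel_pitch = 0.2,
                               frame_size = c(250, 250),
                               size_profile = list(
                                 peak_khz = 11.3, peak_area_um2 = 13.5,
                                 base_area_um2 = 8, sigma_log2 = 0.55,
                                 area_sd_um2 = 3.5),
                               od_profile = list(mean_gray = 90,
                                                 sd_gray = 8),
                               area_scale = 1, gray_shift = 0,
                               button_density = 160,
                               immune_cell_rate = c(macrophage = 0,
                                                    monocyte = 0),
                               immune_gray = c(macrophage = 70,
                                               monocyte = 185),
                               field_background = c(mean = 200, sd = 6),
                               min_gap_px = 4, allow_overlap = FALSE,
                               max_place_attempts = 2000,
                               seed = NULL) {
  check_number(pixel_pitch, "pixel_pitch", lower = .Machine$double.eps)
  check_number(button_density, "button_density", lower = 0)
  check_number(area_scale, "area_scale", lower = .Machine$double.eps)
  if (any(immune_cell_rate < 0)) stop_eq("immune rates must be >= 0")
  if (size_profile$base_area_um2 <= 0 || size_profile$peak_area_um2 <= 0)
    stop_eq("size profile must be strictly positive")
  structure(list(
    cochlea_length = cochlea_length, pixel_pitch = pixel_pitch,
    frame_size = frame_size, size_profile = size_profile,
    od_profile = od_profile, area_scale = area_scale,
    gray_shift = gray_shift, button_density = button_density,
    immune_cell_rate = immune_cell_rate, immune_gray = immune_gray,
    field_background = field_background, min_gap_px = min_gap_px,
    allow_overlap = allow_overlap,
    max_place_attempts = max_place_attempts, seed = seed
  ), class = "cochlea_sim_config")
}

#' Mean button area of the cochleotopic size profile
#'
#' Gaussian over log2-frequency: base + (peak - base) *
#' exp(-log2(f/peak_khz)^2 / (2 sigma^2)).
#'
#' @param frequency kHz (vectorized).
#' @param config a [cochlea_sim_config()].
#' @return mean button area in um^2.
#' @export
size_profile_mean <- function(frequency, config) {
  p <- config$size_profile
  d <- log2(frequency / p$peak_khz)
  config$area_scale *
    (p$base_area_um2 + (p$peak_area_um2 - p$base_area_um2) *
       exp(-d^2 / (2 * p$sigma_log2^2)))
}

## Paint one ellipse onto `img` (pixel centers inside -> value + noise).
## Returns the updated image and the number of pixels painted.
paint_ellipse <- function(img, x0, y0, a, b, theta, value, noise_sd,
                          pitch) {
  d <- dim(img)
  rmax <- max(a, b)
  rows <- max(1L, floor((y0 - rmax) / pitch)):
    min(d[1], ceiling((y0 + rmax) / pitch + 1))
  cols <- max(1L, floor((x0 - rmax) / pitch)):
    min(d[2], ceiling((x0 + rmax) / pitch + 1))
  yc <- (rows - 0.5) * pitch - y0
  xc <- (cols - 0.5) * pitch - x0
  X <- matrix(xc, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(yc, length(rows), length(cols))
  U <- X * cos(theta) + Y * sin(theta)
  V <- -X * sin(theta) + Y * cos(theta)
  inside <- (U / a)^2 + (V / b)^2 <= 1
  n_in <- sum(inside)
  if (n_in > 0) {
    sub <- img[rows, cols, drop = FALSE]
    sub[inside] <- value + stats::rnorm(n_in, 0, noise_sd)
    img[rows, cols] <- sub
  }
  list(img = img, n_pixels = n_in)
}

#' Simulate one cochlear surface-preparation frame with ground truth
#'
#' Renders a frame at the requested frequency region: the button count is
#' Poisson around `button_density` x frame area / 10^4 um^2, per-button
#' areas and gray levels are drawn from the configured profiles, immune
#' cells are added at their per-length Poisson rates, and every rendered
#' object is listed in the ground truth.
#'
#' @param config a [cochlea_sim_config()].
#' @param frequency frequency region in kHz.
#' @return list with `frame` (an [image_frame()]) and `truth`:
#'   `n_buttons`, per-object table `objects` (type, center, drawn area,
#'   rendered pixel count/area, gray, od), immune counts by class, and the
#'   profile mean area at this frequency.
#' @export
simulate_cochlea_image <- function(config, frequency) {
  if (!inherits(config, "cochlea_sim_config"))
    stop_eq("`config` must be a `cochlea_sim_config`")
  check_number(frequency, "frequency", lower = .Machine$double.eps)
  with_seed(config$seed, {
    d <- config$frame_size
    pitch <- config$pixel_pitch
    w_um <- d[2] * pitch; h_um <- d[1] * pitch
    area_um2 <- w_um * h_um
    bg <- config$field_background
    img <- matrix(stats::rnorm(prod(d), bg[["mean"]], bg[["sd"]]),
                  d[1], d[2])

    mean_area <- size_profile_mean(frequency, config)
    n_btn <- stats::rpois(1, config$button_density * area_um2 / 1e4)
    n_mac <- stats::rpois(1, config$immune_cell_rate[["macrophage"]] *
                            w_um / 1000)
    n_mon <- stats::rpois(1, config$immune_cell_rate[["monocyte"]] *
                            w_um / 1000)

    ## draw object geometry first (areas, radii), then place by rejection
    draw_trunc <- function(n, mean, sd, lower) {
      x <- stats::rnorm(n, mean, sd)
      while (any(bad <- x < lower))
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
      x
    }
    objs <- list()
    if (n_btn > 0) {
      area <- draw_trunc(n_btn, mean_area,
                         config$size_profile$area_sd_um2, lower = 2)
      ratio <- stats::runif(n_btn, 0.7, 1)
      a <- sqrt(area / (pi * ratio))
      objs$button <- data.frame(
        type = "button", area_drawn_um2 = area, a = a, b = a * ratio,
        theta = stats::runif(n_btn, 0, pi),
        gray = pmin(250, pmax(30, stats::rnorm(
          n_btn, config$od_profile$mean_gray + config$gray_shift,
          config$od_profile$sd_gray))))
    }
    if (n_mac > 0) {
      diam <- stats::runif(n_mac, 12, 18)
      objs$macrophage <- data.frame(
        type = "macrophage", area_drawn_um2 = pi * (diam / 2)^2,
        a = diam / 2, b = diam / 2, theta = 0,
        gray = config$immune_gray[["macrophage"]])
    }
    if (n_mon > 0) {
      diam <- stats::runif(n_mon, 6, 9)
      objs$monocyte <- data.frame(
        type = "monocyte", area_drawn_um2 = pi * (diam / 2)^2,
        a = diam / 2, b = diam / 2, theta = 0,
        gray = config$immune_gray[["monocyte"]])
    }
    obj <- if (length(objs)) do.call(rbind, objs) else
      data.frame(type = character(), area_drawn_um2 = numeric(),
                 a = numeric(), b = numeric(), theta = numeric(),
                 gray = numeric())
    rownames(obj) <- NULL

    ## place large objects first so they still fit among many small ones
    if (nrow(obj) > 1) obj <- obj[order(-pmax(obj$a, obj$b)), ]
    gap <- config$min_gap_px * pitch
    rad <- pmax(obj$a, obj$b)
    xs <- numeric(nrow(obj)); ys <- numeric(nrow(obj))
    for (i in seq_len(nrow(obj))) {
      m <- rad[i] + pitch          # keep whole object inside the frame
      if (2 * m >= min(w_um, h_um))
        stop_eq("object larger than the frame")
      placed <- FALSE
      for (try in seq_len(config$max_place_attempts)) {
        x <- stats::runif(1, m, w_um - m)
        y <- stats::runif(1, m, h_um - m)
        if (config$allow_overlap || i == 1) { placed <- TRUE }
        else {
          j <- seq_len(i - 1)
          placed <- all((x - xs[j])^2 + (y - ys[j])^2 >
                          (rad[i] + rad[j] + gap)^2)
        }
        if (placed) { xs[i] <- x; ys[i] <- y; break }
      }
      if (!placed)
        stop_eq("could not place all objects without overlap after ",
                config$max_place_attempts, " attempts; lower the density",
                " or allow overlap")
    }
    obj$center_x <- xs; obj$center_y <- ys
    obj$n_pixels <- integer(nrow(obj))
    for (i in seq_len(nrow(obj))) {
      p <- paint_ellipse(img, obj$center_x[i], obj$center_y[i],
                         obj$a[i], obj$b[i], obj$theta[i], obj$gray[i],
                         bg[["sd"]], pitch)
      img <- p$img
      obj$n_pixels[i] <- p$n_pixels
    }
    img[] <- pmin(255, pmax(0, img))
    obj$area_rendered_um2 <- obj$n_pixels * pitch^2
    obj$od <- gray_to_od(obj$gray)

    frame <- image_frame(img, pixel_pitch = pitch, frequency = frequency)
    truth <- list(
      frequency_khz = frequency,
      n_buttons = sum(obj$type == "button"),
      n_macrophages = sum(obj$type == "macrophage"),
      n_monocytes = sum(obj$type == "monocyte"),
      profile_mean_area_um2 = mean_area,
      frame_width_um = w_um,
      objects = obj)
    list(frame = frame, truth = truth)
  })
}
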