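test_that("calibration interpolates linearly and hits its knots", {
  cal <- fit_gray_to_od(data.frame(gray = c(0, 255), od = c(2, 0)))
  expect_equal(gray_to_od(127.5, cal), 1)
  expect_equal(gray_to_od(0, cal), 2)
  expect_equal(gray_to_od(255, cal), 0)

  ## 11 knots sampled from OD = log10(255/gray) in uniform OD steps:
  ## interpolant stays within 0.02 OD of the analytic curve between knots
  cal11 <- default_calibration()
  q <- seq(min(cal11$gray), 255, by = 0.5)
  expect_lt(max(abs(gray_to_od(q, cal11) - log10(255 / q))), 0.02)
  ## monotone: darker gray, higher OD, everywhere
  expect_true(all(diff(gray_to_od(q, cal11)) <= 0))

  expect_error(fit_gray_to_od(data.frame(gray = c(10, 10, 30),
                                         od = c(1, 1, 0))), "monotone")
  expect_warning(gray_to_od(300, cal11), "clamped")
})

test_that("segmentation area calibration is exact at 25 px per um^2", {
  px <- matrix(255, 20, 20)
  px[8:12, 8:12] <- 0                   # 5x5 square
  f <- image_frame(px, pixel_pitch = 0.2)
  seg <- segment_buttons(f, threshold = 128)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$area_um2, 1.0)
  expect_equal(seg$n_pixels, 25L)

  ## blank frame: nothing to segment under the auto threshold
  set.seed(6)
  blank <- image_frame(matrix(pmin(255, pmax(0, rnorm(250 * 250, 200, 6))),
                              250, 250))
  expect_equal(nrow(segment_buttons(blank)), 0)

  ## area limits filter components
  px2 <- matrix(255, 40, 40)
  px2[2:3, 2:3] <- 0                    # 4 px = 0.16 um^2, below min
  px2[20:30, 20:30] <- 0                # 121 px = 4.84 um^2
  f2 <- image_frame(px2)
  seg2 <- segment_buttons(f2, threshold = 100,
                          area_limits = c(0.5, 50))
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$n_pixels, 121L)
})

test_that("8-connected labeling matches a flood-fill oracle", {
  set.seed(13)
  for (i in 1:8) {
    mask <- matrix(runif(40 * 40) < 0.25, 40, 40)
    lab <- efferentquant:::label_components(mask)
    expect_equal(max(lab), oracle_component_count(mask))
    ## labeled support is exactly the mask
    expect_identical(lab > 0, mask)
  }
  ## diagonal-only contact is one component
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(efferentquant:::label_components(m)), 1)
})

test_that("field OD statistics use the population convention", {
  cal <- fit_gray_to_od(data.frame(gray = c(0, 255), od = c(2, 0)))
  uf <- image_frame(matrix(100, 10, 10))
  fs <- field_od_stats(uf, cal)
  expect_equal(fs$mean_od, gray_to_od(100, cal))
  expect_equal(fs$sd_od, 0)

  half <- image_frame(matrix(c(0, 255), 10, 10))
  fs2 <- field_od_stats(half, cal)
  expect_equal(fs2$mean_od, 1)
  expect_equal(fs2$sd_od, 1)

  ## random field equals brute-force per-pixel recomputation
  set.seed(17)
  px <- matrix(runif(400, 20, 250), 20, 20)
  rf <- image_frame(px)
  fs3 <- field_od_stats(rf)
  od <- gray_to_od(as.numeric(px))
  expect_equal(fs3$mean_od, mean(od))
  expect_equal(fs3$sd_od, sqrt(mean((od - mean(od))^2)))
})

test_that("normalized OD is a z-score against the field", {
  fs <- structure(list(mean_od = 0.5, sd_od = 0.1, n = 100),
                  class = "field_stats")
  expect_equal(normalized_od(0.5, fs), 0)
  expect_equal(normalized_od(0.7, fs), 2)
  ## self-normalization: the field's own pixels standardize exactly
  set.seed(19)
  px <- matrix(runif(2500, 20, 240), 50, 50)
  f <- image_frame(px)
  field <- field_od_stats(f)
  z <- normalized_od(gray_to_od(as.numeric(px)), field)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  ## zero field SD is flagged, not infinite
  fs0 <- structure(list(mean_od = 0.5, sd_od = 0, n = 4),
                   class = "field_stats")
  expect_warning(out <- normalized_od(1, fs0), "undefined")
  expect_true(is.na(out))
})

test_that("densitometry sampling is seeded and bounded", {
  seg <- data.frame(id = 1:50, area_um2 = runif(50))
  s1 <- sample_buttons_for_densitometry(seg, 30, seed = 4)
  s2 <- sample_buttons_for_densitometry(seg, 30, seed = 4)
  expect_equal(nrow(s1), 30)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, sample_buttons_for_densitometry(seg, 30, seed = 5)))
  expect_warning(
    all20 <- sample_buttons_for_densitometry(seg[1:20, ], 30),
    "taking all")
  expect_equal(nrow(all20), 20)
})

test_that("button density is count normalized to 10,000 um^2", {
  seg <- data.frame(id = 1:40)
  expect_equal(button_density(seg, 20000), 20)
  expect_equal(button_density(seg[0, ], 20000), 0)
  expect_error(button_density(seg, 0), "frame_area")
})

test_that("immune cells are classified by size and staining", {
  ## constructed frame: 3 dark macrophage-sized disks, 2 faint
  ## monocyte-sized disks, plus button-sized dark disks that must not
  ## contaminate either class
  img <- matrix(200, 400, 400)
  for (c0 in list(c(20, 20), c(45, 20), c(70, 20)))
    img <- paint_disk(img, c0[1], c0[2], 7, 70, 0.2)$img
  for (c0 in list(c(20, 50), c(50, 50)))
    img <- paint_disk(img, c0[1], c0[2], 3.5, 185, 0.2)$img
  for (c0 in list(c(20, 70), c(40, 70), c(60, 70)))
    img <- paint_disk(img, c0[1], c0[2], 1.8, 90, 0.2)$img
  f <- image_frame(img)
  ic <- count_immune_cells(f, analyzed_length = 2000)
  expect_equal(ic$ir_macrophages, 3L)
  expect_equal(ic$monocytes, 2L)
  expect_equal(unname(ic$per_1000um), c(1.5, 1.0))

  ## empty frame counts zero
  set.seed(23)
  blank <- image_frame(matrix(pmin(255, pmax(0, rnorm(160000, 200, 6))),
                              400, 400))
  ic0 <- count_immune_cells(blank, analyzed_length = 2000)
  expect_equal(ic0$ir_macrophages + ic0$monocytes, 0L)
})

test_that("simulated immune rates are recovered within Poisson error", {
  tm <- 0; cm <- 0; tn <- 0; cn <- 0
  for (s in 1:40) {
    si <- simulate_cochlea_image(cochlea_sim_config(
      frame_size = c(400, 400),
      immune_cell_rate = c(macrophage = 25, monocyte = 25),
      seed = 5000 + s), 16)
    ic <- count_immune_cells(si$frame,
                             analyzed_length = si$truth$frame_width_um)
    tm <- tm + si$truth$n_macrophages; cm <- cm + ic$ir_macrophages
    tn <- tn + si$truth$n_monocytes;  cn <- cn + ic$monocytes
  }
  ## counted totals within 3 sqrt(N) of rendered truth
  expect_lt(abs(cm - tm), 3 * sqrt(max(tm, 1)))
  expect_lt(abs(cn - tn), 3 * sqrt(max(tn, 1)))
})

test_that("measure_frame chains morphometry and densitometry", {
  sim <- simulate_cochlea_image(cochlea_sim_config(seed = 31), 11.3)
  m <- measure_frame(sim$frame, seed = 1)
  expect_equal(nrow(m$buttons), sim$truth$n_buttons)
  expect_equal(nrow(m$densitometry_sample), min(30, nrow(m$buttons)))
  expect_equal(m$density_per_10k_um2,
               nrow(m$buttons) * 1e4 / 2500)
  ## buttons are dark: strongly positive normalized OD
  expect_true(all(m$buttons$norm_od > 0))
})
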