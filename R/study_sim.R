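#' Default group x timepoint effect sizes for a simulated study
#'
#' The study conditions emulated by [simulate_study()]: four arms (SC sham
#' control, ES electrically stimulated, AT acoustic trauma, ES_AT
#' stimulation before trauma) followed over protocol days 0, 12, 13, 14,
#' 19, 26. Mean ABR thresholds follow the reported trajectories (SC
#' constant at 10 dB; AT elevated to 30 +/- 6.32 dB one day after trauma
#' with stepwise recovery; ES and ES_AT transiently at 33.33 +/- 5.16 dB
#' right after the last stimulation session, back to baseline a day
#' later). Morphometry/densitometry effects carry the per-arm means, SDs
#' and area-OD correlations of the terminal-timepoint cochleae; immune
#' rates encode the qualitative pattern of an inflammatory peak one day
#' after trauma, curbed by prior stimulation and resolved by day 26.
#'
#' @return list with data.frames `thresholds`, `icc`, `immune`.
#' @export
default_study_effects <- function() {
  days <- c(0, 12, 13, 14, 19, 26)
  thr <- rbind(
    data.frame(group = "SC", timepoint_day = days, mean_db = 10,
               sd_db = 2),
    data.frame(group = "ES", timepoint_day = days,
               mean_db = c(10, 33.33, 10, 10, 10, 10),
               sd_db = c(2, 5.16, 2, 2, 2, 2)),
    data.frame(group = "AT", timepoint_day = days,
               mean_db = c(10, 10, 30, 21.66, 13.33, 10),
               sd_db = c(2, 2, 6.32, 4.08, 5.16, 2)),
    data.frame(group = "ES_AT", timepoint_day = days,
               mean_db = c(10, 33.33, 10, 10, 10, 10),
               sd_db = c(2, 5.16, 2, 2, 2, 2)))
  icc <- data.frame(
    group = c("SC", "AT", "ES_AT", "AT", "ES_AT"),
    timepoint_day = c(26, 13, 13, 26, 26),
    od_mean = c(4.30, 3.37, 3.26, 4.34, 5.14),
    od_sd = c(1.25, 0.84, 0.79, 0.69, 1.90),
    area_mean = c(10.00, 8.14, 9.11, 11.36, 11.33),
    area_sd = c(4.63, 2.51, 3.11, 3.73, 4.45),
    rho = c(-0.123, -0.584, -0.269, -0.578, -0.391))
  immune <- data.frame(
    group = c("SC", "AT", "ES_AT", "AT", "ES_AT"),
    timepoint_day = c(26, 13, 13, 26, 26),
    macrophage_rate = c(0.3, 3.0, 1.5, 1.0, 0.8),
    monocyte_rate = c(0.3, 2.0, 1.0, 0.8, 0.6))
  list(thresholds = thr, icc = icc, immune = immune)
}

#' Define a simulated study design
#'
#' @param groups arms to simulate, subset of SC, ES, AT, ES_AT.
#' @param n_per_group animals per arm (>= 2; default 6).
#' @param timepoints protocol days of ABR recording.
#' @param frequencies analyzed frequency regions in kHz.
#' @param effects effect table as from [default_study_effects()]; every
#'   (group, timepoint) threshold cell must be present.
#' @param analyzed_length_um cochlear length represented by the immune
#'   counting material per animal (default 8080 um, a typical measured
#'   spiral-bundle perimeter).
#' @param buttons_per_frame expected segmented buttons per frequency frame
#'   (Poisson mean, default 40).
#' @param abr ABR simulator settings shared by all animals (an
#'   [abr_sim_config()] whose `true_threshold` and `seed` are overridden
#'   per animal and day).
#' @param render_images also render cochlear frames for every animal at
#'   the terminal timepoints (slow; measurement-level tables are always
#'   generated).
#' @param seed master seed.
#' @return object of class `study_design`.
#' @export
study_design <- function(groups = c("SC", "ES", "AT", "ES_AT"),
                         n_per_group = 6,
                         timepoints = c(0, 12, 13, 14, 19, 26),
                         frequencies = c(2.8, 8, 11.3, 16, 32, 45.2),
                         effects = default_study_effects(),
                         analyzed_length_um = 8080,
                         buttons_per_frame = 40,
                         abr = abr_sim_config(),
                         render_images = FALSE,
                         seed = NULL) {
  known <- c("SC", "ES", "AT", "ES_AT")
  if (!all(groups %in% known))
    stop_eq("unknown group label(s): ",
            paste(setdiff(groups, known), collapse = ", "))
  if (n_per_group < 2) stop_eq("`n_per_group` must be >= 2")
  thr <- effects$thresholds
  for (g in groups) for (d in timepoints) {
    if (!any(thr$group == g & thr$timepoint_day == d))
      stop_eq("effects$thresholds lacks cell (", g, ", day ", d, ")")
  }
  structure(list(groups = groups, n_per_group = n_per_group,
                 timepoints = timepoints, frequencies = frequencies,
                 effects = effects,
                 analyzed_length_um = analyzed_length_um,
                 buttons_per_frame = buttons_per_frame, abr = abr,
                 render_images = render_images, seed = seed),
            class = "study_design")
}

## Snap a drawn threshold to the stimulus-level grid.
snap_to_grid <- function(x, levels) {
  levels[pmin(pmax(round((x - levels[1]) / diff(levels)[1]), 0) + 1,
              length(levels))]
}

#' Simulate a whole study with known ground truth
#'
#' Generates, per animal and timepoint, a true threshold (normal around
#' the arm's configured mean, snapped to the 10-dB stimulus grid) and the
#' corresponding averaged ABR series; per animal and frequency region at
#' the terminal timepoints, measurement-level button tables (area and
#' normalized OD drawn from the arm's effect distribution, with the
#' configured area-OD correlation imposed) and immune-cell counts at the
#' arm's Poisson rates. Optionally renders full image frames.
#'
#' One master seed fans out deterministically to every stage via
#' [child_seeds()], so reruns are bit-identical.
#'
#' @param design a [study_design()].
#' @return object of class `study_dataset`: `design`,
#'   `thresholds` (animal, group, timepoint_day, true_threshold_db),
#'   `abr` (nested list `abr[[animal]][[as.character(day)]]` of
#'   [abr_series] objects), `buttons`, `immune`, and `frames` (NULL
#'   unless `render_images`).
#' @export
simulate_study <- function(design) {
  if (!inherits(design, "study_design"))
    stop_eq("`design` must be a `study_design`")
  seeds <- child_seeds(design$seed %||% 1L, 4)
  eff <- design$effects
  animals <- unlist(lapply(design$groups, function(g)
    paste0(g, "_", seq_len(design$n_per_group))))
  group_of <- sub("_[0-9]+$", "", animals)

  ## --- ABR arm -------------------------------------------------------
  grid <- design$abr$stimulus_levels
  thr_rows <- list(); abr <- list()
  abr_seeds <- child_seeds(seeds[1],
                           length(animals) * length(design$timepoints))
  idx <- 0
  for (ai in seq_along(animals)) {
    abr[[animals[ai]]] <- list()
    for (d in design$timepoints) {
      idx <- idx + 1
      cell <- eff$thresholds[eff$thresholds$group == group_of[ai] &
                               eff$thresholds$timepoint_day == d, ]
      true_thr <- with_seed(abr_seeds[idx],
                            snap_to_grid(stats::rnorm(1, cell$mean_db,
                                                      cell$sd_db), grid))
      cfg <- design$abr
      cfg$true_threshold <- true_thr
      cfg$seed <- abr_seeds[idx] + 1L
      sim <- simulate_abr_series(cfg)
      abr[[animals[ai]]][[as.character(d)]] <- sim$series
      thr_rows[[idx]] <- data.frame(
        animal = animals[ai], group = group_of[ai], timepoint_day = d,
        true_threshold_db = true_thr)
    }
  }
  thresholds <- do.call(rbind, thr_rows)

  ## --- morphometry / densitometry arm (measurement level) ------------
  sham_cfg <- cochlea_sim_config()
  prof <- size_profile_mean(design$frequencies, sham_cfg)
  prof_shape <- prof / mean(prof)
  var_between <- stats::var(prof * 1) * (length(prof) - 1) / length(prof)
  btn_rows <- list()
  icc_cells <- eff$icc[eff$icc$group %in% design$groups, ]
  icc_seeds <- child_seeds(seeds[2], nrow(icc_cells) * design$n_per_group)
  jdx <- 0
  for (ci in seq_len(nrow(icc_cells))) {
    cell <- icc_cells[ci, ]
    for (a in seq_len(design$n_per_group)) {
      jdx <- jdx + 1
      btn_rows[[jdx]] <- with_seed(icc_seeds[jdx], {
        per_f <- lapply(seq_along(design$frequencies), function(fi) {
          nb <- stats::rpois(1, design$buttons_per_frame)
          if (nb == 0) return(NULL)
          mean_f <- cell$area_mean * prof_shape[fi]
          ## split the arm's pooled area SD into between-frequency spread
          ## (carried by the profile) and within-frame scatter
          between <- sqrt(var_between) * cell$area_mean / mean(prof)
          sd_w <- sqrt(max(cell$area_sd^2 - between^2,
                           (0.3 * cell$area_sd)^2))
          ## within-frame correlation inflated so the pooled coefficient
          ## matches the configured rho
          rho_w <- max(-0.99, min(0.99,
                                  cell$rho * cell$area_sd / sd_w))
          z1 <- stats::rnorm(nb); z2 <- stats::rnorm(nb)
          area <- pmax(0.6, mean_f + sd_w * z1)
          od <- cell$od_mean + cell$od_sd *
            (rho_w * z1 + sqrt(1 - rho_w^2) * z2)
          data.frame(
            animal = paste0(cell$group, "_", a), group = cell$group,
            timepoint_day = cell$timepoint_day,
            frequency_khz = design$frequencies[fi],
            button = seq_len(nb), area_um2 = area, norm_od = od)
        })
        do.call(rbind, per_f)
      })
    }
  }
  buttons <- do.call(rbind, btn_rows)
  rownames(buttons) <- NULL

  ## --- immune arm ----------------------------------------------------
  imm_cells <- eff$immune[eff$immune$group %in% design$groups, ]
  imm_seeds <- child_seeds(seeds[3], 1)
  immune <- with_seed(imm_seeds[1], {
    rows <- lapply(seq_len(nrow(imm_cells)), function(ci) {
      cell <- imm_cells[ci, ]
      L <- design$analyzed_length_um
      data.frame(
        animal = paste0(cell$group, "_", seq_len(design$n_per_group)),
        group = cell$group, timepoint_day = cell$timepoint_day,
        macrophages = stats::rpois(design$n_per_group,
                                   cell$macrophage_rate * L / 1000),
        monocytes = stats::rpois(design$n_per_group,
                                 cell$monocyte_rate * L / 1000),
        analyzed_length_um = L)
    })
    out <- do.call(rbind, rows)
    out$macrophages_per_1000um <- out$macrophages * 1000 /
      out$analyzed_length_um
    out$monocytes_per_1000um <- out$monocytes * 1000 /
      out$analyzed_length_um
    out
  })
  rownames(immune) <- NULL

  ## --- optional rendered frames --------------------------------------
  frames <- NULL
  if (design$render_images) {
    frm_seeds <- child_seeds(seeds[4],
                             nrow(icc_cells) * design$n_per_group *
                               length(design$frequencies))
    frames <- list(); fdx <- 0
    for (ci in seq_len(nrow(icc_cells))) {
      cell <- icc_cells[ci, ]
      for (a in seq_len(design$n_per_group)) {
        an <- paste0(cell$group, "_", a)
        for (f in design$frequencies) {
          fdx <- fdx + 1
          cfg <- cochlea_sim_config(
            area_scale = cell$area_mean / 10,
            gray_shift = 12 * (cell$od_mean - 4.30) * -1,
            seed = frm_seeds[fdx])
          key <- paste(an, cell$timepoint_day, f, sep = "|")
          frames[[key]] <- simulate_cochlea_image(cfg, f)
        }
      }
    }
  }

  structure(list(design = design, thresholds = thresholds, abr = abr,
                 buttons = buttons, immune = immune, frames = frames),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", length(x$abr), "animals x",
      length(x$design$timepoints), "timepoints;",
      nrow(x$buttons), "buttons;", nrow(x$immune), "immune rows\n")
  invisible(x)
}

#' Flatten simulated ABR waveforms to a tidy table
#'
#' @param dataset a [simulate_study()] result.
#' @return data.frame `animal`, `timepoint_day`, `level_db`, `time_ms`,
#'   `voltage_uv`.
#' @export
waveform_table <- function(dataset) {
  rows <- list()
  for (an in names(dataset$abr)) {
    for (d in names(dataset$abr[[an]])) {
      s <- dataset$abr[[an]][[d]]
      for (w in s$waveforms) {
        rows[[length(rows) + 1]] <- data.frame(
          animal = an, timepoint_day = as.numeric(d),
          level_db = w$level, time_ms = w$time, voltage_uv = w$voltage)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
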