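#' Pipeline configuration
#'
#' Bundles a [study_design()], a master seed, stage toggles and an output
#' directory into one object that [run_pipeline()] executes end-to-end.
#'
#' @param design a [study_design()] (its `seed` is overridden by `seed`).
#' @param seed master seed for the whole run.
#' @param out_dir directory for the written bundle, or `NULL` to keep the
#'   bundle in memory only.
#' @param stages named logical toggles: `abr`, `icc`, `immune`, `stats`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(), seed = 1,
                            out_dir = NULL,
                            stages = c(abr = TRUE, icc = TRUE,
                                       immune = TRUE, stats = TRUE)) {
  if (!inherits(design, "study_design"))
    stop_eq("`design` must be a `study_design`")
  check_number(seed, "seed")
  for (s in c("abr", "icc", "immune", "stats"))
    if (!s %in% names(stages)) stop_eq("missing stage toggle `", s, "`")
  if (stages[["stats"]] && !(stages[["abr"]] && stages[["icc"]]))
    stop_eq("the stats stage needs the abr and icc stages enabled")
  structure(list(design = design, seed = as.integer(seed),
                 out_dir = out_dir, stages = stages),
            class = "pipeline_config")
}

#' Run the full simulate - measure - analyze pipeline
#'
#' Simulates a study under the configured design, estimates per-animal ABR
#' thresholds from the simulated waveforms, derives threshold shifts, and
#' runs the statistics battery: per-arm Friedman (+ Dunn-Bonferroni post
#' hoc) on thresholds over timepoints, AT vs ES_AT Mann-Whitney per
#' timepoint, one-way ANOVA (Bonferroni + Games-Howell) on button area and
#' normalized OD across arms, two-way arm x frequency ANOVAs, the immune
#' count summary, and the per-arm size-OD correlation table.
#'
#' @param config a [pipeline_config()].
#' @return object of class `report_bundle`: tables `thresholds`,
#'   `shifts`, `morphometry`, `densitometry`, `immune`, `stats_results`,
#'   `correlations`; list `stat_objects` with the full [stat_result]
#'   objects; `manifest` (seed, design summary, package version).
#'   With `out_dir` set, the bundle is also written via
#'   [write_report_bundle()].
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop_eq("`config` must be a `pipeline_config`")
  design <- config$design
  design$seed <- config$seed
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_eq("stage `", name, "` failed: ", conditionMessage(e)))
  }
  dataset <- run_stage("simulate", simulate_study(design))

  thresholds <- shifts <- NULL
  if (config$stages[["abr"]]) {
    thresholds <- run_stage("abr", {
      est <- lapply(names(dataset$abr), function(an) {
        days <- names(dataset$abr[[an]])
        data.frame(
          animal = an,
          timepoint_day = as.numeric(days),
          threshold_db = vapply(days, function(d) {
            r <- estimate_threshold(dataset$abr[[an]][[d]])
            if (r$censored) NA_real_ else r$threshold
          }, numeric(1)))
      })
      est <- do.call(rbind, est)
      out <- merge(dataset$thresholds, est,
                   by = c("animal", "timepoint_day"), sort = FALSE)
      out <- out[order(out$group, out$animal, out$timepoint_day), ]
      rownames(out) <- NULL
      out
    })
    shifts <- run_stage("shifts", threshold_shift_table(thresholds))
  }

  morphometry <- densitometry <- NULL
  if (config$stages[["icc"]]) {
    morphometry <- run_stage("icc", {
      agg <- stats::aggregate(
        area_um2 ~ group + timepoint_day + frequency_khz,
        data = dataset$buttons,
        FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                            n = length(x)))
      flat <- data.frame(agg[1:3], agg$area_um2)
      names(flat)[4:6] <- c("area_mean_um2", "area_sd_um2", "n_buttons")
      flat[order(flat$group, flat$timepoint_day, flat$frequency_khz), ]
    })
    densitometry <- run_stage("densitometry", {
      agg <- stats::aggregate(
        norm_od ~ group + timepoint_day + frequency_khz,
        data = dataset$buttons,
        FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                            n = length(x)))
      flat <- data.frame(agg[1:3], agg$norm_od)
      names(flat)[4:6] <- c("norm_od_mean", "norm_od_sd", "n_buttons")
      flat[order(flat$group, flat$timepoint_day, flat$frequency_khz), ]
    })
    rownames(morphometry) <- rownames(densitometry) <- NULL
  }

  stat_objects <- list(); stats_results <- NULL; correlations <- NULL
  if (config$stages[["stats"]]) {
    run_stage("stats", {
      rows <- list()
      add <- function(analysis, scope, sr) {
        stat_objects[[paste(analysis, scope, sep = ".")]] <<- sr
        rows[[length(rows) + 1]] <<- data.frame(
          analysis = analysis, scope = scope, test = sr$test,
          statistic = sr$statistic, p_value = sr$p_value)
        if (!is.null(sr$posthoc) && "p_adj" %in% names(sr$posthoc)) {
          ph <- sr$posthoc
          rows[[length(rows) + 1]] <<- data.frame(
            analysis = analysis,
            scope = paste0(scope, ":", ph$a, "-vs-", ph$b,
                           if ("method" %in% names(ph))
                             paste0(":", ph$method) else ""),
            test = paste(sr$test, "post hoc"),
            statistic = NA_real_, p_value = ph$p_adj)
        }
      }
      ## thresholds over time within each arm
      for (g in design$groups) {
        d <- thresholds[thresholds$group == g, ]
        d <- d[!is.na(d$threshold_db), ]
        keep <- names(which(table(d$animal) == length(design$timepoints)))
        d <- d[d$animal %in% keep, ]
        if (length(keep) >= 2)
          add("thresholds_friedman", g,
              friedman_with_posthoc(d, value = "threshold_db"))
      }
      ## AT vs ES_AT at each timepoint
      if (all(c("AT", "ES_AT") %in% design$groups)) {
        for (d in design$timepoints) {
          a <- thresholds$threshold_db[thresholds$group == "AT" &
                                         thresholds$timepoint_day == d]
          b <- thresholds$threshold_db[thresholds$group == "ES_AT" &
                                         thresholds$timepoint_day == d]
          a <- a[!is.na(a)]; b <- b[!is.na(b)]
          if (length(a) && length(b))
            add("thresholds_mann_whitney", paste0("day", d),
                mann_whitney(a, b))
        }
      }
      ## ICC one-way ANOVAs across arms (arm = group x terminal day)
      btn <- dataset$buttons
      btn$arm <- paste0(btn$group, "_d", btn$timepoint_day)
      if (length(unique(btn$arm)) >= 2) {
        add("area_anova", "arms",
            anova_oneway_posthoc(btn$area_um2, btn$arm))
        add("norm_od_anova", "arms",
            anova_oneway_posthoc(btn$norm_od, btn$arm))
        add("area_anova2", "arm_x_frequency",
            anova_twoway(btn$area_um2, btn$arm, btn$frequency_khz,
                         "arm", "frequency"))
        add("norm_od_anova2", "arm_x_frequency",
            anova_twoway(btn$norm_od, btn$arm, btn$frequency_khz,
                         "arm", "frequency"))
      }
      correlations <- correlation_table(btn, group = "arm")
      stats_results <- do.call(rbind, rows)
      rownames(stats_results) <- NULL
    })
  }

  manifest <- list(
    package = "efferentquant",
    version = as.character(utils::packageVersion("efferentquant")),
    seed = config$seed,
    design = list(groups = design$groups,
                  n_per_group = design$n_per_group,
                  timepoints = design$timepoints,
                  frequencies = design$frequencies),
    stages = as.list(config$stages))

  bundle <- structure(list(
    thresholds = thresholds, shifts = shifts, morphometry = morphometry,
    densitometry = densitometry, immune = dataset$immune,
    stats_results = stats_results, correlations = correlations,
    stat_objects = stat_objects, dataset = dataset,
    manifest = manifest), class = "report_bundle")
  if (!is.null(config$out_dir))
    write_report_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (seed", x$manifest$seed, ")\n")
  for (t in c("thresholds", "shifts", "morphometry", "densitometry",
              "immune", "stats_results", "correlations")) {
    if (!is.null(x[[t]]))
      cat(sprintf("  %-14s %d rows\n", t, nrow(x[[t]])))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every table as CSV plus a JSON manifest that suffices to
#' regenerate the bundle bit-identically (seed, design, versions).
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "report_bundle"))
    stop_eq("`bundle` must be a `report_bundle`")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (t in c("thresholds", "shifts", "morphometry", "densitometry",
              "immune", "stats_results", "correlations")) {
    if (is.null(bundle[[t]])) next
    p <- file.path(dir, paste0(t, ".csv"))
    utils::write.csv(bundle[[t]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read / write 8-bit grayscale frames as PNG
#'
#' @param frame an [image_frame()].
#' @param path PNG path.
#' @return `write_frame_png` returns the path invisibly;
#'   `read_frame_png` returns an [image_frame()].
#' @export
write_frame_png <- function(frame, path) {
  if (!inherits(frame, "image_frame"))
    stop_eq("`frame` must be an `image_frame`")
  png::writePNG(round(frame$pixels) / 255, path)
  invisible(path)
}

#' @rdname write_frame_png
#' @param pixel_pitch um/pixel of the stored image.
#' @param frequency optional kHz label.
#' @export
read_frame_png <- function(path, pixel_pitch = 0.2,
                           frequency = NA_real_) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  image_frame(round(m * 255), pixel_pitch = pixel_pitch,
              frequency = frequency)
}

#' Read / write a spiral trace as CSV
#'
#' CSV with header `x_um,y_um`, points ordered apex to base.
#'
#' @param t a [spiral_trace()].
#' @param path CSV path.
#' @export
write_trace_csv <- function(t, path) {
  if (!inherits(t, "spiral_trace")) stop_eq("`t` must be a `spiral_trace`")
  utils::write.csv(data.frame(x_um = t$points[, 1], y_um = t$points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  spiral_trace(cbind(d$x_um, d$y_um))
}

#' Read a calibration table (gray, od CSV) into a curve
#'
#' @param path CSV with columns `gray`, `od` (11 rows in the standard
#'   stepped-filter protocol).
#' @return a [fit_gray_to_od()] curve.
#' @export
read_calibration_csv <- function(path) {
  fit_gray_to_od(utils::read.csv(path))
}
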