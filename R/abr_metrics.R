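#' Construct an ABR waveform
#'
#' A single averaged evoked-potential record: voltage (uV) on a uniform time
#' grid (ms) starting at stimulus onset (t = 0), tagged with its stimulus
#' level.
#'
#' @param time time grid in ms, uniform, starting at 0.
#' @param voltage voltage in uV, same length as `time`, all finite.
#' @param level stimulus level in dB SPL.
#' @param meta optional named list of labels (animal, timepoint, ear...).
#' @return an object of class `waveform`.
#' @export
waveform <- function(time, voltage, level, meta = list()) {
  if (length(time) != length(voltage) || length(time) < 2)
    stop_eq("`time` and `voltage` must have equal length >= 2")
  if (!all(is.finite(voltage))) stop_eq("`voltage` must be finite")
  dt <- diff(time)
  if (abs(time[1]) > 1e-9 || any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop_eq("`time` must be uniform and start at 0")
  structure(list(time = as.numeric(time), voltage = as.numeric(voltage),
                 level = level, meta = meta),
            class = "waveform")
}

#' Construct an ABR level series
#'
#' An ascending set of [waveform()]s, one per stimulus level, sharing a time
#' grid — the unit on which thresholds are called.
#'
#' @param waveforms list of `waveform` objects with distinct levels.
#' @return an object of class `abr_series` with elements `waveforms`
#'   (ordered by ascending level) and `levels`.
#' @export
abr_series <- function(waveforms) {
  if (length(waveforms) < 2) stop_eq("need >= 2 waveforms")
  ok <- vapply(waveforms, inherits, logical(1), "waveform")
  if (!all(ok)) stop_eq("all elements must be `waveform` objects")
  levels <- vapply(waveforms, `[[`, numeric(1), "level")
  if (anyDuplicated(levels)) stop_eq("duplicate stimulus levels")
  ord <- order(levels)
  n0 <- length(waveforms[[1]]$time)
  same <- vapply(waveforms, function(w) length(w$time) == n0, logical(1))
  if (!all(same)) stop_eq("waveforms must share one time grid")
  structure(list(waveforms = waveforms[ord], levels = levels[ord]),
            class = "abr_series")
}

#' @export
print.abr_series <- function(x, ...) {
  cat("ABR series:", length(x$levels), "levels (",
      paste(range(x$levels), collapse = "-"), "dB SPL ),",
      length(x$waveforms[[1]]$time), "samples/waveform\n")
  invisible(x)
}

#' Baseline (pre-response) statistics of a waveform
#'
#' Mean and SD of the voltage over an early window of the record that
#' precedes any possible response — by default the first millisecond, which
#' the 1.4-ms conduction delay guarantees is pure background activity. These
#' statistics anchor the mean +/- k*SD response criterion.
#'
#' @param w a [waveform()].
#' @param window numeric length-2, ms; samples in `[window[1], window[2])`
#'   are used. Default `c(0, 1)`.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return a list of class `baseline_stats`: `mean`, `sd` (uV), `window`,
#'   `n`.
#' @export
baseline_stats <- function(w, window = c(0, 1), sd_type = c("sample",
                                                            "population")) {
  sd_type <- match.arg(sd_type)
  if (!inherits(w, "waveform")) stop_eq("`w` must be a `waveform`")
  if (length(window) != 2 || window[2] <= window[1])
    stop_eq("`window` must be an increasing length-2 interval")
  idx <- w$time >= window[1] & w$time < window[2]
  if (sum(idx) < 2) stop_eq("baseline window contains < 2 samples")
  v <- w$voltage[idx]
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  structure(list(mean = mean(v), sd = s, window = window, n = length(v)),
            class = "baseline_stats")
}

#' Response detection by the baseline mean +/- k*SD criterion
#'
#' A waveform is called responsive when at least `min_run` consecutive
#' samples inside the analysis latency window deviate from the baseline mean
#' by more than `k` baseline SDs. The exceedance is two-sided: with
#' alternating-polarity clicks the sign of a "significant voltage change"
#' carries no information.
#'
#' A degenerate baseline (SD = 0) makes the criterion vacuous; by convention
#' any in-window sample differing from the baseline mean then yields a
#' response, and the result carries a `degenerate_baseline` attribute.
#'
#' @param w a [waveform()].
#' @param b a [baseline_stats()] for the same record.
#' @param window analysis latency window in ms (closed), default
#'   `c(1.4, 5)`: conduction delay to 5 ms.
#' @param k SD multiplier of the criterion (default 2).
#' @param min_run minimum number of consecutive supra-criterion samples; the
#'   default spans `min_run_ms` at the waveform's sampling rate.
#' @param min_run_ms duration used to derive the default `min_run`
#'   (default 0.2 ms; see the methods vignette for the false-positive
#'   calibration behind this choice).
#' @return logical scalar; attribute `degenerate_baseline` flags SD = 0.
#' @export
detect_response <- function(w, b, window = c(1.4, 5), k = 2,
                            min_run = NULL, min_run_ms = 0.2) {
  if (!inherits(w, "waveform")) stop_eq("`w` must be a `waveform`")
  if (!inherits(b, "baseline_stats"))
    stop_eq("`b` must be `baseline_stats`")
  if (!is.finite(b$sd)) stop_eq("baseline SD must be finite")
  dt <- w$time[2] - w$time[1]
  if (is.null(min_run)) min_run <- max(1L, ceiling(min_run_ms / dt))
  idx <- which(w$time >= window[1] & w$time <= window[2])
  if (length(idx) == 0) stop_eq("analysis window contains no samples")
  dev <- abs(w$voltage[idx] - b$mean)
  if (b$sd == 0) {
    hit <- any(dev > 0)
    return(structure(hit, degenerate_baseline = TRUE))
  }
  exc <- dev > k * b$sd
  r <- rle(exc)
  hit <- any(r$values & r$lengths >= min_run)
  structure(hit, degenerate_baseline = FALSE)
}

#' ABR threshold over an ascending level series
#'
#' The threshold is the minimal stimulus level whose waveform is called
#' responsive under the mean +/- k*SD criterion, the baseline being taken
#' from each level's own record. When no level responds the threshold is
#' censored at the maximum tested level.
#'
#' @param s an [abr_series()].
#' @param window analysis latency window in ms.
#' @param baseline_window baseline window in ms.
#' @param k SD multiplier.
#' @param min_run,min_run_ms run-length requirement, as in
#'   [detect_response()].
#' @param policy `"minimal"` (default): lowest responsive level.
#'   `"monotone"`: lowest level from which every higher level also
#'   responds, guarding against spurious low-level calls.
#' @return a list of class `threshold_result`: `threshold` (dB SPL, `NA`
#'   when censored), `censored`, `calls` (named logical per level),
#'   `criterion_k`, `policy`.
#' @export
estimate_threshold <- function(s, window = c(1.4, 5),
                               baseline_window = c(0, 1), k = 2,
                               min_run = NULL, min_run_ms = 0.2,
                               policy = c("minimal", "monotone")) {
  policy <- match.arg(policy)
  if (!inherits(s, "abr_series")) stop_eq("`s` must be an `abr_series`")
  calls <- vapply(s$waveforms, function(w) {
    b <- baseline_stats(w, window = baseline_window)
    as.logical(detect_response(w, b, window = window, k = k,
                               min_run = min_run, min_run_ms = min_run_ms))
  }, logical(1))
  names(calls) <- s$levels
  responding <- if (policy == "minimal") {
    which(calls)
  } else {
    ## lowest level such that all levels at or above it respond
    which(rev(cumprod(rev(calls))) == 1)
  }
  if (length(responding) == 0) {
    res <- list(threshold = NA_real_, censored = TRUE, calls = calls,
                criterion_k = k, policy = policy,
                max_level = max(s$levels))
  } else {
    res <- list(threshold = s$levels[min(responding)], censored = FALSE,
                calls = calls, criterion_k = k, policy = policy,
                max_level = max(s$levels))
  }
  structure(res, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$censored) {
    cat("ABR threshold: censored ( >", x$max_level, "dB SPL )\n")
  } else {
    cat("ABR threshold:", x$threshold, "dB SPL\n")
  }
  cat("  calls:", paste(names(x$calls),
                        ifelse(x$calls, "+", "-"), collapse = " "), "\n")
  invisible(x)
}

#' Wave latency and peak-to-peak amplitude measurement
#'
#' Finds local positive maxima inside the search window whose prominence
#' exceeds `prominence` (default 2 baseline SDs — the criterion scale), and
#' measures each wave as: latency = time of the positive peak; amplitude =
#' voltage difference from the nearest preceding local minimum (trough) to
#' the peak.
#'
#' @param w a [waveform()].
#' @param search_window ms interval searched for peaks, default `c(1.4, 5)`.
#' @param b optional [baseline_stats()] used for the default prominence
#'   floor; computed from `w` when missing.
#' @param prominence minimum peak prominence in uV; default `2 * b$sd`.
#' @return data.frame with one row per wave: `wave`, `latency_ms`,
#'   `peak_uv`, `trough_ms`, `trough_uv`, `amplitude_uv`. Zero rows when no
#'   peak qualifies.
#' @export
wave_metrics <- function(w, search_window = c(1.4, 5), b = NULL,
                         prominence = NULL) {
  if (!inherits(w, "waveform")) stop_eq("`w` must be a `waveform`")
  if (is.null(b)) b <- baseline_stats(w)
  if (is.null(prominence)) prominence <- 2 * b$sd
  idx <- which(w$time >= search_window[1] & w$time <= search_window[2])
  if (length(idx) < 3) stop_eq("search window too small")
  v <- w$voltage
  ## local maxima strictly above both neighbours (plateau-free signals)
  cand <- idx[idx > 1 & idx < length(v)]
  cand <- cand[v[cand] > v[cand - 1] & v[cand] >= v[cand + 1]]
  out <- list()
  for (p in cand) {
    ## nearest preceding local minimum (search back from the peak)
    i <- p
    while (i > 2 && v[i - 1] <= v[i]) i <- i - 1
    trough <- i
    ## prominence proxy: height above that trough
    amp <- v[p] - v[trough]
    if (amp <= prominence) next
    out[[length(out) + 1]] <- data.frame(
      latency_ms = w$time[p], peak_uv = v[p],
      trough_ms = w$time[trough], trough_uv = v[trough],
      amplitude_uv = amp)
  }
  if (length(out) == 0) {
    return(data.frame(wave = integer(), latency_ms = numeric(),
                      peak_uv = numeric(), trough_ms = numeric(),
                      trough_uv = numeric(), amplitude_uv = numeric()))
  }
  res <- do.call(rbind, out)
  res <- cbind(wave = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Per-animal threshold shifts relative to the pre-treatment baseline
#'
#' For each animal, the shift at protocol day t is threshold(t) minus the
#' day-0 threshold. Censored thresholds propagate as censored shifts
#' (`NA` shift, `censored = TRUE`). Animals lacking a day-0 record are
#' dropped with a warning.
#'
#' @param thresholds data.frame with columns `animal`, `group`,
#'   `timepoint_day`, `threshold_db` (NA when censored).
#' @param baseline_day day defining the pre-treatment baseline (default 0).
#' @return data.frame `animal`, `group`, `timepoint_day`, `threshold_db`,
#'   `baseline_db`, `shift_db`, `censored`.
#' @export
threshold_shift_table <- function(thresholds, baseline_day = 0) {
  need <- c("animal", "group", "timepoint_day", "threshold_db")
  if (!all(need %in% names(thresholds)))
    stop_eq("`thresholds` must have columns ",
            paste(need, collapse = ", "))
  base <- thresholds[thresholds$timepoint_day == baseline_day, ]
  if (anyDuplicated(base$animal))
    stop_eq("multiple baseline rows for one animal")
  missing_base <- setdiff(unique(thresholds$animal), base$animal)
  if (length(missing_base) > 0) {
    warning("excluding animals without a day-", baseline_day,
            " threshold: ", paste(missing_base, collapse = ", "),
            call. = FALSE)
    thresholds <- thresholds[!thresholds$animal %in% missing_base, ]
  }
  bl <- stats::setNames(base$threshold_db, base$animal)
  out <- thresholds
  out$baseline_db <- unname(bl[as.character(out$animal)])
  out$shift_db <- out$threshold_db - out$baseline_db
  out$censored <- is.na(out$threshold_db) | is.na(out$baseline_db)
  rownames(out) <- NULL
  out
}

#' Zero-phase bandpass for raw (unfiltered) ABR records
#'
#' Acquisition-grade records are normally already bandpassed (500-3000 Hz
#' here); this forward-backward Butterworth filter is provided for raw
#' inputs only and is applied nowhere by default.
#'
#' @param w a [waveform()].
#' @param low,high band edges in Hz.
#' @param order Butterworth order (per pass).
#' @return a filtered [waveform()].
#' @export
bandpass_waveform <- function(w, low = 500, high = 3000, order = 2) {
  if (!inherits(w, "waveform")) stop_eq("`w` must be a `waveform`")
  fs <- 1000 / (w$time[2] - w$time[1])       # Hz
  wn <- c(low, high) / (fs / 2)
  if (any(wn <= 0) || any(wn >= 1)) stop_eq("band outside Nyquist range")
  bf <- signal::butter(order, wn, type = "pass")
  v <- signal::filtfilt(bf, w$voltage)
  waveform(w$time, v, w$level, w$meta)
}
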