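#' Construct a thrombin generation curve
#'
#' A `thrombin_curve` is a sampled free-thrombin concentration time series,
#' the primary output of a thrombin generation (TG) assay and the measured
#' input of thrombin dynamics analysis. Time is in minutes, thrombin in nM.
#'
#' Small negative thrombin values (baseline noise) are allowed down to
#' `-noise_floor` and flagged; they are preserved in the stored curve and only
#' clipped where a computation requires a non-negative concentration.
#'
#' @param time Numeric vector of sampling times in minutes, strictly
#'   increasing, first point >= 0.
#' @param thrombin Numeric vector of free-thrombin concentrations in nM, same
#'   length as `time`, all finite.
#' @param sample_id Sample identifier (single string).
#' @param reagent Trigger reagent class: `"bleed"` (low tissue factor),
#'   `"thrombo"` (intermediate), or `"drug"` (high).
#' @param tm_present Logical; was thrombomodulin present in the trigger?
#' @param replicate Replicate number (integer >= 1).
#' @param noise_floor Largest tolerated negative excursion in nM (baseline
#'   noise), default 25 (about five standard deviations of typical
#'   instrument noise). Values below `-noise_floor` are an error.
#' @param truncated Logical; set `TRUE` to acknowledge that the record ends
#'   before the thrombin peak (otherwise a peak at the last sample is an
#'   error, since descriptive parameters would be meaningless).
#'
#' @return An object of class `thrombin_curve`: a list with elements `time`,
#'   `thrombin`, `sample_id`, `reagent`, `tm_present`, `replicate`, and
#'   `flags` (character vector; may contain `"negative_baseline"` and/or
#'   `"truncated"`).
#' @examples
#' tc <- thrombin_curve(seq(0, 20, 0.5),
#'                      300 * dgamma(seq(0, 20, 0.5), 4, 2),
#'                      sample_id = "HD001")
#' print(tc)
#' @export
thrombin_curve <- function(time, thrombin, sample_id = "sample",
                           reagent = c("bleed", "thrombo", "drug"),
                           tm_present = FALSE, replicate = 1L,
                           noise_floor = 25, truncated = FALSE) {
  reagent <- match.arg(reagent)
  time <- as.numeric(time)
  thrombin <- as.numeric(thrombin)
  if (length(time) != length(thrombin))
    stop("`time` and `thrombin` must have the same length")
  if (length(time) < 8L)
    stop("a thrombin curve needs at least 8 samples, got ", length(time))
  if (anyNA(time) || anyNA(thrombin) || any(!is.finite(thrombin)))
    stop("`time` and `thrombin` must be finite and non-missing")
  dt <- diff(time)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    stop("`time` must be strictly increasing; offending index ", i + 1L,
         " (t = ", time[i + 1L], " after t = ", time[i], ")")
  }
  if (time[1L] < 0) stop("first time point must be >= 0, got ", time[1L])
  if (any(thrombin < -noise_floor))
    stop("thrombin below -noise_floor (", -noise_floor, " nM): minimum is ",
         signif(min(thrombin), 4), " nM")
  flags <- character()
  if (any(thrombin < 0)) flags <- c(flags, "negative_baseline")
  pk <- which.max(thrombin)
  if (pk == length(thrombin) && max(thrombin) > 0) {
    if (!truncated)
      stop("thrombin maximum falls on the last sample; the record does not ",
           "cover the peak (pass `truncated = TRUE` to accept)")
    flags <- c(flags, "truncated")
  }
  structure(
    list(time = time, thrombin = thrombin, sample_id = as.character(sample_id),
         reagent = reagent, tm_present = isTRUE(tm_present),
         replicate = as.integer(replicate), flags = flags),
    class = "thrombin_curve")
}

#' @export
print.thrombin_curve <- function(x, ...) {
  cat(sprintf(
    "<thrombin_curve> %s | %s%s | rep %d | %d pts, %.2f-%.2f min, peak %.1f nM%s\n",
    x$sample_id, x$reagent, if (x$tm_present) "+TM" else "", x$replicate,
    length(x$time), x$time[1L], x$time[length(x$time)], max(x$thrombin),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

# uniform-grid check shared by downstream operations
is_uniform_grid <- function(time, tol = 1e-8) {
  dt <- diff(time)
  diff(range(dt)) <= tol * max(dt)
}

grid_dt <- function(curve) {
  dt <- diff(curve$time)
  if (!is_uniform_grid(curve$time))
    stop("curve is not on a uniform time grid; call resample_uniform() first")
  mean(dt)
}

#' Resample a thrombin curve onto a uniform grid
#'
#' Monotone piecewise-cubic (Fritsch--Carlson Hermite) interpolation onto the
#' grid `t0, t0 + dt, ...`, preserving endpoints and metadata. Monotone
#' Hermite interpolation reproduces affine segments exactly and introduces no
#' overshoot between samples.
#'
#' @param curve A [thrombin_curve()].
#' @param dt Target grid spacing in minutes; must be positive and at most
#'   twice the median input spacing (coarser resampling would discard signal).
#' @return A [thrombin_curve()] on the uniform grid.
#' @export
resample_uniform <- function(curve, dt) {
  stopifnot(inherits(curve, "thrombin_curve"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number of minutes")
  med <- stats::median(diff(curve$time))
  if (dt > 2 * med)
    stop("`dt` = ", dt, " is coarser than twice the median input spacing (",
         signif(med, 4), " min)")
  grid <- seq(curve$time[1L], curve$time[length(curve$time)], by = dt)
  f <- stats::splinefun(curve$time, curve$thrombin, method = "monoH.FC")
  out <- curve
  out$time <- grid
  out$thrombin <- f(grid)
  out
}

#' Average replicate thrombin curves point-wise
#'
#' Replicate runs of the same sample/condition are resampled to a common
#' uniform grid and averaged point-wise, mirroring the instrument convention
#' of reporting a mean result for duplicates.
#'
#' @param curves List of [thrombin_curve()] objects with identical
#'   `sample_id`, `reagent` and `tm_present`.
#' @param dt Common grid spacing in minutes; default: the smallest median
#'   spacing among the replicates.
#' @return A single [thrombin_curve()] with `replicate = 1`.
#' @export
average_replicates <- function(curves, dt = NULL) {
  stopifnot(length(curves) >= 1L, all(vapply(curves, inherits, TRUE, "thrombin_curve")))
  key <- vapply(curves, function(cv) paste(cv$sample_id, cv$reagent, cv$tm_present), "")
  if (length(unique(key)) != 1L)
    stop("replicates to average must share sample_id, reagent and tm_present")
  if (length(curves) == 1L) return(curves[[1L]])
  if (is.null(dt))
    dt <- min(vapply(curves, function(cv) stats::median(diff(cv$time)), 0))
  t0 <- max(vapply(curves, function(cv) cv$time[1L], 0))
  t1 <- min(vapply(curves, function(cv) cv$time[length(cv$time)], 0))
  grid <- seq(t0, t1, by = dt)
  ys <- vapply(curves, function(cv) {
    stats::splinefun(cv$time, cv$thrombin, method = "monoH.FC")(grid)
  }, numeric(length(grid)))
  out <- curves[[1L]]
  out$time <- grid
  out$thrombin <- rowMeans(ys)
  out$replicate <- 1L
  out$flags <- unique(unlist(lapply(curves, `[[`, "flags")))
  out
}

#' Descriptive thrombin generation parameters
#'
#' Computes the standard TG curve parameters: lag time, peak height,
#' time-to-peak, endogenous thrombin potential (ETP; trapezoidal area under
#' the curve) and velocity index (peak / (time-to-peak - lag)).
#'
#' The lag time is the first time the thrombin signal reaches
#' `max(threshold_nM, peak_fraction * peak)`, linearly interpolated between
#' the bracketing samples. Instrument-internal definitions are proprietary;
#' both knobs are configurable. Negative samples (baseline noise) are clipped
#' to 0 for ETP and lag detection only; the stored curve is untouched.
#'
#' If the curve carries visible measurement noise (estimated baseline noise
#' above 0.5 nM, see [estimate_noise_sd()]), the parameters are computed on
#' a Savitzky--Golay smoothed copy and the result is flagged `"smoothed"`:
#' otherwise random baseline excursions trip the lag threshold early and
#' clipping noise at zero biases the ETP upward. Quiet curves are used
#' as-is, so exact geometric signals give exact parameters.
#'
#' @param curve A [thrombin_curve()] on a uniform grid.
#' @param threshold_nM Absolute lag threshold in nM (default 2).
#' @param peak_fraction Relative lag threshold as a fraction of the peak
#'   (default 0.05). Set both to 0 only if you want lag at the first nonzero
#'   sample.
#' @return An object of class `tg_parameters`: list with `lag_time`, `peak`,
#'   `time_to_peak`, `etp`, `velocity_index` and `flags`. For an all-zero
#'   (or never-above-threshold) curve the time parameters are `NA` and the
#'   result carries flag `"degenerate"`; a truncated curve carries
#'   `"truncated"`.
#' @examples
#' tt <- seq(0, 15, 0.1)
#' tri <- ifelse(tt < 2, 0, ifelse(tt < 5, (tt - 2) * 100, 300 * (15 - tt) / 10))
#' p <- tg_parameters(thrombin_curve(tt, tri))
#' p$etp  # 1950 nM*min
#' @export
tg_parameters <- function(curve, threshold_nM = 2, peak_fraction = 0.05) {
  stopifnot(inherits(curve, "thrombin_curve"))
  dt <- grid_dt(curve)
  tt <- curve$time
  flags <- character()
  y <- curve$thrombin
  if (estimate_noise_sd(y) > 0.5) {
    w <- choose_derivative_window(y, dt, length(y))
    y <- signal::sgolayfilt(y, p = 3, n = w)
    flags <- c(flags, "smoothed")
  }
  y <- pmax(y, 0)
  etp <- sum((y[-1L] + y[-length(y)]) / 2) * dt
  peak <- max(y)
  ipk <- which.max(y)
  if (peak <= 0) {
    out <- list(lag_time = NA_real_, peak = 0, time_to_peak = NA_real_,
                etp = 0, velocity_index = NA_real_, flags = "degenerate")
    return(structure(out, class = "tg_parameters"))
  }
  if (ipk == length(y)) flags <- c(flags, "truncated")
  ttp <- tt[ipk]
  thr <- max(threshold_nM, peak_fraction * peak)
  above <- which(y >= thr)
  if (!length(above)) {
    lag <- NA_real_
    flags <- c(flags, "degenerate")
  } else {
    i <- above[1L]
    if (i == 1L) {
      lag <- tt[1L]
    } else {
      # linear interpolation between bracketing samples
      lag <- tt[i - 1L] + (thr - y[i - 1L]) / (y[i] - y[i - 1L]) * dt
    }
  }
  vi <- if (!is.na(lag) && (ttp - lag) > 0) peak / (ttp - lag) else NA_real_
  structure(list(lag_time = lag, peak = peak, time_to_peak = ttp, etp = etp,
                 velocity_index = vi, flags = flags),
            class = "tg_parameters")
}

#' @export
print.tg_parameters <- function(x, ...) {
  cat(sprintf(
    "<tg_parameters> lag %.2f min | peak %.1f nM | ttp %.2f min | ETP %.0f nM*min | VI %.1f nM/min%s\n",
    x$lag_time, x$peak, x$time_to_peak, x$etp, x$velocity_index,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Normalize a result against the run's reference plasma
#'
#' Automated TG analyzers report each parameter relative to a reference
#' plasma run in parallel: `sample / reference * assigned activity` for the
#' reference lot.
#'
#' @param sample_value Parameter value for the sample.
#' @param reference_value Same parameter for the reference plasma; must be
#'   positive.
#' @param assigned_activity Activity assigned to the reference lot for this
#'   parameter.
#' @return The normalized value.
#' @examples
#' normalize_result(168, 150, 100)  # 112
#' @export
normalize_result <- function(sample_value, reference_value, assigned_activity) {
  if (!is.numeric(reference_value) || any(reference_value <= 0))
    stop("invalid reference run: reference_value must be > 0")
  sample_value / reference_value * assigned_activity
}

#' ETP inhibition by thrombomodulin
#'
#' Percent reduction of the endogenous thrombin potential when thrombomodulin
#' is added to the trigger, probing the activated protein C pathway.
#'
#' @param etp_no_tm ETP without thrombomodulin (nM*min), must be > 0.
#' @param etp_tm ETP with thrombomodulin (nM*min), >= 0.
#' @return Percent inhibition, `(1 - etp_tm/etp_no_tm) * 100`. A negative
#'   value (TM paradoxically raising ETP) is returned with a warning.
#' @examples
#' etp_inhibition(1000, 530)  # 47
#' @export
etp_inhibition <- function(etp_no_tm, etp_tm) {
  if (any(etp_no_tm <= 0)) stop("`etp_no_tm` must be > 0")
  if (any(etp_tm < 0)) stop("`etp_tm` must be >= 0")
  out <- (1 - etp_tm / etp_no_tm) * 100
  if (any(out < 0))
    warning("negative ETP inhibition: thrombomodulin raised the ETP")
  out
}
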