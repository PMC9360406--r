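#' Batch analysis configuration
#'
#' Collects every knob of the batch pipeline so that a run is fully
#' reproducible from its configuration: inputs, lag rule, smoothing,
#' rate model, tail handling, seed and output formats. The resolved
#' configuration is embedded in every output artifact.
#'
#' @param curves Path to a long-format curve file (see [read_curves()]) or a
#'   list of [thrombin_curve()] objects.
#' @param factors Path to a factor table (see [read_factors()]) or a data
#'   frame.
#' @param output_dir Directory for result files, or `NULL` to skip writing.
#' @param lag_rule List with `threshold_nM` and `peak_fraction`, see
#'   [tg_parameters()].
#' @param smoothing List with `window` (samples, or `NULL` for
#'   noise-adaptive) and `degree`.
#' @param model A [rate_model()] or a path to a YAML/JSON rate-model file.
#' @param tail List with `mode` (`"auto"`/`"on"`/`"off"`), `threshold`,
#'   `horizon_halflives`.
#' @param group_comparisons If `TRUE` and the factor table has `sex` and
#'   `oc_use` columns, compare men / women without OC / women with OC per
#'   parameter and condition.
#' @param seed Integer seed recorded for provenance.
#' @return Object of class `run_config`.
#' @export
run_config <- function(curves, factors, output_dir = NULL,
                       lag_rule = list(threshold_nM = 2, peak_fraction = 0.05),
                       smoothing = list(window = NULL, degree = 3),
                       model = rate_model(),
                       tail = list(mode = "auto", threshold = 0.01,
                                   horizon_halflives = 10),
                       group_comparisons = FALSE, seed = 1L) {
  if (is.character(model)) model <- read_rate_model(model)
  stopifnot(inherits(model, "rate_model"),
            is.numeric(lag_rule$threshold_nM), is.numeric(lag_rule$peak_fraction),
            tail$mode %in% c("auto", "on", "off"))
  structure(list(curves = curves, factors = factors, output_dir = output_dir,
                 lag_rule = lag_rule, smoothing = smoothing, model = model,
                 tail = tail, group_comparisons = isTRUE(group_comparisons),
                 seed = as.integer(seed)),
            class = "run_config")
}

serialize_config <- function(config) {
  list(lag_rule = config$lag_rule,
       smoothing = config$smoothing,
       model = unclass(config$model),
       tail = config$tail,
       group_comparisons = config$group_comparisons,
       seed = config$seed,
       package_version = as.character(utils::packageVersion("thrombodyn")))
}

oc_group <- function(sex, oc_use) {
  ifelse(sex == "M", "men", ifelse(oc_use, "women_oc", "women_no_oc"))
}

td_parameter_names <- function() c("pc_tot", "pc_max", "t_at", "t_a2m", "tdc")

#' Run the batch thrombin dynamics pipeline
#'
#' High-throughput analysis of a set of TG curves: replicates are averaged,
#' curves are joined to the plasma-factor table on `sample_id`, and every
#' sample x condition gives one row of descriptive TG parameters and TD
#' parameters. Cohort-level outputs are a median/IQR summary, a reference
#' range (2.5th/97.5th percentile) per parameter and condition, per-subject
#' ETP inhibition by thrombomodulin where both `thrombo` conditions are
#' present, and optional sex/OC group comparisons.
#'
#' Results are returned, and -- if `output_dir` is set -- written as
#' `results.csv`, `etp_inhibition.csv` and `summary.json`, each embedding
#' the resolved configuration and package version.
#'
#' @param config A [run_config()].
#' @return List with `results` (per sample x condition data frame),
#'   `etp_inhibition`, `summary` (median/IQR per condition), `ranges`
#'   (reference ranges per condition and TD parameter), `comparisons`
#'   (group comparisons or `NULL`), `skipped` (sample ids without factors),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  curves <- if (is.character(config$curves)) read_curves(config$curves)
            else config$curves
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "thrombin_curve")))
  factors <- if (is.character(config$factors)) read_factors(config$factors)
             else config$factors
  stopifnot(is.data.frame(factors))

  # average replicates within (sample, reagent, tm)
  key <- vapply(curves, function(cv)
    paste(cv$sample_id, cv$reagent, cv$tm_present, sep = "\r"), "")
  curves <- lapply(split(curves, key), function(group) {
    if (length(group) > 1L) average_replicates(group) else group[[1L]]
  })

  ids <- vapply(curves, `[[`, "", "sample_id")
  known <- ids %in% factors$sample_id
  skipped <- sort(unique(ids[!known]))
  if (length(skipped))
    warning("no plasma factors for sample(s): ",
            paste(skipped, collapse = ", "), " -- skipped")
  curves <- curves[known]
  if (!length(curves))
    stop("empty join: no curve has a matching row in the factor table")

  n_flagged <- 0L
  rows <- lapply(curves, function(cv) {
    f <- factors[match(cv$sample_id, factors$sample_id), ]
    pf <- plasma_factors(f$at_pct, f$a2m_uM, f$fib_gL)
    res <- withCallingHandlers(thrombin_dynamics(
      cv, pf, config$model,
      lag_threshold_nM = config$lag_rule$threshold_nM,
      lag_peak_fraction = config$lag_rule$peak_fraction,
      window = config$smoothing$window, degree = config$smoothing$degree,
      tail = config$tail$mode, tail_threshold = config$tail$threshold,
      horizon_halflives = config$tail$horizon_halflives),
      # per-curve noise flags are kept in the result table; summarize once
      warning = function(w) {
        if (grepl("conversion-rate mass", conditionMessage(w))) {
          n_flagged <<- n_flagged + 1L
          invokeRestart("muffleWarning")
        }
      })
    data.frame(
      sample_id = cv$sample_id, reagent = cv$reagent,
      tm_present = cv$tm_present,
      condition = paste0(cv$reagent, if (cv$tm_present) "_tm" else ""),
      lag_time = res$tg$lag_time, peak = res$tg$peak,
      time_to_peak = res$tg$time_to_peak, etp = res$tg$etp,
      velocity_index = res$tg$velocity_index,
      pc_tot = res$td$pc_tot, pc_max = res$td$pc_max,
      t_at = res$td$t_at, t_a2m = res$td$t_a2m, tdc = res$td$tdc,
      negative_mass_fraction = res$td$diagnostics$negative_mass_fraction,
      window = res$td$diagnostics$window,
      tail_extended = res$td$diagnostics$tail_extended,
      flags = paste(unique(c(cv$flags, res$tg$flags)), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results <- results[order(results$sample_id, results$condition), ]
  rownames(results) <- NULL
  if (n_flagged > 0L)
    message(n_flagged, " curve(s) carry > 5% negative conversion-rate mass ",
            "(see the negative_mass_fraction column)")

  # per-subject ETP inhibition by TM (thrombo reagent with and without TM)
  no_tm <- results[results$condition == "thrombo", c("sample_id", "etp")]
  with_tm <- results[results$condition == "thrombo_tm", c("sample_id", "etp")]
  etp_inh <- merge(no_tm, with_tm, by = "sample_id",
                   suffixes = c("_no_tm", "_tm"))
  etp_inh$etp_inhibition_pct <- if (nrow(etp_inh))
    suppressWarnings(etp_inhibition(etp_inh$etp_no_tm, etp_inh$etp_tm))
  else numeric(0)

  params <- c("lag_time", "peak", "time_to_peak", "etp", "velocity_index",
              td_parameter_names())
  summary_tab <- do.call(rbind, lapply(split(results, results$condition),
    function(d) {
      do.call(rbind, lapply(params, function(p) {
        m <- med_iqr(d[[p]][!is.na(d[[p]])])
        data.frame(condition = d$condition[1L], parameter = p,
                   n = sum(!is.na(d[[p]])), median = m[["median"]],
                   q1 = m[["q1"]], q3 = m[["q3"]], stringsAsFactors = FALSE)
      }))
    }))
  rownames(summary_tab) <- NULL

  ranges <- do.call(rbind, lapply(split(results, results$condition),
    function(d) {
      do.call(rbind, lapply(td_parameter_names(), function(p) {
        rr <- tryCatch(reference_range(d[[p]]),
                       error = function(e) list(median = NA_real_,
                                                p2_5 = NA_real_,
                                                p97_5 = NA_real_,
                                                n = sum(!is.na(d[[p]]))))
        data.frame(condition = d$condition[1L], parameter = p, n = rr$n,
                   median = rr$median, p2_5 = rr$p2_5, p97_5 = rr$p97_5,
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(ranges) <- NULL

  comparisons <- NULL
  if (config$group_comparisons &&
      all(c("sex", "oc_use") %in% names(factors))) {
    grp <- oc_group(factors$sex, factors$oc_use)[
      match(results$sample_id, factors$sample_id)]
    comparisons <- list()
    for (cond in unique(results$condition)) {
      for (p in td_parameter_names()) {
        sel <- results$condition == cond & !is.na(results[[p]])
        cmp <- tryCatch(compare_groups(results[[p]][sel], grp[sel]),
                        error = function(e) NULL)
        if (!is.null(cmp)) comparisons[[paste(cond, p, sep = ".")]] <- cmp
      }
    }
  }

  out <- list(results = results, etp_inhibition = etp_inh,
              summary = summary_tab, ranges = ranges,
              comparisons = comparisons, skipped = skipped,
              config = config)
  if (!is.null(config$output_dir)) write_pipeline_outputs(out)
  out
}

write_pipeline_outputs <- function(out) {
  dir <- out$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- serialize_config(out$config)
  cfg_line <- paste0("# config: ",
                     jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  write_stamped_csv <- function(d, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(cfg_line, con)
    utils::write.csv(d, con, row.names = FALSE)
  }
  write_stamped_csv(out$results, file.path(dir, "results.csv"))
  write_stamped_csv(out$etp_inhibition, file.path(dir, "etp_inhibition.csv"))
  summary_json <- list(
    config = cfg,
    summary = out$summary,
    reference_ranges = out$ranges,
    etp_inhibition_median_pct =
      if (nrow(out$etp_inhibition))
        stats::median(out$etp_inhibition$etp_inhibition_pct) else NULL,
    skipped_samples = out$skipped,
    comparisons = lapply(out$comparisons, function(cmp)
      list(statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
           pairwise = cmp$pairwise)))
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
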