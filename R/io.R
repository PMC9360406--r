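#' Read thrombin curves from a delimited text file (long format)
#'
#' Default dialect: comma-separated, period decimal mark, one row per sample
#' point with columns `sample_id`, `reagent` (`bleed`/`thrombo`/`drug`),
#' `tm` (logical or 0/1), `replicate`, `time_min`, `thrombin_nM`. Rows with
#' non-numeric time or thrombin are skipped and counted; structural problems
#' (missing columns, duplicate time points within a curve) are hard errors.
#'
#' @param path File to read.
#' @param sep Field separator (default `","`).
#' @param dec Decimal mark (default `"."`).
#' @param columns Named list mapping the roles `sample_id`, `reagent`, `tm`,
#'   `replicate`, `time`, `thrombin` to header names in the file.
#' @param noise_floor Passed to [thrombin_curve()].
#' @return List of [thrombin_curve()] objects, with attributes `n_rows`
#'   (rows read) and `n_skipped` (malformed rows dropped).
#' @export
read_curves <- function(path, sep = ",", dec = ".",
                        columns = list(sample_id = "sample_id",
                                       reagent = "reagent", tm = "tm",
                                       replicate = "replicate",
                                       time = "time_min",
                                       thrombin = "thrombin_nM"),
                        noise_floor = 25) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- unlist(columns)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("curve file is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  tm_raw <- tolower(raw[[columns$tm]])
  parsed <- data.frame(
    sample_id = raw[[columns$sample_id]],
    reagent = raw[[columns$reagent]],
    tm = tm_raw %in% c("true", "1", "t", "yes"),
    replicate = suppressWarnings(as.integer(raw[[columns$replicate]])),
    time = suppressWarnings(as.numeric(chartr(dec, ".", raw[[columns$time]]))),
    thrombin = suppressWarnings(as.numeric(chartr(dec, ".", raw[[columns$thrombin]]))),
    stringsAsFactors = FALSE)
  bad <- !stats::complete.cases(parsed[c("time", "thrombin", "replicate")])
  n_skipped <- sum(bad)
  if (n_skipped)
    warning(n_skipped, " malformed row(s) skipped in ", basename(path))
  parsed <- parsed[!bad, , drop = FALSE]
  if (!nrow(parsed)) stop("no valid data rows in ", path)
  key <- interaction(parsed$sample_id, parsed$reagent, parsed$tm,
                     parsed$replicate, drop = TRUE)
  curves <- lapply(split(parsed, key), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    if (anyDuplicated(d$time))
      stop("duplicate time points for (", d$sample_id[1L], ", ",
           d$reagent[1L], ", tm=", d$tm[1L], ", rep ", d$replicate[1L],
           "): duplicate (sample, condition, replicate) rows?")
    thrombin_curve(d$time, d$thrombin, sample_id = d$sample_id[1L],
                   reagent = d$reagent[1L], tm_present = d$tm[1L],
                   replicate = d$replicate[1L], noise_floor = noise_floor,
                   truncated = TRUE)
  })
  names(curves) <- NULL
  attr(curves, "n_rows") <- nrow(raw)
  attr(curves, "n_skipped") <- n_skipped
  curves
}

#' Read thrombin curves from a wide-format export
#'
#' Some instrument exports put time in the first column and one curve per
#' subsequent column. All curves share the metadata given in the arguments;
#' column headers become sample ids.
#'
#' @inheritParams read_curves
#' @param reagent,tm_present,replicate Metadata applied to every column.
#' @return List of [thrombin_curve()] objects.
#' @export
read_curves_wide <- function(path, sep = ",", dec = ".", reagent = "bleed",
                             tm_present = FALSE, replicate = 1L,
                             noise_floor = 25) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                         check.names = FALSE)
  if (ncol(d) < 2L) stop("wide curve file needs a time column plus >= 1 curve")
  tt <- as.numeric(d[[1L]])
  if (anyNA(tt)) stop("non-numeric values in the time column of ", path)
  lapply(names(d)[-1L], function(id) {
    thrombin_curve(tt, as.numeric(d[[id]]), sample_id = id, reagent = reagent,
                   tm_present = tm_present, replicate = replicate,
                   noise_floor = noise_floor, truncated = TRUE)
  })
}

#' Write thrombin curves to a long-format delimited file
#'
#' Inverse of [read_curves()]; `read_curves(write_curves(x, f))` reproduces
#' the values to full double precision.
#'
#' @param curves List of [thrombin_curve()] objects.
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, sep = ",") {
  stopifnot(all(vapply(curves, inherits, TRUE, "thrombin_curve")))
  rows <- lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, reagent = cv$reagent,
               tm = cv$tm_present, replicate = cv$replicate,
               time_min = cv$time, thrombin_nM = cv$thrombin,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  utils::write.table(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-sample plasma-factor table
#'
#' Delimited text with columns `sample_id`, `at_pct`, `a2m_uM`, `fib_gL`
#' and optional covariates `sex`, `oc_use`.
#'
#' @inheritParams read_curves
#' @return Data frame.
#' @export
read_factors <- function(path, sep = ",", dec = ".") {
  if (!file.exists(path)) stop("factor table not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "at_pct", "a2m_uM", "fib_gL")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("factor table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in factor table")
  d
}

#' Write a cohort's curves and factor table to a directory
#'
#' Convenience exporter for a [generate_cohort()] result: `curves.csv`
#' (long format), `factors.csv`, and `truth.csv`.
#'
#' @param cohort A `td_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "td_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_curves(cohort$curves, file.path(dir, "curves.csv"))
  fac <- cohort$factors
  names(fac)[names(fac) == "subject_id"] <- "sample_id"  # analyze-ready
  utils::write.csv(fac, file.path(dir, "factors.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
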