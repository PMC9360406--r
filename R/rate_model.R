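#' Plasma inhibitor and fibrinogen levels
#'
#' The three measured plasma quantities that close the thrombin inactivation
#' model: antithrombin (AT, in % of normal activity), alpha-2-macroglobulin
#' (a2M, in micromolar) and fibrinogen (g/L). AT is converted to molar units
#' through `at_nM_per_pct` of the [rate_model()].
#'
#' @param at_pct Antithrombin activity in % of normal, in `[0, 250]`.
#' @param a2m_uM Alpha-2-macroglobulin in uM, >= 0.
#' @param fib_gL Fibrinogen in g/L, >= 0.
#' @return An object of class `plasma_factors`.
#' @examples
#' plasma_factors(113, 2.6, 2.9)  # cohort medians of a healthy population
#' @export
plasma_factors <- function(at_pct, a2m_uM, fib_gL) {
  stopifnot(is.numeric(at_pct), is.numeric(a2m_uM), is.numeric(fib_gL),
            length(at_pct) == 1L, length(a2m_uM) == 1L, length(fib_gL) == 1L)
  if (at_pct < 0 || at_pct > 250)
    stop("`at_pct` outside the plausible range [0, 250]: ", at_pct)
  if (a2m_uM < 0) stop("`a2m_uM` must be >= 0")
  if (fib_gL < 0) stop("`fib_gL` must be >= 0")
  structure(list(at_pct = at_pct, a2m_uM = a2m_uM, fib_gL = fib_gL),
            class = "plasma_factors")
}

#' Kinetic model of thrombin inactivation
#'
#' Bundles the second-order rate constants for thrombin inhibition by
#' antithrombin (`k_at_ref`) and alpha-2-macroglobulin (`k_a2m_ref`) at the
#' reference fibrinogen level, the fibrinogen dependence of both constants
#' (fibrin(ogen) binds thrombin and shields it from its inhibitors, so the
#' effective constants decrease with fibrinogen), the conversion from AT
#' %-activity to nM, and the inhibitor-depletion mode.
#'
#' The numeric defaults are calibration placeholders, not published
#' constants: they are chosen so that median healthy plasma (AT 113%,
#' a2M 2.6 uM, fibrinogen 2.9 g/L) yields a thrombin decay capacity of about
#' 0.9 /min and an initial AT:a2M inactivation flux ratio of about 30:1,
#' the regime in which healthy-donor TG curves and complex splits live.
#' Override them from a calibration of your own system, e.g. via
#' [read_rate_model()].
#'
#' @param k_at_ref AT rate constant at reference fibrinogen, nM^-1 min^-1.
#' @param k_a2m_ref a2M rate constant at reference fibrinogen, nM^-1 min^-1.
#' @param fib_dependence `"saturating"` for
#'   `g(fib) = 1 / (1 + beta * (fib - fib_ref))` clipped to `(0, 1]`, or
#'   `"constant"` for no fibrinogen effect (`g == 1`).
#' @param beta Strength of the fibrinogen dependence (per g/L).
#' @param fib_ref Reference fibrinogen (g/L) at which `g = 1`.
#' @param at_nM_per_pct nM of antithrombin per 1% activity (normal plasma AT
#'   is roughly 2.4 uM, hence the default 24 nM/%).
#' @param stoichiometric_depletion If `TRUE` (default) inhibitors are consumed
#'   1:1 by complex formation, honoring the time-dependent `[AT]_t`,
#'   `[a2M]_t` of the model equations; if `FALSE` inhibitors stay at their
#'   initial level ("excess" mode), which makes thrombin decay exactly
#'   exponential and is used for closed-form verification.
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(k_at_ref = 3.2e-4, k_a2m_ref = 9.7e-6,
                       fib_dependence = c("saturating", "constant"),
                       beta = 0.1, fib_ref = 2.9, at_nM_per_pct = 24,
                       stoichiometric_depletion = TRUE) {
  fib_dependence <- match.arg(fib_dependence)
  stopifnot(k_at_ref >= 0, k_a2m_ref >= 0, beta >= 0, fib_ref > 0,
            at_nM_per_pct > 0)
  structure(list(k_at_ref = k_at_ref, k_a2m_ref = k_a2m_ref,
                 fib_dependence = fib_dependence, beta = beta,
                 fib_ref = fib_ref, at_nM_per_pct = at_nM_per_pct,
                 stoichiometric_depletion = isTRUE(stoichiometric_depletion)),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf(
    "<rate_model> k_AT %.3g, k_a2M %.3g nM^-1 min^-1 @ fib %.2g g/L (%s), AT %.3g nM/%%, %s\n",
    x$k_at_ref, x$k_a2m_ref, x$fib_ref, x$fib_dependence, x$at_nM_per_pct,
    if (x$stoichiometric_depletion) "stoichiometric depletion" else "excess inhibitors"))
  invisible(x)
}

fib_factor <- function(model, fib_gL) {
  switch(model$fib_dependence,
         constant = rep(1, length(fib_gL)),
         saturating = pmin(1, 1 / (1 + model$beta * (fib_gL - model$fib_ref))))
}

#' Effective inactivation rate constants at a given fibrinogen level
#'
#' `k_i = k_i_ref * g(fib)` with `g` the model's fibrinogen-dependence
#' factor, monotone non-increasing in fibrinogen and equal to 1 at the
#' reference level.
#'
#' @param model A [rate_model()].
#' @param fib_gL Fibrinogen in g/L, >= 0.
#' @return Named numeric vector `c(k_at = , k_a2m = )` in nM^-1 min^-1.
#' @export
rate_constants <- function(model, fib_gL) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.numeric(fib_gL) || length(fib_gL) != 1L || fib_gL < 0)
    stop("`fib_gL` must be a single non-negative number")
  g <- fib_factor(model, fib_gL)
  c(k_at = model$k_at_ref * g, k_a2m = model$k_a2m_ref * g)
}

at_nM <- function(factors, model) factors$at_pct * model$at_nM_per_pct
a2m_nM <- function(factors) factors$a2m_uM * 1000

#' Thrombin decay capacity
#'
#' The pseudo-first-order decay constant for free thrombin implied by the
#' plasma levels of antithrombin, alpha-2-macroglobulin and fibrinogen,
#' independent of prothrombin conversion:
#' `TDC = k_at(fib) * [AT]_0 + k_a2m(fib) * [a2M]_0` (per minute).
#' It quantifies the total inhibitory potential of a plasma: a 100 nM
#' thrombin bolus in inhibitor excess decays as `100 * exp(-TDC * t)`.
#'
#' @param factors A [plasma_factors()].
#' @param model A [rate_model()].
#' @return Decay constant in min^-1.
#' @export
thrombin_decay_capacity <- function(factors, model) {
  stopifnot(inherits(factors, "plasma_factors"), inherits(model, "rate_model"))
  k <- rate_constants(model, factors$fib_gL)
  unname(k["k_at"] * at_nM(factors, model) + k["k_a2m"] * a2m_nM(factors))
}

#' Read / write a rate-model configuration
#'
#' Rate-model constants are calibration data, so they live in a YAML or JSON
#' file rather than in code. Fields mirror the arguments of [rate_model()].
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_rate_model()` returns a [rate_model()];
#'   `write_rate_model()` returns `path` invisibly.
#' @export
read_rate_model <- function(path) {
  if (!file.exists(path)) stop("rate-model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported rate-model format: .", ext)
  do.call(rate_model, cfg)
}

#' @rdname read_rate_model
#' @param model A [rate_model()] to serialize.
#' @export
write_rate_model <- function(model, path) {
  stopifnot(inherits(model, "rate_model"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(model)
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json") jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported rate-model format: .", ext)
  invisible(path)
}
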