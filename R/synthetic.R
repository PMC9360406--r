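#' Parametric ground-truth prothrombin conversion pulse
#'
#' The true conversion curve of a plasma sample is not observable; for
#' simulation studies it is represented as a delayed gamma-density pulse:
#' `rate(t) = pc_tot * dgamma(t - delay, shape, scale)`. A two-parameter
#' unimodal pulse spans realistic PCtot/PCmax combinations, and its peak rate
#' has the closed form `pc_tot * dgamma((shape-1)*scale, shape, scale)`
#' (for `shape > 1`), which makes it a convenient oracle.
#'
#' @param pc_tot Total prothrombin converted (nM), area of the pulse.
#' @param delay Onset delay in minutes (>= 0).
#' @param shape Gamma shape (> 0; > 1 for a well-defined interior peak).
#' @param scale Gamma scale in minutes (> 0).
#' @return An object of class `conversion_shape`.
#' @export
conversion_shape <- function(pc_tot, delay, shape, scale) {
  stopifnot(pc_tot >= 0, delay >= 0, shape > 0, scale > 0)
  structure(list(pc_tot = pc_tot, delay = delay, shape = shape, scale = scale),
            class = "conversion_shape")
}

#' @rdname conversion_shape
#' @param x A `conversion_shape`.
#' @param t Times (minutes) at which to evaluate the pulse.
#' @return `conversion_rate()`: the pulse in nM/min; `true_pc_max()`: the
#'   closed-form peak rate in nM/min.
#' @export
conversion_rate <- function(x, t) {
  stopifnot(inherits(x, "conversion_shape"))
  x$pc_tot * stats::dgamma(t - x$delay, shape = x$shape, scale = x$scale)
}

#' @rdname conversion_shape
#' @export
true_pc_max <- function(x) {
  stopifnot(inherits(x, "conversion_shape"))
  if (x$shape <= 1) return(Inf)
  x$pc_tot * stats::dgamma((x$shape - 1) * x$scale, shape = x$shape,
                           scale = x$scale)
}

# peak gamma density for shape k, unit pc_tot: c_k / scale
gamma_peak_factor <- function(shape) {
  stats::dgamma(shape - 1, shape = shape, scale = 1)
}

#' Trigger-reagent presets for the synthetic cohort
#'
#' Median conversion pulses for the three trigger strengths. Tissue-factor
#' content rises from `bleed` (low) through `thrombo` (intermediate) to
#' `drug` (high): stronger triggers convert prothrombin slightly more in
#' total but much faster and earlier, so `pc_tot` rises mildly while
#' `pc_max` rises steeply and the onset delay shortens. The gamma scale of
#' each preset is solved in closed form from the target median `pc_tot` and
#' `pc_max`. These targets place the synthetic cohort's medians in the range
#' reported for healthy donors on automated TG systems; they are generator
#' calibration, not a reproduction of any measured cohort.
#'
#' @return Named list of median pulse settings per reagent, each with
#'   `pc_tot` (nM), `pc_max` (nM/min), `delay` (min) and `shape`.
#' @export
reagent_presets <- function() {
  list(
    bleed   = list(pc_tot = 902, pc_max = 172, delay = 2.7, shape = 3),
    thrombo = list(pc_tot = 933, pc_max = 206, delay = 2.1, shape = 3),
    drug    = list(pc_tot = 988, pc_max = 508, delay = 1.1, shape = 3))
}

preset_shape <- function(preset) {
  scale <- gamma_peak_factor(preset$shape) * preset$pc_tot / preset$pc_max
  conversion_shape(preset$pc_tot, preset$delay, preset$shape, scale)
}

#' Configuration of a synthetic healthy cohort
#'
#' Describes the virtual study population: plasma-factor distributions
#' (medians and spreads matching a healthy adult cohort: AT around 113% with
#' IQR roughly 108--118%, a2M 2.6 uM (2.2--3.1), fibrinogen 2.9 g/L
#' (2.6--3.2)), per-reagent conversion-pulse presets with log-normal
#' between-subject variation, a thrombomodulin condition that scales each
#' subject's conversion pulse by `1 - f` with `f` centred on 0.44, additive
#' Gaussian measurement noise, and the sampling grid.
#'
#' Between-subject variation is a shared log-normal "conversion strength"
#' (sdlog `subject_strength_sdlog`) and "pulse width" (sdlog
#' `subject_width_sdlog`) multiplier applied across all conditions of a
#' subject, plus smaller independent per-condition multipliers -- this gives
#' the within-subject correlation across reagents that paired comparisons
#' rely on.
#'
#' Covariate effects (sex, oral-contraceptive use) are OFF by default so the
#' null cohort is exchangeable; `covariate_profile = "demo"` enables a
#' plausible effect pattern (higher a2M in women, higher and faster
#' conversion plus blunted TM response in OC users) for demonstration and
#' power exploration.
#'
#' @param n_subjects Number of subjects (default 112).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param at_location,at_scale AT activity distribution (% of normal).
#' @param a2m_location,a2m_scale a2M distribution (uM).
#' @param fib_location,fib_scale Fibrinogen distribution (g/L).
#' @param presets Reagent presets, see [reagent_presets()].
#' @param tm_location,tm_scale Mean and sd of the TM fractional conversion
#'   reduction `f`, truncated to (0.05, 0.9).
#' @param subject_strength_sdlog,subject_width_sdlog,condition_strength_sdlog,condition_width_sdlog
#'   Log-normal sdlog of the pulse multipliers.
#' @param delay_jitter_sd Sd (minutes) of the per-condition onset jitter.
#' @param noise_sd Additive Gaussian noise on thrombin (nM), default 5.
#' @param dt,duration Sampling grid: spacing and record length in minutes.
#' @param covariate_profile `"null"` (default) or `"demo"`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 112, seed = 1,
                          at_location = 113, at_scale = 7.4,
                          a2m_location = 2.6, a2m_scale = 0.67,
                          fib_location = 2.9, fib_scale = 0.45,
                          presets = reagent_presets(),
                          tm_location = 0.44, tm_scale = 0.10,
                          subject_strength_sdlog = 0.17,
                          subject_width_sdlog = 0.25,
                          condition_strength_sdlog = 0.06,
                          condition_width_sdlog = 0.15,
                          delay_jitter_sd = 0.15,
                          noise_sd = 5, dt = 0.05, duration = 40,
                          covariate_profile = c("null", "demo")) {
  covariate_profile <- match.arg(covariate_profile)
  stopifnot(n_subjects >= 1, at_scale >= 0, a2m_scale >= 0, fib_scale >= 0,
            tm_location > 0, tm_location < 1, tm_scale >= 0, noise_sd >= 0,
            dt > 0, duration > dt)
  if (at_location <= 0 || a2m_location <= 0 || fib_location <= 0)
    stop("factor distribution locations must be positive")
  for (p in presets)
    stopifnot(p$pc_tot > 0, p$pc_max > 0, p$delay >= 0, p$shape > 1)
  structure(as.list(environment()), class = "cohort_config")
}

# truncated-at-`lower` normal draw by rejection (distributions here put
# negligible mass below zero, so rejection is cheap and exact)
rtnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
  }
  x
}

#' Draw the per-subject plasma factors and covariates
#'
#' Truncated-at-zero draws from the configured distributions, deterministic
#' given the configuration seed.
#'
#' @param config A [cohort_config()].
#' @return Data frame with `subject_id`, `sex` (`"M"`/`"F"`), `oc_use`,
#'   `at_pct`, `a2m_uM`, `fib_gL`.
#' @export
sample_factors <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  sex <- sample(c("M", "F"), n, replace = TRUE)
  oc_use <- sex == "F" & stats::runif(n) < 0.3
  at <- rtnorm(n, config$at_location, config$at_scale)
  a2m <- rtnorm(n, config$a2m_location, config$a2m_scale)
  fib <- rtnorm(n, config$fib_location, config$fib_scale)
  if (config$covariate_profile == "demo") {
    a2m <- a2m * ifelse(sex == "F", 1.12, 1)
    at <- at * ifelse(sex == "M", 1.03, 1)
  }
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), sex = sex,
             oc_use = oc_use, at_pct = at, a2m_uM = a2m, fib_gL = fib,
             stringsAsFactors = FALSE)
}

#' Forward-simulate a TG curve from a known conversion pulse
#'
#' Integrates `dT/dt = rate(t) - inactivation flux` with the inactivation
#' model, returning the noise-free TG curve together with the ground-truth
#' trajectory for oracle use. The grid should cover the pulse plus at least
#' ten thrombin half-lives; if free thrombin at the end of the grid still
#' exceeds 1% of the peak the curve is flagged as truncated.
#'
#' @param shape A [conversion_shape()].
#' @param factors A [plasma_factors()].
#' @param model A [rate_model()].
#' @param times Uniform grid in minutes.
#' @param sample_id,reagent,tm_present Metadata for the returned curve.
#' @return List with `curve` ([thrombin_curve()]), `trajectory`
#'   (`inactivation_trajectory`), and `truth` (list: `pc_tot`, `pc_max`,
#'   `t_at`, `t_a2m`, `tdc`). The truth complexes are end-point totals: if
#'   thrombin has not fully decayed at the end of the grid, the simulation
#'   is continued internally (up to 300 extra minutes) until it has, so the
#'   ground truth does not depend on the record length.
#' @export
forward_simulate_tg <- function(shape, factors, model, times,
                                sample_id = "sim", reagent = "bleed",
                                tm_present = FALSE) {
  stopifnot(inherits(shape, "conversion_shape"))
  src <- function(t) conversion_rate(shape, t)
  traj <- simulate_inactivation(factors, model, times, source = src)
  n <- length(times)
  truncated <- traj$t_free[n] > 0.01 * max(traj$t_free)
  curve <- thrombin_curve(times, traj$t_free, sample_id = sample_id,
                          reagent = reagent, tm_present = tm_present,
                          truncated = TRUE)
  curve$flags <- setdiff(curve$flags, "truncated")
  if (truncated) {
    warning("grid too short: residual free thrombin exceeds 1% of peak")
    curve$flags <- c(curve$flags, "truncated")
  }
  # run the complex formation to completion for the ground truth
  k <- rate_constants(model, factors$fib_gL)
  s <- as.numeric(traj[n, c("t_free", "t_at", "t_a2m", "at_remaining",
                            "a2m_remaining", "cum_source")])
  dt <- times[2L] - times[1L]
  t_end <- times[n]
  tol <- 1e-7 * max(shape$pc_tot, 1)
  while ((s[1L] > tol ||
          shape$pc_tot * (1 - stats::pgamma(t_end - shape$delay,
                                            shape$shape,
                                            scale = shape$scale)) > tol) &&
         t_end < times[n] + 300) {
    chunk <- seq(t_end, t_end + 10, by = dt)
    S <- rk4_inactivation(s, chunk, k[["k_at"]], k[["k_a2m"]],
                          model$stoichiometric_depletion, src)
    s <- S[nrow(S), ]
    t_end <- chunk[length(chunk)]
  }
  # distribute the (negligible) remaining free thrombin over the complexes
  fl_at <- k[["k_at"]] * s[4L]
  fl_a2m <- k[["k_a2m"]] * s[5L]
  w <- if (fl_at + fl_a2m > 0) fl_at / (fl_at + fl_a2m) else 1
  list(curve = curve,
       trajectory = traj,
       truth = list(pc_tot = shape$pc_tot, pc_max = true_pc_max(shape),
                    t_at = s[2L] + w * s[1L],
                    t_a2m = s[3L] + (1 - w) * s[1L],
                    tdc = thrombin_decay_capacity(factors, model)))
}

#' Generate a full synthetic cohort of TG curves
#'
#' For every subject and condition (three trigger reagents plus the
#' `thrombo` trigger with thrombomodulin) this draws a subject-specific
#' conversion pulse, forward-simulates the TG curve through the inactivation
#' model, adds seeded Gaussian measurement noise, and records the hidden
#' ground truth for recovery testing. The TM condition scales the subject's
#' `thrombo` pulse by `1 - f`.
#'
#' @param config A [cohort_config()].
#' @param model A [rate_model()] (default [rate_model()]).
#' @return An object of class `td_cohort`: list with `curves` (list of
#'   [thrombin_curve()]), `factors` (per-subject table from
#'   [sample_factors()]), `truth` (data frame of true `pc_tot`, `pc_max`,
#'   `t_at`, `t_a2m`, `tdc`, `tm_f` per subject x condition), and `config`.
#' @export
generate_cohort <- function(config, model = rate_model()) {
  stopifnot(inherits(config, "cohort_config"), inherits(model, "rate_model"))
  fac <- sample_factors(config)
  n <- config$n_subjects
  times <- seq(0, config$duration, by = config$dt)
  conditions <- c("bleed", "thrombo", "thrombo_tm", "drug")

  set.seed(config$seed + 1L)
  subj_strength <- stats::rlnorm(n, 0, config$subject_strength_sdlog)
  subj_width <- stats::rlnorm(n, 0, config$subject_width_sdlog)
  tm_f <- rtnorm(n, config$tm_location, config$tm_scale, 0.05, 0.9)
  cond_strength <- matrix(stats::rlnorm(n * 3, 0, config$condition_strength_sdlog), n, 3)
  cond_width <- matrix(stats::rlnorm(n * 3, 0, config$condition_width_sdlog), n, 3)
  delay_jit <- matrix(stats::rnorm(n * 3, 0, config$delay_jitter_sd), n, 3)

  oc_strength <- rep(1, n); oc_width <- rep(1, n); oc_tm <- rep(1, n)
  if (config$covariate_profile == "demo") {
    oc_strength[fac$oc_use] <- 1.15
    oc_width[fac$oc_use] <- 1 / 1.3
    oc_tm[fac$oc_use] <- 0.55
  }

  curves <- vector("list", n * length(conditions))
  truth <- vector("list", n * length(conditions))
  idx <- 0L
  for (i in seq_len(n)) {
    f_i <- plasma_factors(fac$at_pct[i], fac$a2m_uM[i], fac$fib_gL[i])
    for (cond in conditions) {
      reagent <- if (cond == "thrombo_tm") "thrombo" else cond
      tm <- cond == "thrombo_tm"
      j <- match(reagent, c("bleed", "thrombo", "drug"))
      p <- config$presets[[reagent]]
      base <- preset_shape(p)
      pc_tot <- p$pc_tot * subj_strength[i] * cond_strength[i, j] * oc_strength[i]
      scale <- base$scale * subj_width[i] * cond_width[i, j] * oc_width[i]
      delay <- max(0.2, p$delay + delay_jit[i, j])
      if (tm) pc_tot <- pc_tot * (1 - tm_f[i] * oc_tm[i])
      shape_i <- conversion_shape(pc_tot, delay, p$shape, scale)
      sim <- withCallingHandlers(
        forward_simulate_tg(shape_i, f_i, model, times,
                            sample_id = fac$subject_id[i],
                            reagent = reagent, tm_present = tm),
        warning = function(w) {
          if (grepl("grid too short", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      idx <- idx + 1L
      curves[[idx]] <- sim$curve
      truth[[idx]] <- data.frame(
        subject_id = fac$subject_id[i], reagent = reagent, tm_present = tm,
        condition = cond, pc_tot = sim$truth$pc_tot, pc_max = sim$truth$pc_max,
        t_at = sim$truth$t_at, t_a2m = sim$truth$t_a2m, tdc = sim$truth$tdc,
        tm_f = if (tm) tm_f[i] * oc_tm[i] else 0,
        delay = shape_i$delay, shape = shape_i$shape, scale = shape_i$scale,
        stringsAsFactors = FALSE)
    }
  }
  if (config$noise_sd > 0) {
    set.seed(config$seed + 2L)
    for (k in seq_along(curves)) {
      cv <- curves[[k]]
      cv$thrombin <- cv$thrombin +
        stats::rnorm(length(cv$thrombin), 0, config$noise_sd)
      # re-validate flags without re-running the constructor checks that
      # noise can legitimately trip (peak position is unchanged in truth)
      if (any(cv$thrombin < 0))
        cv$flags <- unique(c(cv$flags, "negative_baseline"))
      curves[[k]] <- cv
    }
  }
  structure(list(curves = curves, factors = fac,
                 truth = do.call(rbind, truth), config = config),
            class = "td_cohort")
}

#' @export
print.td_cohort <- function(x, ...) {
  cat(sprintf(
    "<td_cohort> %d subjects x %d conditions = %d curves | noise %.1f nM | seed %d\n",
    x$config$n_subjects, length(unique(x$truth$condition)), length(x$curves),
    x$config$noise_sd, x$config$seed))
  invisible(x)
}
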