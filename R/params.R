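#' Radiosensitivity parameters
#'
#' Linear-quadratic (LQ) and induced-repair coefficients governing clonogenic
#' cell killing and radiation-induced Sfpi1 deletion in murine bone marrow
#' cells. The LQ lethal-event count is \eqn{L(D) = \alpha_r D + \beta D^2};
#' under hyper-radiosensitivity (HRS) the linear coefficient becomes
#' dose-dependent, interpolating from a steep low-dose slope \code{alpha_s}
#' down to \code{alpha_r} with characteristic dose \code{D_c}.
#'
#' @param alpha_r conventional LQ linear coefficient (per Gy).
#' @param alpha_s low-dose HRS slope for cell killing (per Gy).
#' @param beta LQ quadratic coefficient (per Gy^2).
#' @param D_c characteristic dose at which induced radioresistance is 63%
#'   complete (Gy).
#' @param deletion_slope_ratio assumed \code{alpha_s/alpha_r} ratio for the
#'   HRS-stimulated induction of the Sfpi1 deletion (dimensionless); it
#'   affects deletion induction only, never cell killing.
#' @return An object of class \code{radiosensitivity_params}.
#' @examples
#' rp <- radiosensitivity_params()
#' lethal_events_lq(3, rp)
#' @export
radiosensitivity_params <- function(alpha_r = 0.0402, alpha_s = 20,
                                    beta = 0.122, D_c = 0.06,
                                    deletion_slope_ratio = 3) {
  p <- list(alpha_r = alpha_r, alpha_s = alpha_s, beta = beta, D_c = D_c,
            deletion_slope_ratio = deletion_slope_ratio)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
    }
  }
  if (alpha_s < alpha_r) stop("'alpha_s' must be >= 'alpha_r'", call. = FALSE)
  if (deletion_slope_ratio < 1) {
    stop("'deletion_slope_ratio' must be >= 1", call. = FALSE)
  }
  structure(p, class = "radiosensitivity_params")
}

#' Leukemogenesis parameters
#'
#' Cell-population parameters of the two-mutation model: initial number of
#' normal target cells, probability of acquiring the Sfpi1 deletion per
#' lethal event, net proliferation rate of pre-leukemic cells, Sfpi1 point
#' mutation rate, and the fixed latency between first malignant cell and
#' rAML diagnosis.
#'
#' @param N0 initial number of normal target cells.
#' @param mu_del Sfpi1-deletion probability per lethal event (dimensionless).
#' @param b proliferation rate of pre-leukemic cells (per month).
#' @param mu_p Sfpi1 point-mutation rate (per cell per month).
#' @param t_lag diagnosis latency (months); the default is the 22-week
#'   median AML latency of Sfpi1-deleted mice converted to months, see
#'   [weeks_to_months()].
#' @return An object of class \code{leukemogenesis_params}.
#' @export
leukemogenesis_params <- function(N0 = 15670, mu_del = 0.0498, b = 0.0995,
                                  mu_p = 2.17e-5, t_lag = 5.06) {
  p <- list(N0 = N0, mu_del = mu_del, b = b, mu_p = mu_p, t_lag = t_lag)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
    }
  }
  if (b <= mu_p) {
    stop("'b' must exceed 'mu_p' (pre-leukemic clones must have net growth)",
         call. = FALSE)
  }
  structure(p, class = "leukemogenesis_params")
}

#' Competing (non-rAML) mortality parameters
#'
#' Parameters of the dose-shifted skew-normal distribution of non-rAML death
#' times of male CBA/H mice: location \eqn{\xi(D) = \xi_0 - s D} months,
#' scale \eqn{\omega} months and shape \eqn{\alpha}.
#'
#' @param xi_intercept location at zero dose (months).
#' @param xi_dose_slope subtractive dose dependence of the location
#'   (months per Gy).
#' @param omega scale (months).
#' @param shape skew-normal shape (dimensionless; negative = left skew).
#' @param max_calibrated_dose largest dose (Gy) at which the parameters were
#'   calibrated; computations beyond it carry an extrapolation flag.
#' @return An object of class \code{mortality_params}.
#' @export
mortality_params <- function(xi_intercept = 25.86, xi_dose_slope = 0.57,
                             omega = 5.87, shape = -1.01,
                             max_calibrated_dose = 6) {
  if (!is.numeric(omega) || omega <= 0) stop("'omega' must be > 0", call. = FALSE)
  if (!is.numeric(xi_intercept) || xi_intercept <= 0) {
    stop("'xi_intercept' must be > 0", call. = FALSE)
  }
  structure(list(xi_intercept = xi_intercept, xi_dose_slope = xi_dose_slope,
                 omega = omega, shape = shape,
                 max_calibrated_dose = max_calibrated_dose),
            class = "mortality_params")
}

#' Acute exposure protocol
#'
#' A whole-body exposure with total dose \code{total_dose} Gy delivered at a
#' constant dose rate (Gy/month); duration is derived. The model's
#' closed-form solutions assume acute exposure (very high dose rate, so the
#' exposure time is negligible on the month time-scale of leukemogenesis).
#'
#' @param total_dose total absorbed dose D (Gy).
#' @param dose_rate constant dose rate (Gy per month). The default is
#'   effectively acute.
#' @return An object of class \code{exposure_protocol} with fields
#'   \code{total_dose}, \code{dose_rate} and \code{duration} (months).
#' @export
exposure_protocol <- function(total_dose, dose_rate = 1e4) {
  if (!is.numeric(total_dose) || total_dose < 0) {
    stop("'total_dose' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(dose_rate) || dose_rate <= 0) {
    stop("'dose_rate' must be > 0", call. = FALSE)
  }
  structure(list(total_dose = total_dose, dose_rate = dose_rate,
                 duration = total_dose / dose_rate),
            class = "exposure_protocol")
}

#' HRS scenario labels
#'
#' The three target-cell hyper-radiosensitivity assumptions:
#' \describe{
#'   \item{\code{"hrs_minus"}}{no HRS; conventional LQ killing and deletion
#'     induction (control).}
#'   \item{\code{"hrs_plus1"}}{HRS stimulates cell killing only.}
#'   \item{\code{"hrs_plus2"}}{HRS stimulates cell killing and the induction
#'     of the Sfpi1 deletion.}
#' }
#' @export
hrs_scenarios <- c("hrs_minus", "hrs_plus1", "hrs_plus2")

match_scenario <- function(scenario) {
  if (length(scenario) != 1L || !is.character(scenario) ||
      !scenario %in% hrs_scenarios) {
    stop("unknown HRS scenario: ", paste(scenario, collapse = ", "),
         "; must be one of ", paste(hrs_scenarios, collapse = ", "),
         call. = FALSE)
  }
  scenario
}

#' Convert a latency in weeks to months
#'
#' Uses the mean Gregorian month of 365.25/12 days. The default diagnosis
#' latency of the model, 5.06 months, is the 22-week median AML latency of
#' Sfpi1-deleted mice expressed in months.
#'
#' @param weeks latency in weeks.
#' @return latency in months.
#' @examples
#' weeks_to_months(22) # ~5.06
#' @export
weeks_to_months <- function(weeks) {
  stopifnot(is.numeric(weeks), all(weeks >= 0))
  weeks * 7 / (365.25 / 12)
}

#' Default run configuration
#'
#' A flat configuration mirroring the model's parameter symbols, suitable
#' for YAML round-tripping and the command-line interface.
#'
#' @return A named list with components \code{radiosensitivity},
#'   \code{leukemogenesis}, \code{mortality}, \code{scenarios},
#'   \code{dose_grid}, \code{time_grid} and \code{seed}.
#' @export
default_run_config <- function() {
  list(
    radiosensitivity = list(alpha_r = 0.0402, alpha_s = 20, beta = 0.122,
                            D_c = 0.06, deletion_slope_ratio = 3),
    leukemogenesis = list(N0 = 15670, mu_del = 0.0498, b = 0.0995,
                          mu_p = 2.17e-5, t_lag = 5.06),
    mortality = list(xi_intercept = 25.86, xi_dose_slope = 0.57,
                     omega = 5.87, shape = -1.01),
    scenarios = hrs_scenarios,
    dose_grid = list(min = 0, max = 6, n = 121L),
    time_grid = list(min = 0, max = 40, n = 161L),
    seed = NULL
  )
}

config_blocks <- c("radiosensitivity", "leukemogenesis", "mortality",
                   "scenarios", "dose_grid", "time_grid", "seed")

validate_run_config <- function(config) {
  bad <- setdiff(names(config), config_blocks)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ref <- default_run_config()
  for (blk in c("radiosensitivity", "leukemogenesis", "mortality")) {
    extra <- setdiff(names(config[[blk]]), names(ref[[blk]]))
    if (length(extra) > 0) {
      stop("unknown config keys in '", blk, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(config$scenarios)) {
    lapply(config$scenarios, match_scenario)
  }
  invisible(config)
}

#' Read / write a run configuration
#'
#' Configurations are stored as YAML whose keys are the model's parameter
#' symbols; missing keys fall back to defaults and unknown keys raise an
#' error listing the offenders.
#'
#' @param path file path.
#' @param config configuration list as returned by [default_run_config()].
#' @return \code{read_run_config} returns the merged, validated
#'   configuration list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), raw)
  validate_run_config(raw)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build parameter objects from a configuration
#'
#' @param config configuration list.
#' @return A list with elements \code{rp}, \code{lp}, \code{mp}.
#' @export
config_params <- function(config) {
  validate_run_config(config)
  list(rp = do.call(radiosensitivity_params, config$radiosensitivity),
       lp = do.call(leukemogenesis_params, config$leukemogenesis),
       mp = do.call(mortality_params, config$mortality))
}
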