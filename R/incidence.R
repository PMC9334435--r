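#' Actual rAML diagnosis-time density
#'
#' Competing-risks product of the potential diagnosis-time density and the
#' probability of still being alive:
#' \eqn{f_d(t) = (1 - \hat F_{\bar A}(t)) f_A(t)}.
#' The result is an improper density: its integral is the lifetime rAML
#' probability, strictly below 1.
#'
#' @param times evaluation grid (months, non-negative, increasing).
#' @param D absorbed dose (Gy).
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp,mp parameter objects.
#' @return A \code{density_curve}: data frame with columns \code{times} and
#'   \code{values}.
#' @export
diagnosis_density <- function(times, D, scenario = "hrs_minus",
                              lp = leukemogenesis_params(),
                              rp = radiosensitivity_params(),
                              mp = mortality_params()) {
  stopifnot(is.numeric(times), all(times >= 0), !is.unsorted(times))
  I0 <- initial_intermediate_cells(D, scenario, lp, rp)
  vals <- (1 - corrected_cdf(times, D, mp)) *
    potential_diagnosis_density(times, I0, lp)
  structure(data.frame(times = times, values = vals),
            class = c("density_curve", "data.frame"))
}

# f_d as a plain function of time for quadrature; I0 precomputed.
fd_fun <- function(D, I0, lp, mp) {
  function(t) {
    (1 - corrected_cdf(t, D, mp)) * potential_diagnosis_density(t, I0, lp)
  }
}

#' Lifetime probability of developing rAML
#'
#' \eqn{P(rAML) = P(t_A < t_{\bar A}) = \int_0^\infty f_d(t)\,dt},
#' computed by adaptive quadrature from the diagnosis latency (below which
#' \eqn{f_A} vanishes) to the time at which the non-rAML survival
#' probability is negligible (residual below 1e-10, capped at 120 months).
#'
#' @param D absorbed dose (Gy); vectorised.
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp,mp parameter objects.
#' @param abs_tol absolute quadrature tolerance.
#' @return Probability in [0, 1), same length as D.
#' @examples
#' raml_probability(3) # about 0.2
#' @export
raml_probability <- function(D, scenario = "hrs_minus",
                             lp = leukemogenesis_params(),
                             rp = radiosensitivity_params(),
                             mp = mortality_params(),
                             abs_tol = 1e-8) {
  check_dose(D)
  vapply(D, function(d) {
    if (d == 0) return(0)
    I0 <- initial_intermediate_cells(d, scenario, lp, rp)
    if (I0 == 0) return(0)
    tmax <- mortality_horizon(d, mp)
    if (tmax <= lp$t_lag) return(0)
    q <- stats::integrate(fd_fun(d, I0, lp, mp), lower = lp$t_lag,
                          upper = tmax, abs.tol = abs_tol, rel.tol = 1e-8,
                          subdivisions = 200L, stop.on.error = FALSE)
    if (q$message != "OK" && q$abs.error > 1e-6) {
      stop("quadrature failed for dose ", d, ": ", q$message, call. = FALSE)
    }
    min(max(q$value, 0), 1)
  }, numeric(1))
}

#' Time-resolved cumulative rAML incidence
#'
#' Running integral of the diagnosis-time density \eqn{f_d} at a fixed
#' dose: the probability of having been diagnosed with rAML by each
#' requested time. Computed by trapezoidal integration of \eqn{f_d} on a
#' fine internal grid and interpolated at \code{times}.
#'
#' @param times evaluation times (months, non-negative, increasing).
#' @param D absorbed dose (Gy).
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp,mp parameter objects.
#' @param n_grid internal integration grid size.
#' @return Vector of cumulative probabilities, non-decreasing, same length
#'   as \code{times}; the plateau equals [raml_probability()].
#' @export
cumulative_incidence <- function(times, D, scenario = "hrs_minus",
                                 lp = leukemogenesis_params(),
                                 rp = radiosensitivity_params(),
                                 mp = mortality_params(),
                                 n_grid = 4001L) {
  stopifnot(is.numeric(times), all(times >= 0), !is.unsorted(times))
  I0 <- initial_intermediate_cells(D, scenario, lp, rp)
  if (I0 == 0) return(numeric(length(times)))
  tmax <- max(max(times), mortality_horizon(D, mp))
  grid <- seq(lp$t_lag, tmax, length.out = n_grid)
  vals <- fd_fun(D, I0, lp, mp)(grid)
  cum <- c(0, cumsum((vals[-1] + vals[-n_grid]) / 2 * diff(grid)))
  out <- stats::approx(grid, cum, xout = pmin(pmax(times, lp$t_lag), tmax),
                       rule = 2)$y
  out[times < lp$t_lag] <- 0
  out
}

#' rAML dose-response curve
#'
#' Maps [raml_probability()] over a dose grid for one HRS scenario.
#'
#' @param doses dose grid (Gy, increasing, at least two points).
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp,mp parameter objects.
#' @return A \code{dose_response_curve}: data frame with columns
#'   \code{dose_Gy}, \code{scenario}, \code{p_raml}.
#' @export
dose_response_curve <- function(doses, scenario = "hrs_minus",
                                lp = leukemogenesis_params(),
                                rp = radiosensitivity_params(),
                                mp = mortality_params()) {
  stopifnot(length(doses) >= 2, !is.unsorted(doses))
  scenario <- match_scenario(scenario)
  p <- raml_probability(doses, scenario, lp, rp, mp)
  structure(data.frame(dose_Gy = doses, scenario = scenario, p_raml = p),
            class = c("dose_response_curve", "data.frame"))
}

#' Dose maximising the lifetime rAML probability
#'
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp,mp parameter objects.
#' @param interval search interval (Gy).
#' @return list with \code{dose} (Gy) and \code{p_raml} at the maximum.
#' @export
raml_dose_argmax <- function(scenario = "hrs_minus",
                             lp = leukemogenesis_params(),
                             rp = radiosensitivity_params(),
                             mp = mortality_params(),
                             interval = c(1.5, 3.5)) {
  opt <- stats::optimize(function(D) raml_probability(D, scenario, lp, rp, mp),
                         interval = interval, maximum = TRUE, tol = 1e-4)
  list(dose = opt$maximum, p_raml = opt$objective)
}

#' Low-dose linear-quadratic approximation of a dose-response curve
#'
#' Ordinary least squares of \eqn{y(D) = c_1 D + c_2 D^2} (through the
#' origin) on incidence percentages over doses up to 0.2 Gy — the regime
#' where the control (no-HRS) dose-response curve is accurately
#' linear-quadratic.
#'
#' @param curve a \code{dose_response_curve} restricted to doses <= 0.2 Gy
#'   with at least three points.
#' @return An \code{lq_approx} list: \code{c1} (per Gy), \code{c2}
#'   (per Gy^2), both on the percent scale, plus the fitted \code{model}.
#' @export
fit_lq_approximation <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve") ||
              all(c("dose_Gy", "p_raml") %in% names(curve)))
  if (nrow(curve) < 3) stop("need at least 3 dose points", call. = FALSE)
  if (max(curve$dose_Gy) > 0.2 + 1e-12) {
    stop("low-dose fit restricted to doses <= 0.2 Gy", call. = FALSE)
  }
  pct <- 100 * curve$p_raml
  fit <- stats::lm(pct ~ 0 + dose_Gy + I(dose_Gy^2), data = curve)
  if (any(!is.finite(stats::coef(fit)))) {
    stop("singular design in low-dose fit", call. = FALSE)
  }
  cf <- unname(stats::coef(fit))
  structure(list(c1 = cf[1], c2 = cf[2], model = fit), class = "lq_approx")
}

#' Low-dose LQ coefficients of the modelled incidence
#'
#' Convenience pipeline: evaluates the incidence at \code{n} equally spaced
#' doses on [0, \code{d_max}] Gy, converts to percent, and fits the
#' through-origin linear-quadratic form.
#'
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp,mp parameter objects.
#' @param n number of dose points (default 21).
#' @param d_max maximum dose of the fit window (Gy).
#' @return An \code{lq_approx}, see [fit_lq_approximation()].
#' @export
low_dose_lq_coefficients <- function(scenario = "hrs_minus",
                                     lp = leukemogenesis_params(),
                                     rp = radiosensitivity_params(),
                                     mp = mortality_params(),
                                     n = 21L, d_max = 0.2) {
  doses <- seq(0, d_max, length.out = n)
  fit_lq_approximation(dose_response_curve(doses, scenario, lp, rp, mp))
}

#' HRS-modified linear coefficient of the low-dose approximation
#'
#' Dose-dependent replacements for the linear coefficient \eqn{c_1} of the
#' low-dose approximation \eqn{y(D) = c_1 D + c_2 D^2}, describing the two
#' HRS scenarios:
#' \deqn{c_{1,+1}(D) = c_{1,r}\big(1 - (c_{1,s}/c_{1,r} - 1)\, zD\,
#'   e^{-D/D_c}\big),}
#' \deqn{c_{1,+2}(D) = c_{1,r}\big(1 + (c_{1,s}/c_{1,r} - 1)\,
#'   e^{-D/D_c}\big),}
#' with \eqn{z = 1} per Gy making \eqn{zD} dimensionless. The first form
#' reduces incidence (suppressed deletion carriers) and equals
#' \eqn{c_{1,r}} at D = 0; the second is the induced-repair form itself and
#' equals \eqn{c_{1,s}} at D = 0. Both approach \eqn{c_{1,r}} at higher
#' doses.
#'
#' @param D dose (Gy); vectorised.
#' @param coeffs list with \code{c1_r}, \code{c1_s}, \code{D_c} (Gy) and
#'   optionally \code{z} (per Gy, default 1).
#' @param scenario \code{"hrs_plus1"} or \code{"hrs_plus2"}.
#' @return per Gy, same length as D.
#' @export
hrs_modified_linear_coefficient <- function(D, coeffs,
                                            scenario = c("hrs_plus1",
                                                         "hrs_plus2")) {
  scenario <- match.arg(scenario)
  check_dose(D)
  z <- if (is.null(coeffs$z)) 1 else coeffs$z
  r <- coeffs$c1_s / coeffs$c1_r - 1
  switch(scenario,
         hrs_plus1 = coeffs$c1_r * (1 - r * z * D * exp(-D / coeffs$D_c)),
         hrs_plus2 = coeffs$c1_r * (1 + r * exp(-D / coeffs$D_c)))
}

#' Fit the HRS-modified coefficient forms to a modelled curve
#'
#' Optional descriptive routine: given a dose-response curve of an HRS
#' scenario (percent scale) over doses up to 0.3 Gy and the quadratic
#' coefficient of the no-HRS reference fit, estimates \code{c1_r},
#' \code{c1_s} and \code{D_c} of the corresponding closed form in
#' [hrs_modified_linear_coefficient()] by least squares on
#' \eqn{y(D) = c_1(D) D + c_2 D^2}.
#'
#' @param curve a \code{dose_response_curve} for \code{"hrs_plus1"} or
#'   \code{"hrs_plus2"} with doses in (0, 0.3] Gy.
#' @param c2 fixed quadratic coefficient (percent per Gy^2).
#' @param start named start values for \code{c1_r}, \code{c1_s}, \code{D_c}.
#' @return list with the fitted \code{c1_r}, \code{c1_s}, \code{D_c} and
#'   the \code{nls.lm} fit object.
#' @export
fit_hrs_coefficient_forms <- function(curve, c2,
                                      start = c(c1_r = 3.6, c1_s = 12,
                                                D_c = 0.05)) {
  scenario <- match.arg(unique(as.character(curve$scenario)),
                        c("hrs_plus1", "hrs_plus2"))
  D <- curve$dose_Gy
  keep <- D > 0 & D <= 0.3 + 1e-12
  D <- D[keep]
  pct <- 100 * curve$p_raml[keep]
  resid_fn <- function(logp) {
    p <- exp(logp)
    cf <- list(c1_r = p[1], c1_s = p[2], D_c = p[3])
    pct - (hrs_modified_linear_coefficient(D, cf, scenario) * D + c2 * D^2)
  }
  fit <- minpack.lm::nls.lm(par = log(start), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- exp(fit$par)
  list(c1_r = unname(est[1]), c1_s = unname(est[2]), D_c = unname(est[3]),
       fit = fit)
}

#' Export a dose-response curve as CSV
#'
#' Columns \code{dose_Gy}, \code{scenario}, \code{p_raml}.
#' @param curve a \code{dose_response_curve}.
#' @param path output file.
#' @export
write_dose_response_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
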