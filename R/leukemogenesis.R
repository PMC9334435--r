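# Scenario dispatch: which lethal-event functions drive cell killing and
# Sfpi1-deletion induction. Killing uses the induced-repair count for both
# HRS+ scenarios; deletion induction uses the LQ count except under
# "hrs_plus2", where the assumed slope-ratio induced-repair form applies.
scenario_lethal_events <- function(D, scenario, rp) {
  scenario <- match_scenario(scenario)
  switch(scenario,
         hrs_minus = list(kill = lethal_events_lq(D, rp),
                          del  = lethal_events_lq(D, rp)),
         hrs_plus1 = list(kill = lethal_events_hrs(D, rp),
                          del  = lethal_events_lq(D, rp)),
         hrs_plus2 = list(kill = lethal_events_hrs(D, rp),
                          del  = lethal_events_hrs_deletion(D, rp)))
}

#' Pre-leukemic cells surviving an acute exposure
#'
#' Expected number of intermediate (Sfpi1-deleted) cells present immediately
#' after a brief high-dose-rate exposure,
#' \deqn{I_0(D) = N_0 e^{-(L_{kill} + \mu_{del} L_{del})}
#'   (e^{\mu_{del} L_{del}} - 1),}
#' where the killing and deletion lethal-event counts depend on the HRS
#' scenario: killing is LQ for \code{"hrs_minus"} and induced-repair for
#' both \code{"hrs_plus"} scenarios; deletion induction is LQ except for
#' \code{"hrs_plus2"}, which uses the slope-ratio induced-repair form.
#' The \code{expm1} primitive preserves precision at very low doses, where
#' \eqn{\mu_{del} L} is of order 1e-4.
#'
#' @param D absorbed dose (Gy); vectorised.
#' @param scenario one of [hrs_scenarios].
#' @param lp [leukemogenesis_params()].
#' @param rp [radiosensitivity_params()].
#' @return Expected pre-leukemic cell count, same length as D.
#' @examples
#' initial_intermediate_cells(3, "hrs_minus")
#' @export
initial_intermediate_cells <- function(D, scenario = "hrs_minus",
                                       lp = leukemogenesis_params(),
                                       rp = radiosensitivity_params()) {
  check_dose(D)
  le <- scenario_lethal_events(D, scenario, rp)
  lp$N0 * exp(-(le$kill + lp$mu_del * le$del)) * expm1(lp$mu_del * le$del)
}

#' Dose maximising pre-leukemic cell formation
#'
#' Numerically locates the dose at which \eqn{I_0(D)} peaks, together with
#' the analytic cross-check available for the \code{"hrs_minus"} scenario:
#' at the maximum the lethal-event count satisfies
#' \eqn{L^* = \ln(1+\mu_{del})/\mu_{del}}, and the dose solves
#' \eqn{\alpha_r D + \beta D^2 = L^*}.
#'
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp parameter objects.
#' @param interval search interval in Gy.
#' @return list with \code{dose} (numerical argmax, Gy), \code{I0} (cells at
#'   the maximum), \code{lethal_events} at the maximum and, for
#'   \code{"hrs_minus"}, \code{analytic_dose} from the stationarity
#'   condition.
#' @export
pre_leukemic_dose_argmax <- function(scenario = "hrs_minus",
                                     lp = leukemogenesis_params(),
                                     rp = radiosensitivity_params(),
                                     interval = c(0.5, 6)) {
  scenario <- match_scenario(scenario)
  opt <- stats::optimize(function(D) initial_intermediate_cells(D, scenario, lp, rp),
                         interval = interval, maximum = TRUE,
                         tol = 1e-8)
  out <- list(dose = opt$maximum, I0 = opt$objective,
              lethal_events = scenario_lethal_events(opt$maximum, scenario,
                                                     rp)$kill)
  if (scenario == "hrs_minus") {
    Lstar <- log1p(lp$mu_del) / lp$mu_del
    out$analytic_dose <-
      (-rp$alpha_r + sqrt(rp$alpha_r^2 + 4 * rp$beta * Lstar)) / (2 * rp$beta)
  }
  out
}

#' Intermediate-cell growth after exposure
#'
#' \eqn{I(t) = I_0 e^{(b - \mu_p) t}}: the pre-leukemic clone expands at net
#' rate \eqn{b - \mu_p} once irradiation has ceased.
#'
#' @param t time since exposure (months); vectorised.
#' @param I0 initial pre-leukemic cell count.
#' @param lp [leukemogenesis_params()].
#' @return Expected intermediate-cell count.
#' @export
intermediate_cells <- function(t, I0, lp = leukemogenesis_params()) {
  stopifnot(is.numeric(t), all(t >= 0), I0 >= 0)
  I0 * exp((lp$b - lp$mu_p) * t)
}

#' Expected cumulative number of malignant cells
#'
#' \eqn{M(t) = \mu_p/(b - \mu_p) (I(t) - I_0)}, the expected number of
#' malignant-cell formation events by time t (the integrated rate of the
#' Poisson arrival process).
#'
#' @inheritParams intermediate_cells
#' @return Expected malignant-cell count; 0 at t = 0, non-decreasing.
#' @export
expected_malignant_cells <- function(t, I0, lp = leukemogenesis_params()) {
  stopifnot(is.numeric(t), all(t >= 0), I0 >= 0)
  if (lp$b <= lp$mu_p) {
    stop("degenerate parameterisation: 'b' must exceed 'mu_p'", call. = FALSE)
  }
  lp$mu_p / (lp$b - lp$mu_p) * (intermediate_cells(t, I0, lp) - I0)
}

#' Density of the first malignant cell's arrival time
#'
#' Malignant-cell formation is an inhomogeneous Poisson process with rate
#' \eqn{\dot M(t) = \mu_p I(t)}; the first arrival then has density
#' \eqn{f_{M=1}(t) = \dot M(t) e^{-M(t)}}. The density is proper (integrates
#' to 1) whenever \eqn{I_0 > 0} because \eqn{M(t) \to \infty}; it is
#' identically zero when \eqn{I_0 = 0}.
#'
#' @inheritParams intermediate_cells
#' @return density per month, same length as t.
#' @export
first_malignant_density <- function(t, I0, lp = leukemogenesis_params()) {
  stopifnot(is.numeric(t), all(t >= 0), I0 >= 0)
  if (I0 == 0) return(rep(0, length(t)))
  # log-space evaluation: at large t the rate overflows while exp(-M)
  # underflows; their product must go to 0, not NaN
  g <- lp$b - lp$mu_p
  logMdot <- log(lp$mu_p * I0) + g * t
  exp(logMdot - expected_malignant_cells(t, I0, lp))
}

#' Density of the potential rAML diagnosis time
#'
#' The potential diagnosis time (in the absence of competing death) is the
#' first malignant cell's arrival time plus the fixed latency
#' \code{t_lag}: \eqn{f_A(t) = f_{M=1}(t - t_{lag})} for \eqn{t \ge
#' t_{lag}} and 0 before.
#'
#' @inheritParams intermediate_cells
#' @return density per month, same length as t.
#' @export
potential_diagnosis_density <- function(t, I0, lp = leukemogenesis_params()) {
  stopifnot(is.numeric(t), all(t >= 0))
  out <- numeric(length(t))
  idx <- t >= lp$t_lag
  if (any(idx)) {
    out[idx] <- first_malignant_density(t[idx] - lp$t_lag, I0, lp)
  }
  out
}

#' Numerically integrate the during-exposure cell dynamics
#'
#' Solves the ordinary differential equations for normal (N), intermediate
#' (I) and malignant (M) bone marrow cells over the exposure window
#' \eqn{[0, T]}, \eqn{T = D/\dot D}, with the scenario-specific lethal-event
#' rates substituted for killing and deletion induction:
#' \deqn{\dot N = -\dot L_{kill} N - \mu_{del} \dot L_{del} N, \quad
#'       \dot I = \mu_{del} \dot L_{del} N - \dot L_{kill} I.}
#' Matching the closed-form derivation, proliferation and point mutation are
#' inactive during the (brief) exposure, so M stays 0 and at high dose rate
#' I(T) converges to [initial_intermediate_cells()].
#'
#' @param proto [exposure_protocol()].
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp parameter objects.
#' @param n_steps number of output grid points over the exposure window.
#' @return A \code{cell_trajectory}: data frame with columns
#'   \code{time_months}, \code{N}, \code{I}, \code{M}.
#' @export
integrate_exposure_ode <- function(proto, scenario = "hrs_minus",
                                   lp = leukemogenesis_params(),
                                   rp = radiosensitivity_params(),
                                   n_steps = 200L) {
  scenario <- match_scenario(scenario)
  if (proto$total_dose == 0) {
    traj <- data.frame(time_months = c(0, 1), N = lp$N0, I = 0, M = 0)
    class(traj) <- c("cell_trajectory", "data.frame")
    return(traj)
  }
  Ddot <- proto$dose_rate
  D <- proto$total_dose
  # rates per unit time; the induced-repair alpha is evaluated at the
  # protocol's total dose, constant during exposure
  a_kill <- switch(scenario,
                   hrs_minus = rp$alpha_r,
                   alpha_induced_repair(D, rp))
  a_del <- switch(scenario,
                  hrs_plus2 = alpha_induced_repair(
                    D, rp, slope_ratio_override = rp$deletion_slope_ratio),
                  rp$alpha_r)
  deriv <- function(t, y, parms) {
    Lk <- a_kill * Ddot + 2 * rp$beta * Ddot^2 * t
    Ld <- a_del * Ddot + 2 * rp$beta * Ddot^2 * t
    dN <- -Lk * y[1] - lp$mu_del * Ld * y[1]
    dI <- lp$mu_del * Ld * y[1] - Lk * y[2]
    list(c(dN, dI, 0))
  }
  times <- seq(0, proto$duration, length.out = n_steps + 1L)
  sol <- deSolve::ode(y = c(N = lp$N0, I = 0, M = 0), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed (solver state ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  traj <- data.frame(time_months = sol[, "time"], N = sol[, "N"],
                     I = sol[, "I"], M = sol[, "M"])
  class(traj) <- c("cell_trajectory", "data.frame")
  traj
}

#' Export a cell trajectory as CSV
#'
#' @param traj a \code{cell_trajectory}.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cell_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
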