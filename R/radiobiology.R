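#' Lethal events under the linear-quadratic model
#'
#' Expected number of lethal events \eqn{L(D) = \alpha_r D + \beta D^2}
#' after an acute dose D. The clonogenic surviving fraction is
#' \eqn{S(D) = e^{-L(D)}}.
#'
#' @param D absorbed dose (Gy); vectorised.
#' @param p [radiosensitivity_params()].
#' @return Expected lethal-event count (dimensionless), same length as D.
#' @export
lethal_events_lq <- function(D, p = radiosensitivity_params()) {
  check_dose(D)
  p$alpha_r * D + p$beta * D^2
}

check_dose <- function(D) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0)) {
    stop("dose must be finite and >= 0", call. = FALSE)
  }
  invisible(D)
}

#' Dose-dependent linear coefficient of the induced-repair model
#'
#' \deqn{\alpha(D) = \alpha_r (1 + (\alpha_s/\alpha_r - 1) e^{-D/D_c})}
#' interpolates from the steep hypersensitive slope \eqn{\alpha_s} at zero
#' dose down to the conventional \eqn{\alpha_r} as increased radioresistance
#' is induced; \eqn{D_c} is the dose at which the transition is 63% complete.
#'
#' @param D absorbed dose (Gy); vectorised.
#' @param p [radiosensitivity_params()].
#' @param slope_ratio_override optional \eqn{\alpha_s/\alpha_r} ratio to use
#'   instead of \code{p$alpha_s / p$alpha_r} (used for deletion induction,
#'   where the ratio is assumed rather than fitted to survival data).
#' @return rate per Gy, same length as D.
#' @export
alpha_induced_repair <- function(D, p = radiosensitivity_params(),
                                 slope_ratio_override = NULL) {
  check_dose(D)
  ratio <- if (is.null(slope_ratio_override)) p$alpha_s / p$alpha_r else
    slope_ratio_override
  p$alpha_r * (1 + (ratio - 1) * exp(-D / p$D_c))
}

#' Lethal events under the induced-repair (HRS) model
#'
#' \eqn{L_{HRS}(D) = \alpha(D) D + \beta D^2}, governing cell killing for
#' hyper-radiosensitive target cells. Always at least the LQ count when
#' \code{alpha_s > alpha_r}, with the excess vanishing at high dose.
#'
#' @inheritParams lethal_events_lq
#' @return Expected lethal-event count, same length as D.
#' @export
lethal_events_hrs <- function(D, p = radiosensitivity_params()) {
  alpha_induced_repair(D, p) * D + p$beta * D^2
}

#' HRS-modified lethal events for deletion induction
#'
#' Same induced-repair form as [lethal_events_hrs()] but with the low-dose
#' slope set to \code{deletion_slope_ratio * alpha_r} (default ratio 3).
#' This function drives the induction of the Sfpi1 deletion in the
#' \code{"hrs_plus2"} scenario only; it never enters cell killing.
#'
#' @inheritParams lethal_events_lq
#' @return Expected lethal-event count, same length as D.
#' @export
lethal_events_hrs_deletion <- function(D, p = radiosensitivity_params()) {
  alpha_induced_repair(D, p, slope_ratio_override = p$deletion_slope_ratio) *
    D + p$beta * D^2
}

#' Clonogenic surviving fraction
#'
#' @inheritParams lethal_events_lq
#' @param kind survival model: \code{"lq"} (conventional linear-quadratic)
#'   or \code{"induced_repair"} (low-dose hyper-radiosensitivity).
#' @return Surviving fraction in (0, 1], same length as D.
#' @examples
#' survival_fraction(0.06, kind = "induced_repair") # about 0.64
#' @export
survival_fraction <- function(D, p = radiosensitivity_params(),
                              kind = c("lq", "induced_repair")) {
  kind <- match.arg(kind)
  L <- switch(kind,
              lq = lethal_events_lq(D, p),
              induced_repair = lethal_events_hrs(D, p))
  exp(-L)
}

#' Lethal-event rate during constant-rate exposure
#'
#' Time derivative of the cumulative lethal-event count while dose is being
#' absorbed at constant rate: \eqn{\dot L(t) = \alpha \dot D + 2\beta \dot
#' D^2 t} for \eqn{0 \le t \le T = D/\dot D} and zero afterwards. For the
#' induced-repair variant, \eqn{\alpha} is \eqn{\alpha(D)} evaluated at the
#' protocol's total dose (constant during the exposure).
#'
#' @param t time since exposure start (months); vectorised.
#' @param proto [exposure_protocol()].
#' @param p [radiosensitivity_params()].
#' @param kind \code{"lq"} or \code{"induced_repair"}.
#' @return rate per month, same length as t.
#' @export
lethal_event_rate <- function(t, proto, p = radiosensitivity_params(),
                              kind = c("lq", "induced_repair")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(t), all(t >= 0))
  a <- switch(kind,
              lq = p$alpha_r,
              induced_repair = alpha_induced_repair(proto$total_dose, p))
  rate <- a * proto$dose_rate + 2 * p$beta * proto$dose_rate^2 * t
  rate[t > proto$duration] <- 0
  rate
}
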