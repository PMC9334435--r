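#' Dose-group cohort incidence data
#'
#' One record per experimental dose group: dose, number of mice and number
#' of rAML cases. Observed incidences enter the cost function in percent,
#' weighted by each group's share of the total mouse count.
#'
#' @param dose_Gy dose per group (Gy).
#' @param n_mice mice per group.
#' @param n_cases rAML cases per group (may be non-integer for noise-free
#'   synthetic cohorts).
#' @return A \code{cohort_data} data frame.
#' @export
cohort_data <- function(dose_Gy, n_mice, n_cases) {
  stopifnot(length(dose_Gy) == length(n_mice),
            length(n_mice) == length(n_cases),
            all(dose_Gy >= 0), all(n_mice >= 1), all(n_cases >= 0))
  if (any(n_cases > n_mice)) {
    stop("'n_cases' cannot exceed 'n_mice'", call. = FALSE)
  }
  structure(data.frame(dose_Gy = dose_Gy, n_mice = n_mice,
                       n_cases = n_cases),
            class = c("cohort_data", "data.frame"))
}

#' Time-resolved cumulative incidence data
#'
#' Cumulative rAML incidence (percent of the cohort) observed at increasing
#' times after a single acute dose; used for the second, shape-matching
#' term of the fitting cost, normalised by its final time point and
#' weighted by \code{w2}, the mean incidence at that dose.
#'
#' @param time_months observation times (months, increasing).
#' @param cum_percent cumulative incidence (percent, non-decreasing).
#' @param w2 weight: mean observed incidence at the time-course dose
#'   (percent).
#' @param dose_Gy the time-course dose (Gy, default 4.5).
#' @param n_mice number of mice in the time-course arm (optional; used for
#'   the standard-error covariance of the fit).
#' @return A \code{time_course_data} data frame with attributes \code{w2},
#'   \code{dose_Gy} and \code{n_mice}.
#' @export
time_course_data <- function(time_months, cum_percent, w2, dose_Gy = 4.5,
                             n_mice = NULL) {
  stopifnot(length(time_months) == length(cum_percent),
            !is.unsorted(time_months), !is.unsorted(cum_percent),
            all(cum_percent >= 0), w2 >= 0)
  structure(data.frame(time_months = time_months,
                       cum_percent = cum_percent),
            w2 = w2, dose_Gy = dose_Gy, n_mice = n_mice,
            class = c("time_course_data", "data.frame"))
}

#' Mouse-weighted mean incidence at a dose
#'
#' Helper used to compute the time-course weight \code{w2}: the
#' mouse-weighted mean rAML incidence (percent) over the cohort records at
#' the given dose.
#'
#' @param cohort a [cohort_data()].
#' @param dose_Gy dose to select (Gy).
#' @return percent.
#' @export
mean_incidence_at_dose <- function(cohort, dose_Gy = 4.5) {
  rec <- cohort[abs(cohort$dose_Gy - dose_Gy) < 1e-9, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop("no cohort records at dose ", dose_Gy, " Gy", call. = FALSE)
  }
  100 * sum(rec$n_cases) / sum(rec$n_mice)
}

# Weighted residual vector whose sum of squares is the cost:
#   r1_i = w1(i) (y(i) - yhat(i)),   w1(i) = n_mice,i / sum(n_mice)
#   r2_i = w2 (z(t_i)/z(t_20) - zhat(t_i)/zhat(t_20))
fit_residuals <- function(p, cohort, timecourse, scenario, lp, rp, mp) {
  lp_try <- leukemogenesis_params(N0 = lp$N0, mu_del = lp$mu_del,
                                  b = p[["b"]], mu_p = p[["mu_p"]],
                                  t_lag = lp$t_lag)
  w1 <- cohort$n_mice / sum(cohort$n_mice)
  y <- 100 * cohort$n_cases / cohort$n_mice
  doses <- sort(unique(cohort$dose_Gy))
  phat <- raml_probability(doses, scenario, lp_try, rp, mp)
  yhat <- 100 * phat[match(cohort$dose_Gy, doses)]
  r1 <- w1 * (y - yhat)
  tc_dose <- attr(timecourse, "dose_Gy")
  zhat <- 100 * cumulative_incidence(timecourse$time_months, tc_dose,
                                     scenario, lp_try, rp, mp)
  z_final <- timecourse$cum_percent[nrow(timecourse)]
  zhat_final <- zhat[length(zhat)]
  if (z_final <= 0 || zhat_final <= 0) {
    stop("cumulative incidence at the final time point is zero; ",
         "normalisation undefined", call. = FALSE)
  }
  r2 <- attr(timecourse, "w2") *
    (timecourse$cum_percent / z_final - zhat / zhat_final)
  c(r1, r2)
}

#' Weighted least-squares cost for the proliferation parameters
#'
#' The cost joins a dose-response term and a time-course shape term:
#' \deqn{C(p) = \sum_i \big(w_1(i)(y(i) - \hat y(i, p))\big)^2 +
#'   \sum_i \Big(w_2 \big(\tfrac{z(t_i)}{z(t_{20})} -
#'   \tfrac{\hat z(t_i,p)}{\hat z(t_{20},p)}\big)\Big)^2,}
#' where y are observed dose-group incidence percentages weighted by each
#' group's fraction of the total mice, and z is the cumulative incidence
#' time course, normalised by its final point so model and data share the
#' same end value, weighted by the mean incidence at the time-course dose.
#'
#' @param p named vector with elements \code{b} and \code{mu_p} (per
#'   month), both > 0.
#' @param cohort a [cohort_data()].
#' @param timecourse a [time_course_data()].
#' @param scenario HRS scenario used for the model predictions.
#' @param lp,rp,mp fixed parameter objects (\code{b} and \code{mu_p} in
#'   \code{lp} are overridden by \code{p}).
#' @return non-negative scalar.
#' @export
cost_function <- function(p, cohort, timecourse, scenario = "hrs_minus",
                          lp = leukemogenesis_params(),
                          rp = radiosensitivity_params(),
                          mp = mortality_params()) {
  if (any(p <= 0)) stop("parameters must be positive", call. = FALSE)
  sum(fit_residuals(p, cohort, timecourse, scenario, lp, rp, mp)^2)
}

#' Estimate the proliferation and point-mutation rates
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) on the stacked
#' weighted residual vector of [cost_function()], with \code{b} and
#' \code{mu_p} log-transformed to enforce positivity. Standard errors are
#' asymptotic, from a sandwich combining the residual Jacobian at the
#' optimum with the model-based covariance of the data: independent
#' binomial variance per dose group, and the empirical-process covariance
#' \eqn{G_i(1-G_j)/k} of the normalised cumulative time course (k the
#' expected number of counted cases). The naive homoscedastic formula
#' would badly understate the uncertainty here because the two residual
#' blocks of the cost have very different noise scales and the cumulative
#' curve's errors are serially correlated.
#'
#' @param cohort a [cohort_data()].
#' @param timecourse a [time_course_data()].
#' @param start named start values for \code{b} and \code{mu_p}.
#' @param scenario HRS scenario.
#' @param lp,rp,mp fixed parameter objects.
#' @return A \code{fit_result} list: \code{b_hat}, \code{mu_p_hat},
#'   \code{se_b}, \code{se_mu_p}, \code{cost}, \code{converged},
#'   \code{identifiable}, \code{start}, \code{niter}, \code{message}.
#'   Non-convergence is flagged, not raised.
#' @export
fit_proliferation_parameters <- function(cohort, timecourse,
                                         start = c(b = 0.0624,
                                                   mu_p = 6.87e-5),
                                         scenario = "hrs_minus",
                                         lp = leukemogenesis_params(),
                                         rp = radiosensitivity_params(),
                                         mp = mortality_params()) {
  stopifnot(all(start > 0), all(c("b", "mu_p") %in% names(start)))
  identifiable <- length(unique(cohort$dose_Gy)) >= 2
  resid_log <- function(logp) {
    p <- exp(logp)
    names(p) <- c("b", "mu_p")
    fit_residuals(p, cohort, timecourse, scenario, lp, rp, mp)
  }
  fit <- minpack.lm::nls.lm(
    par = log(start[c("b", "mu_p")]), fn = resid_log,
    control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12,
                                         ptol = 1e-10))
  est <- exp(fit$par)
  names(est) <- c("b", "mu_p")
  converged <- fit$info %in% 1:4
  se <- c(NA_real_, NA_real_)
  if (identifiable) {
    cv <- try(fit_sandwich_cov(est, fit$par, resid_log, cohort, timecourse,
                               scenario, lp, rp, mp), silent = TRUE)
    if (!inherits(cv, "try-error") && all(is.finite(diag(cv))) &&
        all(diag(cv) >= 0)) {
      se <- est * sqrt(diag(cv)) # delta method, log to natural scale
    } else {
      identifiable <- FALSE
    }
  }
  structure(list(b_hat = unname(est[1]), mu_p_hat = unname(est[2]),
                 se_b = unname(se[1]), se_mu_p = unname(se[2]),
                 cost = sum(fit$fvec^2), converged = converged,
                 identifiable = identifiable,
                 start = start, niter = fit$niter,
                 message = fit$message),
            class = "fit_result")
}

# Model-based sandwich covariance of (log b, log mu_p):
#   V = (J'J)^-1 J' Omega J (J'J)^-1,
# J the numerical Jacobian of the weighted residuals at the optimum and
# Omega the covariance the generating process implies for those residuals:
#  - dose block: Var(r1_i) = w1_i^2 * 100^2 * p_i(1-p_i)/m_i, independent;
#  - time-course block: the normalised cumulative curve is a binomial
#    empirical CDF given the counted cases k, so
#    Cov(r2_i, r2_j) = w2^2 * G_i (1 - G_j) / k for t_i <= t_j,
#    with G the model's normalised curve and k = n_mice * zhat(t_20)/100.
fit_sandwich_cov <- function(est, logpar, resid_log, cohort, timecourse,
                             scenario, lp, rp, mp) {
  n1 <- nrow(cohort)
  n2 <- nrow(timecourse)
  # central-difference Jacobian in log-parameter space
  h <- 1e-5
  J <- vapply(1:2, function(j) {
    dp <- logpar
    dm <- logpar
    dp[j] <- dp[j] + h
    dm[j] <- dm[j] - h
    (resid_log(dp) - resid_log(dm)) / (2 * h)
  }, numeric(n1 + n2))
  lp_hat <- leukemogenesis_params(N0 = lp$N0, mu_del = lp$mu_del,
                                  b = est[["b"]], mu_p = est[["mu_p"]],
                                  t_lag = lp$t_lag)
  w1 <- cohort$n_mice / sum(cohort$n_mice)
  doses <- sort(unique(cohort$dose_Gy))
  phat <- raml_probability(doses, scenario, lp_hat, rp, mp)
  p_i <- phat[match(cohort$dose_Gy, doses)]
  v1 <- w1^2 * 1e4 * p_i * (1 - p_i) / cohort$n_mice
  tc_dose <- attr(timecourse, "dose_Gy")
  n_tc <- attr(timecourse, "n_mice")
  if (is.null(n_tc)) {
    n_tc <- sum(cohort$n_mice[abs(cohort$dose_Gy - tc_dose) < 1e-9])
  }
  zhat <- 100 * cumulative_incidence(timecourse$time_months, tc_dose,
                                     scenario, lp_hat, rp, mp)
  G <- zhat / zhat[n2]
  k <- n_tc * zhat[n2] / 100
  w2 <- attr(timecourse, "w2")
  Om2 <- outer(seq_len(n2), seq_len(n2), function(i, j) {
    G[pmin(i, j)] * (1 - G[pmax(i, j)]) / k
  }) * w2^2
  Omega <- matrix(0, n1 + n2, n1 + n2)
  diag(Omega)[seq_len(n1)] <- v1
  Omega[n1 + seq_len(n2), n1 + seq_len(n2)] <- Om2
  jtj_inv <- solve(crossprod(J))
  jtj_inv %*% crossprod(J, Omega %*% J) %*% jtj_inv
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Two-mutation rAML model fit (b, mu_p)\n")
  cat(sprintf("  b     = %.4g +/- %.3g per month\n", x$b_hat, x$se_b))
  cat(sprintf("  mu_p  = %.4g +/- %.3g per month\n", x$mu_p_hat, x$se_mu_p))
  cat(sprintf("  cost  = %.4g; converged: %s; identifiable: %s\n",
              x$cost, x$converged, x$identifiable))
  invisible(x)
}

#' Read cohort and time-course CSV files
#'
#' Cohort files have columns \code{dose_Gy}, \code{n_mice}, \code{n_cases};
#' time-course files have columns \code{time_months}, \code{cum_cases},
#' \code{n_mice} (cumulative cases are converted to percent of the cohort).
#'
#' @param path CSV file.
#' @param w2 time-course weight (percent); required for the time-course
#'   reader, typically [mean_incidence_at_dose()] of the matching cohort.
#' @param dose_Gy the time-course dose (Gy).
#' @return A [cohort_data()] or [time_course_data()].
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("dose_Gy", "n_mice", "n_cases")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cohort_data(df$dose_Gy, df$n_mice, df$n_cases)
}

#' @rdname read_cohort_csv
#' @export
read_time_course_csv <- function(path, w2, dose_Gy = 4.5) {
  df <- utils::read.csv(path)
  need <- c("time_months", "cum_cases", "n_mice")
  if (!all(need %in% names(df))) {
    stop("time-course CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  time_course_data(df$time_months, 100 * df$cum_cases / df$n_mice,
                   w2 = w2, dose_Gy = dose_Gy, n_mice = df$n_mice[1])
}
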