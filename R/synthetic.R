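#' Design of a synthetic mouse cohort experiment
#'
#' Mirrors the structure of the historical CBA/H irradiation experiments
#' behind the model's calibration: dose groups of 0.75-6.0 Gy with four
#' replicate groups per dose (20 dose-response points) and a 20-point
#' cumulative-incidence time course after 4.5 Gy. The replicate size
#' default of 250 gives dose groups of a thousand mice, the scale of the
#' historical experiments (the 4.5 Gy time-course cohort alone counted
#' over a thousand animals).
#'
#' @param doses dose groups (Gy).
#' @param replicates_per_dose replicate groups per dose.
#' @param mice_per_replicate mice per replicate group.
#' @param timecourse_dose dose of the time-course arm (Gy).
#' @param timecourse_times observation times (months).
#' @return A \code{cohort_design} list.
#' @export
cohort_design <- function(doses = c(0.75, 1.5, 3.0, 4.5, 6.0),
                          replicates_per_dose = 4L,
                          mice_per_replicate = 250L,
                          timecourse_dose = 4.5,
                          timecourse_times = seq(6, 30, length.out = 20L)) {
  stopifnot(all(doses > 0), replicates_per_dose >= 1,
            mice_per_replicate >= 1, timecourse_dose %in% doses,
            !is.unsorted(timecourse_times))
  structure(list(doses = doses,
                 replicates_per_dose = as.integer(replicates_per_dose),
                 mice_per_replicate = as.integer(mice_per_replicate),
                 timecourse_dose = timecourse_dose,
                 timecourse_times = timecourse_times),
            class = "cohort_design")
}

#' Generate a synthetic cohort and time-course dataset
#'
#' Draws dose-group case counts from the analytic lifetime rAML
#' probability (binomial sampling per replicate group) and a cumulative
#' time course at the design's time-course dose: case diagnosis times are
#' sampled from the normalised diagnosis-time density via inverse-CDF on
#' the analytic cumulative curve, then accumulated at the design's
#' observation times. With \code{noise = FALSE} the analytic values are
#' returned directly (expected counts, no sampling), so the fitting cost
#' at the generating parameters is numerically zero.
#'
#' @param design a [cohort_design()].
#' @param scenario one of [hrs_scenarios].
#' @param lp,rp,mp generating parameter objects.
#' @param seed integer seed (required when \code{noise = TRUE}).
#' @param noise draw binomial/event-time sampling noise?
#' @return list with \code{cohort} (a [cohort_data()]) and
#'   \code{timecourse} (a [time_course_data()] whose \code{w2} attribute is
#'   the mouse-weighted mean incidence of the generated records at the
#'   time-course dose).
#' @export
generate_cohort_dataset <- function(design = cohort_design(),
                                    scenario = "hrs_minus",
                                    lp = leukemogenesis_params(),
                                    rp = radiosensitivity_params(),
                                    mp = mortality_params(),
                                    seed = NULL, noise = TRUE) {
  scenario <- match_scenario(scenario)
  if (noise) {
    if (is.null(seed)) stop("'seed' is required when noise = TRUE",
                            call. = FALSE)
    set.seed(seed)
  }
  p_dose <- raml_probability(design$doses, scenario, lp, rp, mp)
  dose_rep <- rep(design$doses, each = design$replicates_per_dose)
  p_rep <- rep(p_dose, each = design$replicates_per_dose)
  m <- design$mice_per_replicate
  n_cases <- if (noise) {
    stats::rbinom(length(dose_rep), m, p_rep)
  } else {
    m * p_rep
  }
  cohort <- cohort_data(dose_rep, rep(m, length(dose_rep)), n_cases)

  tc_dose <- design$timecourse_dose
  tc_times <- design$timecourse_times
  n_tc <- m * design$replicates_per_dose
  if (noise) {
    # sample diagnosis times among cases from the normalised f_d by
    # inverse-CDF on a fine analytic cumulative grid
    p_tc <- p_dose[match(tc_dose, design$doses)]
    k <- stats::rbinom(1, n_tc, p_tc)
    horizon <- mortality_horizon(tc_dose, mp)
    grid <- seq(lp$t_lag, horizon, length.out = 2001L)
    cum <- cumulative_incidence(grid, tc_dose, scenario, lp, rp, mp)
    u <- stats::runif(k, 0, max(cum))
    t_diag <- stats::approx(cum, grid, xout = u, ties = "ordered")$y
    cum_cases <- vapply(tc_times, function(tt) sum(t_diag <= tt),
                        numeric(1))
    z <- 100 * cum_cases / n_tc
  } else {
    z <- 100 * cumulative_incidence(tc_times, tc_dose, scenario, lp, rp, mp)
  }
  tc_records <- abs(cohort$dose_Gy - tc_dose) < 1e-9
  w2 <- 100 * sum(cohort$n_cases[tc_records]) / sum(cohort$n_mice[tc_records])
  list(cohort = cohort,
       timecourse = time_course_data(tc_times, z, w2 = w2,
                                     dose_Gy = tc_dose, n_mice = n_tc))
}

#' Write a synthetic dataset to CSV files
#'
#' Emits the two files consumed by the fitting interface: a cohort file
#' (\code{dose_Gy}, \code{n_mice}, \code{n_cases}) and a time-course file
#' (\code{time_months}, \code{cum_cases}, \code{n_mice}).
#'
#' @param dataset result of [generate_cohort_dataset()].
#' @param cohort_path,timecourse_path output files.
#' @param n_mice_timecourse total mice in the time-course arm.
#' @export
write_synthetic_csv <- function(dataset, cohort_path, timecourse_path,
                                n_mice_timecourse = NULL) {
  utils::write.csv(as.data.frame(dataset$cohort), cohort_path,
                   row.names = FALSE)
  tc <- dataset$timecourse
  if (is.null(n_mice_timecourse)) {
    rec <- abs(dataset$cohort$dose_Gy - attr(tc, "dose_Gy")) < 1e-9
    n_mice_timecourse <- sum(dataset$cohort$n_mice[rec])
  }
  utils::write.csv(data.frame(time_months = tc$time_months,
                              cum_cases = tc$cum_percent / 100 *
                                n_mice_timecourse,
                              n_mice = n_mice_timecourse),
                   timecourse_path, row.names = FALSE)
  invisible(c(cohort_path, timecourse_path))
}
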