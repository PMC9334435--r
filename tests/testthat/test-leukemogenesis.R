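test_that("initial pre-leukemic cell count behaves at the dose extremes", {
  for (sc in hrs_scenarios) {
    expect_equal(initial_intermediate_cells(0, sc, lp0, rp0), 0)
    expect_lt(initial_intermediate_cells(50, sc, lp0, rp0), 1e-6)
  }
  expect_error(initial_intermediate_cells(1, "hrs_plus3", lp0, rp0),
               "unknown HRS scenario")
  # expm1 keeps low-dose counts accurate: I0 ~ N0 mu_del L for small L
  D <- 1e-4
  expect_equal(initial_intermediate_cells(D, "hrs_minus", lp0, rp0),
               lp0$N0 * lp0$mu_del * lethal_events_lq(D, rp0),
               tolerance = 1e-3)
})

test_that("pre-leukemic maximum sits near 2.7 Gy and matches the analytic condition", {
  am <- pre_leukemic_dose_argmax("hrs_minus", lp0, rp0)
  expect_equal(am$dose, am$analytic_dose, tolerance = 1e-6)
  # lethal events at the optimum satisfy L* = ln(1+mu_del)/mu_del
  expect_equal(lethal_events_lq(am$dose, rp0),
               log1p(lp0$mu_del) / lp0$mu_del, tolerance = 1e-6)
  expect_equal(am$dose, 2.668318, tolerance = 1e-5)
})

test_that("post-exposure growth follows the closed forms", {
  expect_equal(intermediate_cells(0, 100, lp0), 100)
  t2 <- log(2) / (lp0$b - lp0$mu_p)
  expect_equal(intermediate_cells(t2, 100, lp0), 200, tolerance = 1e-12)
  expect_equal(intermediate_cells(12, 100, lp0), 329.9397, tolerance = 1e-6)
  expect_equal(expected_malignant_cells(0, 100, lp0), 0)
  expect_equal(expected_malignant_cells(20, 0, lp0), 0)
  # dM/dt = mu_p I(t), checked by central differences
  h <- 1e-4
  for (t in c(1, 10, 25)) {
    dM <- (expected_malignant_cells(t + h, 100, lp0) -
             expected_malignant_cells(t - h, 100, lp0)) / (2 * h)
    expect_equal(dM, lp0$mu_p * intermediate_cells(t, 100, lp0),
                 tolerance = 1e-8)
  }
})

test_that("first-malignant-cell density is a proper density with correct support", {
  expect_equal(first_malignant_density(c(0, 5, 50), 0, lp0), c(0, 0, 0))
  q <- integrate(function(t) first_malignant_density(t, 10, lp0), 0, Inf,
                 rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
  # latency shift: zero before t_lag, translated copy after
  expect_equal(potential_diagnosis_density(lp0$t_lag / 2, 10, lp0), 0)
  s <- c(0.5, 3, 12)
  expect_equal(potential_diagnosis_density(lp0$t_lag + s, 10, lp0),
               first_malignant_density(s, 10, lp0))
})

test_that("scenario ordering and ratio identities hold for I0", {
  D <- seq(0.01, 6, length.out = 120)
  i_minus <- initial_intermediate_cells(D, "hrs_minus", lp0, rp0)
  i_p1 <- initial_intermediate_cells(D, "hrs_plus1", lp0, rp0)
  i_p2 <- initial_intermediate_cells(D, "hrs_plus2", lp0, rp0)
  expect_true(all(i_p1 <= i_minus))
  # killing-only HRS suppresses exactly by the extra killing
  expect_equal(i_p1 / i_minus,
               exp(-(lethal_events_hrs(D, rp0) - lethal_events_lq(D, rp0))),
               tolerance = 1e-12)
  # ... which is also the survival-fraction quotient
  expect_equal(i_minus / i_p1,
               survival_fraction(D, rp0, "lq") /
                 survival_fraction(D, rp0, "induced_repair"),
               tolerance = 1e-12)
  # deletion-stimulating HRS wins at very low doses only
  expect_gt(initial_intermediate_cells(0.02, "hrs_plus2", lp0, rp0),
            initial_intermediate_cells(0.02, "hrs_minus", lp0, rp0))
  hi <- D >= 0.5
  expect_true(all(abs(i_p1[hi] / i_minus[hi] - 1) < 0.01))
  expect_true(all(abs(i_p2[hi] / i_minus[hi] - 1) < 0.01))
})

test_that("ODE solution converges to the acute closed form at high dose rate", {
  proto <- exposure_protocol(3, dose_rate = 1e4)
  for (sc in hrs_scenarios) {
    traj <- integrate_exposure_ode(proto, sc, lp0, rp0)
    I0 <- initial_intermediate_cells(3, sc, lp0, rp0)
    expect_lt(abs(traj$I[nrow(traj)] - I0) / I0, 1e-3)
    expect_true(all(traj$N >= 0) && all(traj$I >= 0))
  }
  # zero dose: constant trajectory
  traj0 <- integrate_exposure_ode(exposure_protocol(0), "hrs_minus", lp0, rp0)
  expect_true(all(traj0$N == lp0$N0) && all(traj0$I == 0) &&
                all(traj0$M == 0))
})

test_that("trajectories export with the documented columns", {
  proto <- exposure_protocol(1, dose_rate = 1e4)
  traj <- integrate_exposure_ode(proto, "hrs_minus", lp0, rp0, n_steps = 20)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- read.csv(f)
  expect_named(back, c("time_months", "N", "I", "M"))
  expect_equal(back$I, traj$I, tolerance = 1e-12)
})
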