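test_that("diagnosis-time density is the mortality-damped potential density", {
  tgrid <- seq(0, 40, by = 0.25)
  dc <- diagnosis_density(tgrid, 4.5, "hrs_minus", lp0, rp0, mp0)
  I0 <- initial_intermediate_cells(4.5, "hrs_minus", lp0, rp0)
  fA <- potential_diagnosis_density(tgrid, I0, lp0)
  expect_true(all(dc$values >= 0))
  expect_true(all(dc$values <= fA + 1e-15))
  expect_true(all(dc$values[tgrid < lp0$t_lag] == 0))
  # zero dose means no pre-leukemic cells and no diagnoses
  expect_true(all(diagnosis_density(tgrid, 0, "hrs_minus", lp0, rp0,
                                    mp0)$values == 0))
})

test_that("lifetime rAML probability agrees with an independent trapezoidal integral", {
  p <- raml_probability(3, "hrs_minus", lp0, rp0, mp0)
  g <- seq(lp0$t_lag, 120, length.out = 20001)
  fd <- diagnosis_density(g, 3, "hrs_minus", lp0, rp0, mp0)$values
  trap <- sum((fd[-1] + fd[-length(fd)]) / 2 * diff(g))
  expect_equal(p, trap, tolerance = 1e-6)
  expect_equal(raml_probability(0, "hrs_minus", lp0, rp0, mp0), 0)
  expect_true(p > 0 && p < 1)
})

test_that("incidence peaks near 2.5 Gy", {
  am <- raml_dose_argmax("hrs_minus", lp0, rp0, mp0)
  expect_equal(am$dose, 2.5, tolerance = 0.25 / 2.5)
  expect_gt(am$p_raml, 0.2)
})

test_that("cumulative incidence rises monotonically to the lifetime probability", {
  times <- seq(0, 100, by = 1)
  ci <- cumulative_incidence(times, 4.5, "hrs_minus", lp0, rp0, mp0)
  expect_equal(ci[times <= lp0$t_lag], rep(0, sum(times <= lp0$t_lag)))
  expect_true(all(diff(ci) >= 0))
  expect_equal(ci[length(ci)], raml_probability(4.5, "hrs_minus", lp0, rp0, mp0),
               tolerance = 1e-6)
})

test_that("scenario dose-response curves keep their order and converge", {
  doses <- c(0.02, 0.04, 0.06, 0.08, 0.1, 0.5, 1, 3)
  p <- sapply(hrs_scenarios, function(sc)
    raml_probability(doses, sc, lp0, rp0, mp0))
  expect_true(all(p[, "hrs_plus1"] <= p[, "hrs_minus"]))
  # deletion-stimulating HRS raises incidence at very low doses
  low <- doses <= 0.06
  expect_true(all(p[low, "hrs_plus2"] > p[low, "hrs_minus"]))
  hi <- doses >= 0.5
  expect_true(all(abs(p[hi, ] / p[hi, "hrs_minus"] - 1) < 0.01))
  # killing-only suppression equals the pre-leukemic suppression ratio
  i_ratio <- initial_intermediate_cells(doses[low], "hrs_plus1", lp0, rp0) /
    initial_intermediate_cells(doses[low], "hrs_minus", lp0, rp0)
  expect_equal(p[low, "hrs_plus1"] / p[low, "hrs_minus"], i_ratio,
               tolerance = 2e-3)
  # maximum relative suppression sits at the HRS-effect dose ~0.06 Gy
  supp <- function(D) 1 - raml_probability(D, "hrs_plus1", lp0, rp0, mp0) /
    raml_probability(D, "hrs_minus", lp0, rp0, mp0)
  expect_equal(optimize(supp, c(0.01, 0.3), maximum = TRUE)$maximum, 0.06,
               tolerance = 0.02 / 0.06)
})

test_that("dose-response container enforces its contract", {
  cur <- dose_response_curve(c(0, 1, 2), "hrs_minus", lp0, rp0, mp0)
  expect_s3_class(cur, "dose_response_curve")
  expect_equal(cur$p_raml[1], 0)
  expect_error(dose_response_curve(c(0, 1), "bogus", lp0, rp0, mp0),
               "unknown HRS scenario")
})

test_that("low-dose LQ fit recovers exact polynomial input and rejects bad input", {
  D <- seq(0, 0.2, length.out = 11)
  exact <- structure(data.frame(dose_Gy = D, scenario = "hrs_minus",
                                p_raml = (2 * D + 5 * D^2) / 100),
                     class = c("dose_response_curve", "data.frame"))
  fit <- fit_lq_approximation(exact)
  expect_equal(fit$c1, 2, tolerance = 1e-10)
  expect_equal(fit$c2, 5, tolerance = 1e-10)
  zero <- exact
  zero$p_raml <- 0
  fit0 <- fit_lq_approximation(zero)
  expect_equal(c(fit0$c1, fit0$c2), c(0, 0))
  expect_error(fit_lq_approximation(exact[1:2, ]), "at least 3")
  toohigh <- exact
  toohigh$dose_Gy <- toohigh$dose_Gy * 2
  expect_error(fit_lq_approximation(toohigh), "0.2 Gy")
})

test_that("HRS-modified linear coefficients have the documented limits", {
  cf1 <- list(c1_r = 3.63, c1_s = 71.9, D_c = 0.06)
  cf2 <- list(c1_r = 3, c1_s = 10.8, D_c = 0.026)
  expect_equal(hrs_modified_linear_coefficient(0, cf1, "hrs_plus1"), 3.63)
  expect_equal(hrs_modified_linear_coefficient(0, cf2, "hrs_plus2"), 10.8)
  expect_equal(hrs_modified_linear_coefficient(10 * 0.06, cf1, "hrs_plus1"),
               3.63, tolerance = 0.01)
  expect_equal(hrs_modified_linear_coefficient(10 * 0.026, cf2, "hrs_plus2"),
               3, tolerance = 0.01)
  # suppression form dips below c1_r at intermediate doses
  expect_lt(hrs_modified_linear_coefficient(0.06, cf1, "hrs_plus1"), 3.63)
})

test_that("descriptive HRS coefficient-form fit tracks the modelled curves", {
  doses <- seq(0.01, 0.3, length.out = 25)
  ref <- low_dose_lq_coefficients("hrs_minus", lp0, rp0, mp0)
  cur2 <- dose_response_curve(doses, "hrs_plus2", lp0, rp0, mp0)
  est <- fit_hrs_coefficient_forms(cur2, c2 = ref$c2)
  pred <- hrs_modified_linear_coefficient(doses, est, "hrs_plus2") * doses +
    ref$c2 * doses^2
  expect_lt(max(abs(pred - 100 * cur2$p_raml)), 0.05)
  expect_gt(est$c1_s, est$c1_r)
})
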