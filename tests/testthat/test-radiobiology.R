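test_that("LQ lethal-event count evaluates and is strictly increasing", {
  expect_equal(lethal_events_lq(0, rp0), 0)
  # 0.0402*3 + 0.122*9, evaluated by hand
  expect_equal(lethal_events_lq(3, rp0), 1.2186, tolerance = 1e-12)
  expect_lt(lethal_events_lq(2, rp0), lethal_events_lq(3, rp0))
  expect_error(lethal_events_lq(-1, rp0), "dose")
})

test_that("induced-repair alpha interpolates from alpha_s to alpha_r", {
  expect_equal(alpha_induced_repair(0, rp0), 20)
  # at D = D_c: alpha_r + (alpha_s - alpha_r) e^-1
  expect_equal(alpha_induced_repair(0.06, rp0),
               0.0402 + (20 - 0.0402) * exp(-1), tolerance = 1e-12)
  expect_equal(alpha_induced_repair(0.06, rp0), 7.383, tolerance = 1e-4)
  lim <- 0.0402 + (20 - 0.0402) * exp(-10)
  expect_equal(alpha_induced_repair(0.6, rp0), lim, tolerance = 1e-4 * lim)
  # monotone decreasing on [0, 10 D_c]
  grid <- alpha_induced_repair(seq(0, 0.6, length.out = 200), rp0)
  expect_true(all(diff(grid) < 0))
  # override used for deletion induction
  expect_equal(alpha_induced_repair(0, rp0, slope_ratio_override = 3),
               3 * 0.0402)
})

test_that("HRS lethal events dominate LQ and converge back at high dose", {
  expect_equal(lethal_events_hrs(0, rp0), 0)
  expect_equal(lethal_events_hrs(0.06, rp0), 0.4434192, tolerance = 1e-6)
  D <- seq(0.01, 6, length.out = 100)
  # strict dominance until exp(-D/D_c) underflows, equality beyond
  expect_true(all(lethal_events_hrs(D, rp0) >= lethal_events_lq(D, rp0)))
  Dlow <- seq(0.01, 2, length.out = 50)
  expect_true(all(lethal_events_hrs(Dlow, rp0) > lethal_events_lq(Dlow, rp0)))
  expect_equal(lethal_events_hrs(10, rp0) / lethal_events_lq(10, rp0), 1,
               tolerance = 1e-6)
})

test_that("deletion-specific HRS lethal events use the assumed slope ratio", {
  expect_equal(lethal_events_hrs_deletion(0, rp0), 0)
  expect_equal(lethal_events_hrs_deletion(0.06, rp0),
               0.0402 * (1 + 2 * exp(-1)) * 0.06 + 0.122 * 0.0036,
               tolerance = 1e-12)
  expect_equal(lethal_events_hrs_deletion(10, rp0),
               lethal_events_lq(10, rp0), tolerance = 1e-6)
})

test_that("surviving fractions match the reported in vitro anchor points", {
  expect_equal(survival_fraction(0, rp0, "lq"), 1)
  expect_equal(survival_fraction(0, rp0, "induced_repair"), 1)
  # HRS maximum effect at 0.06 Gy: surviving fraction about 0.65
  expect_equal(survival_fraction(0.06, rp0, "induced_repair"), 0.65,
               tolerance = 0.02)
  # with the directly measured LT-HSC parameters the model only reaches 0.79
  rp_lt <- radiosensitivity_params(alpha_r = 0.63, alpha_s = 9.84,
                                   beta = 0.122, D_c = 0.06)
  expect_equal(round(survival_fraction(0.06, rp_lt, "induced_repair"), 2),
               0.79)
  D <- seq(0.01, 10, length.out = 50)
  s_lq <- survival_fraction(D, rp0, "lq")
  s_ir <- survival_fraction(D, rp0, "induced_repair")
  expect_true(all(s_ir <= s_lq))
  expect_true(all(s_ir[D <= 2] < s_lq[D <= 2]))
  expect_equal(s_ir[50] / s_lq[50], 1, tolerance = 1e-6)
})

test_that("lethal-event rate is piecewise and integrates to the cumulative count", {
  proto <- exposure_protocol(3, dose_rate = 6) # 0.5 months exposure
  expect_equal(lethal_event_rate(proto$duration + 0.1, proto, rp0, "lq"), 0)
  expect_equal(lethal_event_rate(0, proto, rp0, "lq"), 0.0402 * 6)
  for (kind in c("lq", "induced_repair")) {
    q <- integrate(function(t) lethal_event_rate(t, proto, rp0, kind),
                   0, proto$duration, rel.tol = 1e-12)
    target <- switch(kind, lq = lethal_events_lq(3, rp0),
                     induced_repair = lethal_events_hrs(3, rp0))
    expect_equal(q$value, target, tolerance = 1e-8)
  }
})

test_that("parameter constructors validate their invariants", {
  expect_error(radiosensitivity_params(alpha_r = -1), "positive")
  expect_error(radiosensitivity_params(alpha_s = 0.01), "alpha_s")
  expect_error(radiosensitivity_params(deletion_slope_ratio = 0.5), ">= 1")
  expect_error(leukemogenesis_params(b = 1e-6), "exceed")
  expect_error(exposure_protocol(-1), ">= 0")
  expect_error(mortality_params(omega = -2), "omega")
  expect_equal(exposure_protocol(3, 6)$duration, 0.5)
})
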