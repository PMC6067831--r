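test_that("release fraction saturates and matches its closed form", {
  expect_identical(release_fraction(0, 2.83), 0)
  expect_lt(abs(release_fraction(1, 2.83) - 0.9410), 5e-5)
  expect_lt(release_fraction(10, 2.83), 1)
  expect_lte(release_fraction(1e6, 2.83), 1)
  expect_gt(release_fraction(1e3, 2.83), 1 - 1e-10)
  cs <- seq(0, 5, by = 0.25)
  expect_true(all(diff(release_fraction(cs, 2.83)) > 0))
  expect_error(release_fraction(-0.1, 2.83), "nonnegative")
  expect_error(release_fraction(1, 0), "positive")
})

test_that("autocrine upregulation is a Hill curve with the reference scale", {
  p <- ref_params()
  expect_identical(autocrine_upregulation(0, p), 0)
  # half-saturation at c = 1/q1 = 25 by construction
  expect_equal(autocrine_upregulation(25, p), 21, tolerance = 1e-12)
  expect_equal(autocrine_upregulation(1e9, p), 42, tolerance = 1e-6)
})

test_that("pituitary feedback is decreasing and convex", {
  expect_identical(pituitary_feedback(0, 15), 1)
  expect_equal(pituitary_feedback(1 / 15, 15), 0.5, tolerance = 1e-12)
  expect_gt(pituitary_feedback(0.01, 15) + pituitary_feedback(0.03, 15),
            2 * pituitary_feedback(0.02, 15))
  grid <- seq(0, 2, by = 0.05)
  expect_true(all(diff(pituitary_feedback(grid, 15)) < 0))
})

test_that("GR production has the right basal level and saturation", {
  expect_equal(gr_production(0, 0.05, 0.11), 0.11, tolerance = 1e-14)
  expect_equal(gr_production(sqrt(0.05), 0.05, 0.11), 0.61, tolerance = 1e-12)
  expect_equal(gr_production(1e8, 0.05, 0.11), 1.11, tolerance = 1e-10)
})

test_that("the CRH synthesis target decreases from c_inf_bar + 1 to c_inf_bar", {
  expect_equal(crh_synthesis_target(0, 0.6, 0.25), 1.25, tolerance = 1e-14)
  expect_equal(crh_synthesis_target(1e6, 0.6, 0.25), 0.25, tolerance = 1e-12)
  o <- seq(0, 10, by = 0.5)
  expect_true(all(diff(crh_synthesis_target(o, 0.6, 0.25)) < 0))
})

test_that("system_rhs matches hand-computed limits", {
  p <- ref_params()
  d0 <- system_rhs(hpa_state(), 0, 0, 1, p)
  expect_equal(unname(d0["dcs"]), (p[["c_inf_bar"]] + 1) / p[["t_c"]],
               tolerance = 1e-14)
  expect_identical(unname(d0[c("dc", "da", "do")]), c(0, 0, 0))
  expect_equal(unname(d0["dr"]), p[["p5"]], tolerance = 1e-14)

  # DEX strictly lowers ACTH production, all else equal
  s <- hpa_state(cs = 0.7, c = 20, a = 1, r = 0.4, o = 1)
  s_dex <- hpa_state(cs = 0.7, c = 20, a = 1, r = 0.4, o = 1, o_exo = 0.5)
  expect_lt(system_rhs(s_dex, 1, 0, 1, p)["da"],
            system_rhs(s, 1, 0, 1, p)["da"])
  # ...but never enters the stored-CRH synthesis equation
  expect_identical(system_rhs(s_dex, 1, 0, 1, p)["dcs"],
                   system_rhs(s, 1, 0, 1, p)["dcs"])
})

test_that("system_rhs with zero exogenous drugs equals the base five-variable model", {
  p <- ref_params()
  for (i in 1:20) {
    set.seed(i)
    v <- stats::runif(5, 0, c(2, 40, 3, 1, 3))
    s7 <- hpa_state(cs = v[1], c = v[2], a = v[3], r = v[4], o = v[5])
    d <- system_rhs(s7, a_delayed = 0.8, a_exo_delayed = 0, I_now = 1, p)
    or <- v[5] * v[4]
    expect_identical(unname(d["da"]),
                     v[2] * (1 / (1 + p[["p2"]] * or)) - p[["p3"]] * v[3])
    expect_identical(unname(d["dr"]),
                     or^2 / (p[["p4"]] + or^2) + p[["p5"]] - p[["p6"]] * v[4])
    expect_identical(unname(d["do"]), 0.8 - v[5])
  }
})

test_that("exogenous pharmacokinetics follow the linear closed form", {
  # constant-rate infusion from zero: x(t) = (A/k)(1 - exp(-k t))
  expect_equal(pharmacokinetics_rhs(0, 2, 0.03), 2)
  expect_equal(pharmacokinetics_rhs(5, 0, 0.03), -0.15, tolerance = 1e-14)
  p <- hpa_params(q0 = 1e-9)   # decouple the endogenous loop
  w <- minutes_to_dimensionless(30)
  tr <- hpa_integrate(p, hpa_state(), c(0, 20),
                      pulses = dose_pulse("dex", 1, w, 2))
  sol <- trajectory_solution(tr)
  A <- 2; k <- p[["p7"]]
  expected <- ifelse(sol$time < 1, 0,
              ifelse(sol$time <= 1 + w,
                     (A / k) * (1 - exp(-k * (sol$time - 1))),
                     (A / k) * (1 - exp(-k * w)) * exp(-k * (sol$time - 1 - w))))
  expect_lt(max(abs(sol$o_exo - expected)), 1e-8)
})

test_that("half-life ratios and time conversions reproduce the derived constants", {
  expect_equal(rate_ratio_from_halflives(7.2, 240), 0.03, tolerance = 1e-15)
  for (h in c(0.5, 7.2, 100)) expect_identical(rate_ratio_from_halflives(h, h), 1)
  expect_equal(rate_ratio_from_halflives(7.2, 4.1), 1.756098, tolerance = 1e-6)
  expect_lt(abs(minutes_to_dimensionless(15) - 1.44), 0.005)
  expect_identical(minutes_to_dimensionless(0), 0)
  expect_equal(minutes_to_dimensionless(30), 2.888113, tolerance = 1e-6)
  expect_equal(dimensionless_to_minutes(minutes_to_dimensionless(77)), 77,
               tolerance = 1e-12)
  expect_error(rate_ratio_from_halflives(-1, 10), "positive")
})

test_that("parameter sets are validated", {
  expect_error(hpa_params(q2 = -1), "strictly positive")
  expect_error(hpa_params(n = 0.5), ">= 1")
  expect_error(hpa_params(t_d = -0.1), ">= 0")
  expect_error(hpa_params(zz = 2), "unknown parameter")
  expect_silent(hpa_params(c_inf_bar = 0))
  p <- update_params(ref_params(), q0 = 33.6)
  expect_identical(p[["q0"]], 33.6)
  expect_identical(p[["q1"]], 0.04)
})

test_that("states and inputs enforce nonnegativity", {
  expect_error(hpa_state(o = -1), "nonnegative")
  expect_error(dose_pulse("dex", 0, -1, 2), "positive")
  expect_error(input_signal(-1), "nonnegative")
  sig <- input_signal(1, data.frame(start = 2, duration = 3, amplitude = 0.5))
  expect_identical(input_value(sig, c(1.9, 2, 4.9, 5, 6)),
                   c(1, 1.5, 1.5, 1, 1))
})
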