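test_that("percentage suppression is the scale-free statistic it claims to be", {
  expect_identical(percentage_suppression(1, 1), 0)
  expect_identical(percentage_suppression(2.5, 0), 100)
  expect_equal(percentage_suppression(1.0, 0.26), 74, tolerance = 1e-12)
  for (lam in c(0.1, 3, 1e4))
    expect_equal(percentage_suppression(lam * 1.2, lam * 0.3),
                 percentage_suppression(1.2, 0.3), tolerance = 1e-10)
  expect_error(percentage_suppression(0, 0.1), "positive")
  expect_error(percentage_suppression(1, -0.1), "nonnegative")
})

test_that("suppression is stronger from the diseased basin under identical parameters", {
  rn <- ref_dex("normal")
  rd <- ref_dex("diseased")
  expect_gt(rd$s, rn$s)
  expect_gt(rd$delta_fa, rn$delta_fa)
  # the diseased state starts from a *smaller* feedback-complex level
  expect_lt(rd$pre_mean_or, rn$pre_mean_or)
})

test_that("cortisol oscillations cease under dexamethasone suppression", {
  for (basin in c("normal", "diseased")) {
    r <- ref_dex(basin)
    expect_gt(r$pre_amplitude, 0.1)
    expect_lt(r$post_amplitude, 0.01 * r$pre_amplitude)
  }
})

test_that("dexamethasone suppresses, never stimulates, the endogenous axis", {
  p <- ref_params()
  fps <- ref_fixed_points()
  r <- ref_dex("normal")
  # undosed continuation from the same equilibrated history
  i <- which(fps$regime %in% "normal")
  cyc <- attr(fps, "cycles")[[i]]
  eq <- hpaxis:::equilibrate_attractor(p, fps[i, ], cyc, 150, 0.01)
  undosed <- hpa_integrate(p, trajectory_history(eq$trajectory, lookback = 3),
                           c(eq$t_eq, r$t_measure + 1))
  at <- seq(r$t_dose + 5, r$t_measure, by = 2)
  dosed_o <- trajectory_at(r$trajectory, at)$o
  free_o <- trajectory_at(undosed, at)$o
  expect_true(all(dosed_o <= free_o + 1e-8))
  dosed_a <- trajectory_at(r$trajectory, at)$a
  free_a <- trajectory_at(undosed, at)$a
  expect_true(all(dosed_a <= free_a + 1e-8))
})

test_that("the feedback drop is larger from a smaller initial complex level", {
  # convexity mechanism: equal increments of cortisol at equal receptor
  # availability bite harder when the starting complex level is low
  p2 <- 15
  for (r in c(0.2, 0.4, 0.6)) for (d_o in c(0.5, 1, 2)) {
    o_grid <- seq(0.1, 2, by = 0.1)
    drop <- pituitary_feedback(o_grid * r, p2) -
      pituitary_feedback((o_grid + d_o) * r, p2)
    expect_true(all(diff(drop) < 0))
  }
})

test_that("peak-phase pre-measurement raises the measured suppression", {
  for (basin in c("normal", "diseased")) {
    expect_gt(ref_dex(basin, "instantaneous")$s, ref_dex(basin)$s)
  }
})

test_that("DST runs are deterministic", {
  a <- run_dex_test(ref_params(), "normal", fixed_points = ref_fixed_points())
  b <- run_dex_test(ref_params(), "normal", fixed_points = ref_fixed_points())
  expect_identical(a$s, b$s)
  expect_identical(a$pre_o, b$pre_o)
})

test_that("a diseased basin cannot be requested from a monostable set", {
  p <- hpa_params(n = 4)
  fps <- cached("fps_n4", find_fixed_points(p))
  expect_error(run_dex_test(p, "diseased", fixed_points = fps),
               "not bistable")
})

test_that("reduced adrenal reactivity rescales the couplings exactly", {
  p <- ref_params()
  sp <- adrenal_reactivity_params(p, 0.9)
  expect_equal(sp[["p2"]], 0.9 * 15)
  expect_equal(sp[["p4"]], 0.05 / 0.81)
  expect_identical(adrenal_reactivity_params(p, 1), p)
  expect_error(adrenal_reactivity_params(p, 0), "positive")
  expect_error(adrenal_reactivity_params(p, 1.1), "at most 1")
})

test_that("hyporeactivity raises basal cortisol in the subject's own units", {
  s1 <- ref_acth_sweep(1)
  s9 <- ref_acth_sweep(0.9)
  expect_gt(s9$summary$baseline_mean_o_model, s1$summary$baseline_mean_o_model)
  # while the stimulated response on the common hormonal scale is damped
  expect_lt(s9$summary$peak_mean, s1$summary$peak_mean)
})

test_that("the per-phase peak response is periodic and nadir-sensitive", {
  bl <- cached("acth_bl_1", acth_baseline(ref_params(), 1))
  r0 <- run_acth_test(ref_params(), baseline = bl, phase_at_dose = 0)
  r2 <- run_acth_test(ref_params(), baseline = bl,
                      phase_at_dose = 2 * pi - 1e-9)
  expect_equal(r0$peak_o, r2$peak_o, tolerance = 1e-6)
  s1 <- ref_acth_sweep(1)
  # the best response comes from dosing in the half-cycle around the nadir,
  # never at the cortisol peak itself
  ph_best <- s1$phases[which.max(s1$peaks)]
  expect_gt(ph_best, pi / 2)
  expect_lt(ph_best, 3 * pi / 2)
  expect_gt(max(s1$peaks), s1$peaks[1])
})

test_that("a zero-height pulse reproduces the undosed cycle maximum", {
  bl <- cached("acth_bl_1", acth_baseline(ref_params(), 1))
  r <- run_acth_test(ref_params(), baseline = bl, phase_at_dose = 1,
                     protocol = acth_protocol(dose_height = 0))
  expect_lte(r$peak_o, r$baseline_max_o * (1 + 1e-3))
  expect_gt(r$peak_o, r$baseline_max_o * 0.95)
})

test_that("the two-stage stressor exposes the diseased basin", {
  ts <- cached("two_stage_ref",
               run_two_stage_test(ref_params(),
                                  fixed_points = ref_fixed_points()))
  s <- ts$summary
  expect_gt(s$peak_o[s$basin == "diseased"], s$peak_o[s$basin == "normal"])
  expect_gt(s$response[s$basin == "diseased"],
            s$response[s$basin == "normal"])
  # the diseased subject starts the stressor *more* suppressed
  expect_lt(s$pre_stressor_o[s$basin == "diseased"],
            s$pre_stressor_o[s$basin == "normal"])
})

test_that("a null stressor reduces the two-stage test to a plain DST run", {
  ts0 <- run_two_stage_test(ref_params(), stressor_amplitude = 0,
                            basins = "normal",
                            fixed_points = ref_fixed_points())
  r <- ref_dex("normal")
  t_on <- ts0$runs$normal$t_stress_on
  at <- seq(t_on - 5, t_on + 1, by = 0.5)  # the DST run ends 1 unit post-measure
  expect_equal(trajectory_at(ts0$runs$normal$trajectory, at)$o,
               trajectory_at(r$trajectory, at)$o, tolerance = 1e-9)
})

test_that("sufficient stress drives a diseased-to-normal transition, monotonically in amplitude", {
  p <- ref_params()
  fps <- ref_fixed_points()
  null_run <- stress_transition(p, "diseased", fixed_points = fps)
  expect_identical(null_run$final_basin, "diseased")
  make_input <- function(a) input_signal(1, data.frame(start = 5, duration = 40,
                                                       amplitude = a))
  amps <- c(0.05, 0.2, 0.5)
  out <- vapply(amps, function(a)
    stress_transition(p, "diseased", make_input(a),
                      fixed_points = fps)$final_basin, character(1))
  expect_identical(out[length(out)], "normal")
  # once an amplitude escapes the diseased basin, every larger one does too
  esc <- out == "normal"
  expect_true(all(diff(as.integer(esc)) >= 0))
})
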