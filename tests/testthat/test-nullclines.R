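test_that("the c-nullcline passes through the origin and satisfies its relation", {
  p <- ref_params()
  nc <- cached("cnull_ref", c_nullcline(p))
  expect_identical(nc$cs[nc$c == 0], 0)
  expect_lt(max(abs(nullcline_residual(nc))), 1e-8)
})

test_that("the closed form agrees with a bisection root-finder on the release relation", {
  set.seed(7)
  for (i in 1:12) {
    p <- hpa_params(q0 = stats::runif(1, 20, 36), q1 = stats::runif(1, 0.03, 0.05),
                    q2 = stats::runif(1, 1.4, 2.2), gc_max = stats::runif(1, 30, 50),
                    n = sample(4:6, 1), k = stats::runif(1, 2.2, 3.4))
    cv <- stats::runif(1, 1, 12)
    cs_closed <- c_nullcline_cs(cv, p)
    if (is.na(cs_closed)) next
    g <- function(cs) p[["q0"]] * p[["I0"]] * (1 - exp(-p[["k"]] * cs)) +
      autocrine_upregulation(cv, p) - p[["q2"]] * cv
    lo <- 0; hi <- 50
    for (j in 1:200) {
      mid <- (lo + hi) / 2
      if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
    }
    expect_lt(abs(cs_closed - (lo + hi) / 2), 1e-10)
  }
})

test_that("the fold appears between Hill coefficients 4 and 5", {
  p <- ref_params()
  folded <- vapply(1:8, function(nn) {
    nrow(attr(c_nullcline(hpa_params(n = nn)), "knees")) >= 2
  }, logical(1))
  expect_identical(min(which(folded)), 5L)
  expect_false(any(folded[1:4]))
  expect_true(all(folded[5:8]))
})

test_that("the cs-nullcline is built from cycle averages and flags oscillatory samples", {
  p <- ref_params()
  curve <- cached("csnull_ref", cs_nullcline(p))
  expect_lt(max(abs(nullcline_residual(curve))), 1e-12)
  expect_true(any(curve$oscillatory))
  expect_true(any(!curve$oscillatory))
  # stronger synthesis suppression moves the whole curve to smaller cs
  shifted <- averaged_crh_target(20, update_params(p, b = 0.72))
  expect_lt(shifted, averaged_crh_target(20, p))
  # stronger pituitary feedback moves it to larger cs at fixed c
  expect_gt(averaged_crh_target(20, update_params(p, p2 = 18)),
            averaged_crh_target(20, p))
})

test_that("the reference set is bistable with a correctly labelled pair of states", {
  fps <- ref_fixed_points()
  expect_identical(nrow(fps), 3L)
  expect_identical(sum(fps$stability == "stable"), 2L)
  expect_identical(fps$stability[order(fps$c)][2], "unstable")
  nrm <- fps[fps$regime %in% "normal", ]
  dis <- fps[fps$regime %in% "diseased", ]
  expect_gt(nrm$mean_o, dis$mean_o)
  expect_gt(nrm$c, dis$c)
  expect_lt(max(abs(fps$residual_c)), 1e-8)
  expect_lt(max(abs(fps$residual_cs)), 1e-8)
})

test_that("a monotone c-nullcline yields a single stable intersection", {
  p <- hpa_params(n = 4)
  fps <- cached("fps_n4", find_fixed_points(p))
  expect_identical(nrow(fps), 1L)
  expect_identical(fps$stability, "stable")
  expect_identical(fps$regime, "normal")
})

test_that("raising the basal CRH drive moves every intersection up", {
  fps <- ref_fixed_points()
  # a small increase keeps all three crossings and lifts each one toward
  # larger CRH and cortisol (the low state's basin shrinks rapidly, so the
  # comparison is made on the intersections themselves)
  fps_hi <- cached("fps_q0_hi",
                   find_fixed_points(update_params(ref_params(),
                                                   q0 = 1.02 * 28),
                                     classify = FALSE))
  expect_identical(nrow(fps_hi), 3L)
  # both observable (outer) states move to larger c and larger cortisol;
  # the middle saddle slides toward the approaching lower state
  expect_gt(min(fps_hi$c), min(fps$c))
  expect_gt(max(fps_hi$c), max(fps$c))
  expect_gt(min(fps_hi$mean_o), min(fps$mean_o))
  expect_gt(max(fps_hi$mean_o), max(fps$mean_o))
  # a +20% drive pushes the fold past the averaged nullcline: only the
  # high-cortisol state survives, at yet larger CRH and cortisol
  i_n <- which(fps$regime %in% "normal")
  fps_20 <- cached("fps_q0_20",
                   find_fixed_points(update_params(ref_params(),
                                                   q0 = 1.2 * 28),
                                     classify = FALSE))
  expect_identical(nrow(fps_20), 1L)
  expect_gt(fps_20$c, fps$c[i_n])
  expect_gt(fps_20$mean_o, fps$mean_o[i_n])
})

test_that("only the product of drive and input enters the c-nullcline", {
  p <- ref_params()
  lam <- 1.7
  p2 <- update_params(p, q0 = lam * p[["q0"]], I0 = p[["I0"]] / lam)
  cg <- seq(0, 40, by = 0.5)
  expect_equal(c_nullcline_cs(cg, p), c_nullcline_cs(cg, p2),
               tolerance = 1e-12)
})

test_that("sweeps validate their target and summarize knees", {
  p <- ref_params()
  expect_error(nullcline_sweep(p, "bogus", 1), "unknown parameter")
  sw <- nullcline_sweep(p, "q0", c(28, 33.6), "c")
  expect_identical(length(sw$curves), 2L)
  expect_true(all(sw$summary$folded))
  # both knees sit at smaller stored-CRH for the stronger drive
  expect_lt(sw$summary$knee_lower_cs[2], sw$summary$knee_lower_cs[1])
  expect_lt(sw$summary$knee_upper_cs[2], sw$summary$knee_upper_cs[1])
})

test_that("curves and fixed points export to delimited text and JSON", {
  nc <- cached("cnull_ref", c_nullcline(ref_params()))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  write_nullcline_csv(nc, f1)
  back <- utils::read.csv(f1)
  expect_identical(nrow(back), nrow(nc))
  write_fixed_points_json(ref_fixed_points(), f2)
  js <- jsonlite::fromJSON(f2)
  expect_identical(nrow(js$fixed_points), 3L)
  unlink(c(f1, f2))
})
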