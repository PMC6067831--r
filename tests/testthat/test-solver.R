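test_that("decoupled subsystems relax to their analytic equilibria", {
  # with negligible CRH drive the c/a/o chain stays at zero while cs and r
  # relax to the roots of their own linear equations
  p <- hpa_params(q0 = 1e-12, gc_max = 1e-12, t_c = 5)
  tr <- hpa_integrate(p, hpa_state(), c(0, 80))
  fin <- trajectory_solution(tr)
  fin <- fin[nrow(fin), ]
  expect_equal(fin$cs, p[["c_inf_bar"]] + 1, tolerance = 1e-6)
  expect_lt(fin$c, 1e-9)
  expect_lt(fin$a, 1e-9)
  expect_lt(fin$o, 1e-9)
  expect_equal(fin$r, p[["p5"]] / p[["p6"]], tolerance = 1e-6)
})

test_that("halving the step barely moves a long reference run", {
  p <- ref_params()
  run <- function(h) {
    tr <- hpa_integrate(p, seed_state(), c(0, 100), step = h)
    unlist(trajectory_solution(tr)[nrow(trajectory_solution(tr)),
                                   c("cs", "c", "a", "r", "o")])
  }
  y1 <- run(0.01); y2 <- run(0.005)
  expect_lt(sqrt(sum((y1 - y2)^2)) / sqrt(sum(y2^2)), 1e-6)
})

test_that("the scheme converges at fourth order on a smooth segment", {
  p <- ref_params()
  term <- function(h) {
    tr <- hpa_integrate(p, seed_state(), c(0, 10), step = h)
    sol <- trajectory_solution(tr)
    unlist(sol[nrow(sol), c("cs", "c", "a", "r", "o")])
  }
  ref <- term(0.0025)
  e1 <- sqrt(sum((term(0.02) - ref)^2))
  e2 <- sqrt(sum((term(0.01) - ref)^2))
  # error ratio for a step halving should be ~2^4; allow a generous band
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 32)
})

test_that("splitting a run and continuing from its history reproduces it", {
  p <- ref_params()
  whole <- hpa_integrate(p, seed_state(), c(0, 40))
  first <- hpa_integrate(p, seed_state(), c(0, 17.3))
  second <- hpa_integrate(p, trajectory_history(first, lookback = 3),
                          c(17.3, 40))
  at <- seq(20, 40, by = 0.5)
  a <- trajectory_at(whole, at)
  b <- trajectory_at(second, at)
  expect_lt(max(abs(as.matrix(a[-1]) - as.matrix(b[-1]))), 1e-8)
})

test_that("trajectories from nonnegative histories stay nonnegative", {
  p <- ref_params()
  set.seed(42)
  for (i in 1:6) {
    s <- hpa_state(cs = stats::runif(1, 0, 2), c = stats::runif(1, 0, 40),
                   a = stats::runif(1, 0, 4), r = stats::runif(1, 0, 1),
                   o = stats::runif(1, 0, 4))
    tr <- hpa_integrate(p, s, c(0, 60))
    expect_gte(min(as.matrix(trajectory_solution(tr)[, c("cs", "c", "a",
                                                         "r", "o", "o_exo",
                                                         "a_exo")])), 0)
  }
})

test_that("the integrator agrees with an independent adaptive DDE solver", {
  skip_if_not_installed("deSolve")
  p <- ref_params()
  s0 <- unclass(seed_state())[1:5]
  derhs <- function(t, y, parms) {
    alag <- if (t < p[["t_d"]]) s0[["a"]] else deSolve::lagvalue(t - p[["t_d"]], 3)
    or <- y[5] * y[4]
    list(c((p[["c_inf_bar"]] + exp(-p[["b"]] * y[5]) - y[1]) / p[["t_c"]],
           p[["q0"]] * (1 - exp(-p[["k"]] * y[1])) +
             p[["gc_max"]] * (p[["q1"]] * y[2])^p[["n"]] /
             (1 + (p[["q1"]] * y[2])^p[["n"]]) - p[["q2"]] * y[2],
           y[2] / (1 + p[["p2"]] * or) - p[["p3"]] * y[3],
           or^2 / (p[["p4"]] + or^2) + p[["p5"]] - p[["p6"]] * y[4],
           alag - y[5]))
  }
  times <- seq(0, 20, by = 0.1)
  ref <- deSolve::dede(y = unname(s0), times = times, func = derhs,
                       parms = NULL, atol = 1e-10, rtol = 1e-10)
  mine <- trajectory_at(hpa_integrate(p, seed_state(), c(0, 20)), times)
  expect_lt(max(abs(as.matrix(mine[, c("cs", "c", "a", "r", "o")]) -
                      ref[, 2:6])), 1e-4)
})

test_that("configuration errors are caught before integration", {
  p <- ref_params()
  expect_error(hpa_integrate(p, seed_state(), c(0, 10), step = 2),
               "must not exceed the delay")
  expect_error(hpa_integrate(p, seed_state(), c(10, 10)), "positive length")
  h <- constant_history(seed_state(), t0 = 0, lookback = 5)
  h$states[1, 3] <- -1
  expect_error(hpa_integrate(p, h, c(0, 10)), "nonnegative")
})

test_that("constant history evaluates to its state and rejects negatives", {
  s <- seed_state()
  h <- constant_history(s, t0 = 0, lookback = 5)
  v <- history_value(h, c(-5, -2.5, 0))
  for (i in 1:3) expect_identical(unname(v[i, ]), unname(unclass(s)))
  expect_error(constant_history(c(cs = -1, o = 0)), "nonnegative")
})

test_that("trajectory CSV round-trips at stated precision", {
  p <- ref_params()
  tr <- hpa_integrate(p, seed_state(), c(0, 5))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  expect_true(startsWith(readLines(path, n = 1), "#"))
  back <- read_trajectory(path)
  sol <- trajectory_solution(tr)
  expect_equal(back$o, sol$o, tolerance = 1e-6)
  expect_identical(names(back), names(sol))
  unlink(path)
})
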