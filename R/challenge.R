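#' Percentage suppression of cortisol
#'
#' The dexamethasone suppression test statistic:
#' `s = 100 (pre - post) / pre`, scale-free in the cortisol units.
#'
#' @param pre_o pre-dose cortisol (> 0).
#' @param post_o post-dose cortisol (>= 0).
#' @return Percentage suppression (at most 100; negative if cortisol rose).
#' @examples
#' percentage_suppression(1.0, 0.26)
#' @export
percentage_suppression <- function(pre_o, post_o) {
  if (any(pre_o <= 0)) stop("pre-dose cortisol must be strictly positive")
  if (any(post_o < 0)) stop("post-dose cortisol must be nonnegative")
  100 * (pre_o - post_o) / pre_o
}

#' Protocol descriptions for the challenge tests
#'
#' `dst_protocol()` encodes the dexamethasone suppression test: a rectangle
#' dose (default width 30 min, height 2 in nondimensional cortisol units)
#' administered at night, with post-dose cortisol measured 9 h later (the
#' 11 p.m. dose / 8 a.m. measurement convention); clock times are converted
#' via [minutes_to_dimensionless()]. Pre-dose cortisol is measured either as
#' the average over one full ultradian cycle (`"period_averaged"`) or
#' instantaneously at the cycle peak (`"instantaneous"`).
#'
#' `acth_protocol()` encodes cosyntropin stimulation: a rectangle dose of the
#' same width; the clinical dose does not fix the height in nondimensional
#' units, so the default (14) is a package calibration placing a normal
#' subject's peak response at the stimulation test's characteristic response
#' scale (peak cortisol near 8, a several-fold transient over the basal
#' cycle). Responses are interpreted relationally (orderings, phase
#' dependence) rather than absolutely.
#'
#' @param dose_height rectangle infusion rate.
#' @param dose_width rectangle duration (dimensionless).
#' @param post_delay time from dose onset to the post measurement.
#' @param measurement_mode `"period_averaged"` or `"instantaneous"` (at the
#'   cortisol cycle peak).
#' @param equilibration settling time on the chosen attractor before the
#'   protocol starts.
#' @param response_window window after dose onset searched for the peak
#'   response (`NULL`: dose width + 3).
#' @param step integrator step size.
#' @return A named list of protocol settings.
#' @export
dst_protocol <- function(dose_height = 2,
                         dose_width = minutes_to_dimensionless(30),
                         post_delay = minutes_to_dimensionless(540),
                         measurement_mode = c("period_averaged",
                                              "instantaneous"),
                         equilibration = 150,
                         step = 0.01) {
  measurement_mode <- match.arg(measurement_mode)
  if (dose_width <= 0 || dose_height < 0) stop("invalid dose rectangle")
  if (post_delay <= 0) stop("post_delay must be positive")
  list(dose_height = dose_height, dose_width = dose_width,
       post_delay = post_delay, measurement_mode = measurement_mode,
       equilibration = equilibration, step = step)
}

#' @rdname dst_protocol
#' @export
acth_protocol <- function(dose_height = 14,
                          dose_width = minutes_to_dimensionless(30),
                          response_window = NULL,
                          equilibration = 150,
                          step = 0.01) {
  if (dose_width <= 0 || dose_height < 0) stop("invalid dose rectangle")
  if (is.null(response_window)) response_window <- dose_width + 3
  list(dose_height = dose_height, dose_width = dose_width,
       response_window = response_window, equilibration = equilibration,
       step = step)
}

## --- internal machinery -----------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoid statistics of a solution column over a time window; the
# oscillation amplitude is measured on the linearly detrended signal so a
# slow monotone drift (e.g. decaying drug levels) does not read as a cycle
window_stats <- function(sol, t1, t2) {
  i <- sol$time >= t1 - 1e-9 & sol$time <= t2 + 1e-9
  if (sum(i) < 2) stop("measurement window outside simulated span")
  tt <- sol$time[i]
  trap <- function(x) sum(diff(tt) * (x[-1] + x[-length(x)]) / 2) /
    (tt[length(tt)] - tt[1])
  o <- sol$o[i]
  resid <- stats::lm.fit(cbind(1, tt - tt[1]), o)$residuals
  list(mean_o = trap(o), max_o = max(o), min_o = min(o),
       amplitude_o = max(resid) - min(resid),
       mean_or = trap(o * sol$r[i]),
       mean_c = trap(sol$c[i]), mean_cs = trap(sol$cs[i]))
}

# settle the full system on the attractor of one stable fixed point and
# measure its ultradian cycle (period, time of the last cortisol peak)
equilibrate_attractor <- function(params, fp_row, cycle, equilibration,
                                  step = 0.01) {
  s0 <- cycle$state
  init <- hpa_state(cs = fp_row$cs, c = fp_row$c,
                    a = s0[["a"]], r = s0[["r"]], o = s0[["o"]])
  tr <- hpa_integrate(params, init, c(0, equilibration), step = step)
  sol <- trajectory_solution(tr)
  win <- sol[sol$time >= equilibration - 40, ]
  m <- mean(win$o)
  amp <- max(win$o) - min(win$o)
  if (amp / max(m, .Machine$double.eps) < 1e-6) {
    return(list(trajectory = tr, t_eq = equilibration, period = NA_real_,
                t_peak = equilibration, oscillatory = FALSE))
  }
  cross <- upward_crossings(win$time, win$o, m)
  if (length(cross) < 3)
    stop("attractor did not settle onto a resolvable cycle during equilibration")
  period <- mean(diff(utils::tail(cross, 6)))
  # cortisol peak inside the last full cycle
  last <- win[win$time >= cross[length(cross)] - period, ]
  t_peak <- last$time[which.max(last$o)]
  list(trajectory = tr, t_eq = equilibration, period = period,
       t_peak = t_peak, oscillatory = TRUE)
}

# first time >= t_min that realizes phase `phase` (theta = 0 at the cortisol
# peak) of a cycle with the given period and a known peak time
phase_time_after <- function(t_peak, period, phase, t_min) {
  t0 <- t_peak + phase / (2 * pi) * period
  t0 + period * ceiling((t_min - t0) / period)
}

pick_basin <- function(fixed_points, basin) {
  stable <- fixed_points[fixed_points$stability %in% "stable", , drop = FALSE]
  if (basin == "diseased" && sum(!is.na(fixed_points$regime)) < 2)
    stop("parameter set is not bistable: no diseased basin exists")
  i <- which(fixed_points$regime %in% basin)
  if (!length(i))
    stop("no stable fixed point labelled '", basin, "' (",
         nrow(stable), " stable point(s) found)")
  i
}

## --- DEX suppression test ---------------------------------------------------

#' Simulate a dexamethasone suppression test
#'
#' Equilibrates the full system on the attractor of the chosen basin
#' (`"normal"`: high mean cortisol; `"diseased"`: low), administers the
#' rectangle dexamethasone dose at the cortisol cycle peak, integrates the
#' extended system (dexamethasone enters the pituitary feedback and receptor
#' equations only) for 9 h, and measures percentage suppression. The pre-dose
#' level is the cycle average or the cycle peak depending on the protocol's
#' `measurement_mode`. The drop in the pituitary feedback factor
#' `fa(or)` from its pre-dose period-averaged value to its post-dose value is
#' reported as `delta_fa`, and the residual post-dose cortisol oscillation
#' amplitude as `post_amplitude`.
#'
#' @param params an [hpa_params()] object; must yield a bistable nullcline
#'   structure.
#' @param basin `"normal"` or `"diseased"` — which stable state the subject
#'   starts in (normal and diseased subjects share all parameters).
#' @param protocol a [dst_protocol()].
#' @param fixed_points optionally precomputed [find_fixed_points()] for
#'   `params` (recomputed otherwise).
#' @return An object of class `hpa_dex_result`: list with `s` (percentage
#'   suppression), `pre_o`, `post_o`, `delta_fa`, `fa_pre`, `fa_post`,
#'   `pre_amplitude`, `post_amplitude`, `period`, `t_dose`, `t_measure`,
#'   `basin`, `measurement_mode` and the post-dose `trajectory`.
#' @examples
#' \donttest{
#' fps <- find_fixed_points(hpa_params())
#' run_dex_test(hpa_params(), "normal", fixed_points = fps)
#' }
#' @export
run_dex_test <- function(params, basin = c("normal", "diseased"),
                         protocol = dst_protocol(), fixed_points = NULL) {
  stopifnot(inherits(params, "hpa_params"))
  basin <- match.arg(basin)
  fps <- fixed_points %||% find_fixed_points(params)
  i <- pick_basin(fps, basin)
  cyc <- attr(fps, "cycles")[[i]]
  eq <- equilibrate_attractor(params, fps[i, ], cyc, protocol$equilibration,
                              protocol$step)
  if (!eq$oscillatory)
    stop("chosen attractor is not oscillatory; DST phase conventions need an ultradian cycle")

  T <- eq$period
  t_dose <- phase_time_after(eq$t_peak, T, 0, eq$t_eq + T + 1)
  t_meas <- t_dose + protocol$post_delay
  pulse <- dose_pulse("dex", start = t_dose, width = protocol$dose_width,
                      height = protocol$dose_height)
  tr <- hpa_integrate(params,
                      trajectory_history(eq$trajectory,
                                         lookback = max(params[["t_d"]], 1) + 1),
                      c(eq$t_eq, t_meas + 1), pulses = list(pulse),
                      step = protocol$step)
  sol <- trajectory_solution(tr)

  pre <- window_stats(sol, t_dose - T, t_dose)
  post_win <- window_stats(sol, t_meas - T, t_meas)
  at_meas <- trajectory_at(tr, t_meas)

  pre_o <- switch(protocol$measurement_mode,
                  period_averaged = pre$mean_o,
                  instantaneous = pre$max_o)
  post_o <- switch(protocol$measurement_mode,
                   period_averaged = post_win$mean_o,
                   instantaneous = at_meas$o)

  fa_pre <- pituitary_feedback(pre$mean_or, params[["p2"]])
  fa_post <- pituitary_feedback((at_meas$o + at_meas$o_exo) * at_meas$r,
                                params[["p2"]])

  structure(list(
    s = percentage_suppression(pre_o, post_o),
    pre_o = pre_o, post_o = post_o,
    fa_pre = fa_pre, fa_post = fa_post, delta_fa = fa_pre - fa_post,
    pre_amplitude = pre$amplitude_o, post_amplitude = post_win$amplitude_o,
    pre_mean_or = pre$mean_or,
    period = T, t_dose = t_dose, t_measure = t_meas,
    basin = basin, measurement_mode = protocol$measurement_mode,
    trajectory = tr), class = "hpa_dex_result")
}

#' @export
print.hpa_dex_result <- function(x, ...) {
  cat(sprintf(paste0("<hpa_dex_result> basin=%s (%s): s = %.2f%% ",
                     "(pre %.4f -> post %.4f), delta_fa = %.4f, ",
                     "post/pre amplitude = %.2g\n"),
              x$basin, x$measurement_mode, x$s, x$pre_o, x$post_o,
              x$delta_fa, x$post_amplitude / max(x$pre_amplitude, 1e-300)))
  invisible(x)
}

## --- ACTH (cosyntropin) stimulation test ------------------------------------

#' Map an adrenal-reactivity scale onto the parameter set
#'
#' A reactivity factor `lambda` in (0, 1] scales the adrenal
#' cortisol-secretion gain: a hyporeactive gland releases `lambda` times as
#' much cortisol per unit ACTH. Because the model measures cortisol in units
#' of the subject's own secretion gain, this propagates exactly into the two
#' couplings that compare against the cortisol-receptor complex:
#' `p2 -> lambda * p2` and `p4 -> p4 / lambda^2` (equivalently, the delayed
#' adrenal drive in fixed units is multiplied by `lambda`). Model-unit
#' cortisol from such a run is multiplied by `lambda` to express it on the
#' common scale shared with a normal subject.
#'
#' Two opposing effects follow. In the subject's own model units basal
#' cortisol *rises* under hyporeactivity — the delayed feedback loop
#' partially compensates the weaker gland — while on the common hormonal
#' scale the stimulated response to an ACTH bolus is damped by the reduced
#' gain. Both signatures matter when interpreting stimulation tests.
#'
#' @param params an [hpa_params()] object.
#' @param reactivity scale factor in (0, 1].
#' @return The rescaled `hpa_params` (the hyporeactive subject's own-unit
#'   parameter set).
#' @export
adrenal_reactivity_params <- function(params, reactivity) {
  stopifnot(inherits(params, "hpa_params"))
  if (reactivity <= 0) stop("reactivity must be positive")
  if (reactivity > 1) stop("reactivity must be at most 1")
  update_params(params, p2 = reactivity * params[["p2"]],
                p4 = params[["p4"]] / reactivity^2)
}

#' Basal state for an ACTH stimulation run
#'
#' Precomputes everything a phase sweep reuses: the reactivity-scaled
#' parameters, their fixed points, and the equilibrated basal attractor with
#' its cycle timing.
#'
#' @param params an [hpa_params()] object (unscaled).
#' @param adrenal_reactivity reactivity scale in (0, 1]; 1 = normal.
#' @param basin which stable state to equilibrate on.
#' @param protocol an [acth_protocol()].
#' @param fixed_points optionally, precomputed fixed points of the *scaled*
#'   parameter set.
#' @return A list used as the `baseline` argument of [run_acth_test()].
#' @export
acth_baseline <- function(params, adrenal_reactivity = 1,
                          basin = "normal", protocol = acth_protocol(),
                          fixed_points = NULL) {
  sp <- adrenal_reactivity_params(params, adrenal_reactivity)
  fps <- fixed_points %||% find_fixed_points(sp)
  i <- pick_basin(fps, basin)
  cyc <- attr(fps, "cycles")[[i]]
  eq <- equilibrate_attractor(sp, fps[i, ], cyc, protocol$equilibration,
                              protocol$step)
  if (!eq$oscillatory)
    stop("basal attractor is not oscillatory; phase-controlled dosing undefined")
  list(params = sp, reactivity = adrenal_reactivity, basin = basin,
       fixed_points = fps, eq = eq)
}

#' Simulate a phase-controlled ACTH (cosyntropin) stimulation test
#'
#' Equilibrates on the basal attractor (optionally with reduced adrenal
#' reactivity, see [adrenal_reactivity_params()]), times a rectangle
#' cosyntropin dose to a requested phase of the cortisol ultradian cycle
#' (`theta = 0` at the cortisol peak), and reports the peak cortisol during
#' the response window together with the pre-dose cycle statistics.
#' Responses are reported on the common hormonal scale (model units times
#' the reactivity factor), with the subject's own model-unit values
#' alongside; see [adrenal_reactivity_params()] for the two unit systems.
#'
#' @param params an [hpa_params()] object (unscaled reference set).
#' @param adrenal_reactivity reactivity in (0, 1].
#' @param phase_at_dose phase in `[0, 2 pi)` at which the dose starts.
#' @param protocol an [acth_protocol()].
#' @param basin which stable state the subject is in (default `"normal"`).
#' @param baseline optional precomputed [acth_baseline()] (overrides
#'   `adrenal_reactivity`/`basin`).
#' @return An object of class `hpa_acth_result`: list with `peak_o`,
#'   `baseline_mean_o`, `baseline_max_o` (common scale), `peak_o_model`,
#'   `baseline_mean_o_model` (model units), `phase_at_dose`, `reactivity`,
#'   `period`, `t_dose`, and the `trajectory`.
#' @export
run_acth_test <- function(params, adrenal_reactivity = 1, phase_at_dose = 0,
                          protocol = acth_protocol(), basin = "normal",
                          baseline = NULL) {
  if (phase_at_dose < 0 || phase_at_dose >= 2 * pi)
    phase_at_dose <- phase_at_dose %% (2 * pi)
  bl <- baseline %||% acth_baseline(params, adrenal_reactivity, basin,
                                    protocol)
  sp <- bl$params
  lam <- bl$reactivity
  eq <- bl$eq
  T <- eq$period
  t_dose <- phase_time_after(eq$t_peak, T, phase_at_dose, eq$t_eq + T + 1)
  t_end <- t_dose + protocol$response_window + 1
  pulse <- dose_pulse("acth", start = t_dose, width = protocol$dose_width,
                      height = protocol$dose_height)
  tr <- hpa_integrate(sp,
                      trajectory_history(eq$trajectory,
                                         lookback = max(sp[["t_d"]], 1) + 1),
                      c(eq$t_eq, t_end), pulses = list(pulse),
                      step = protocol$step)
  sol <- trajectory_solution(tr)
  pre <- window_stats(sol, t_dose - T, t_dose)
  resp <- window_stats(sol, t_dose, t_dose + protocol$response_window)

  structure(list(
    peak_o = lam * resp$max_o,
    baseline_mean_o = lam * pre$mean_o, baseline_max_o = lam * pre$max_o,
    peak_o_model = resp$max_o,
    baseline_mean_o_model = pre$mean_o,
    phase_at_dose = phase_at_dose, reactivity = lam, basin = bl$basin,
    period = T, t_dose = t_dose, trajectory = tr),
    class = "hpa_acth_result")
}

#' @export
print.hpa_acth_result <- function(x, ...) {
  cat(sprintf(paste0("<hpa_acth_result> reactivity=%.2f phase=%.3f: ",
                     "peak o = %.3f (baseline mean %.3f, max %.3f)\n"),
              x$reactivity, x$phase_at_dose, x$peak_o, x$baseline_mean_o,
              x$baseline_max_o))
  invisible(x)
}

#' Sweep the cosyntropin dose over the ultradian phase
#'
#' Runs [run_acth_test()] on an evenly spaced phase grid (one shared
#' equilibration) and summarizes the per-phase peak response.
#'
#' @inheritParams run_acth_test
#' @param n_phases number of phases (>= 8).
#' @return An `hpa_acth_sweep`: list with `results` (per-phase list),
#'   `phases`, `peaks` and `summary` (max/min/mean peak,
#'   baseline mean).
#' @export
phase_sweep_acth <- function(params, adrenal_reactivity = 1, n_phases = 16,
                             protocol = acth_protocol(), basin = "normal",
                             baseline = NULL) {
  if (n_phases < 8) stop("n_phases must be at least 8")
  bl <- baseline %||% acth_baseline(params, adrenal_reactivity, basin,
                                    protocol)
  phases <- seq(0, 2 * pi, length.out = n_phases + 1)[-(n_phases + 1)]
  results <- lapply(phases, function(ph)
    run_acth_test(params, phase_at_dose = ph, protocol = protocol,
                  baseline = bl))
  peaks <- vapply(results, `[[`, numeric(1), "peak_o")
  structure(list(
    results = results, phases = phases, peaks = peaks,
    reactivity = bl$reactivity,
    summary = data.frame(reactivity = bl$reactivity,
                         peak_max = max(peaks), peak_min = min(peaks),
                         peak_mean = mean(peaks),
                         baseline_mean_o = results[[1]]$baseline_mean_o,
                         baseline_mean_o_model = results[[1]]$baseline_mean_o_model)),
    class = "hpa_acth_sweep")
}

#' @export
print.hpa_acth_sweep <- function(x, ...) {
  cat(sprintf("<hpa_acth_sweep> reactivity=%.2f over %d phases\n",
              x$reactivity, length(x$phases)))
  print(x$summary, digits = 4)
  invisible(x)
}

## --- two-stage DEX + stressor test ------------------------------------------

#' Simulate the two-stage dexamethasone-plus-stressor challenge
#'
#' Stage one is a standard dexamethasone suppression run; stage two applies a
#' psychological stressor — a rectangle increase `Iext` of the synaptic input
#' — while the suppression is still in effect (default: amplitude 0.5 for
#' 60 min, starting 9 h after the dose, i.e. at the usual post-DEX
#' measurement time). Both basins are simulated under identical parameters;
#' the summary compares their peak cortisol during the stressor window.
#'
#' @param params an [hpa_params()] object (bistable).
#' @param dex_protocol a [dst_protocol()].
#' @param stressor_amplitude `Iext` amplitude (>= 0).
#' @param stressor_start onset relative to dose onset (dimensionless).
#' @param stressor_duration stressor length (dimensionless).
#' @param basins which basins to run (default both).
#' @param fixed_points optionally precomputed [find_fixed_points()].
#' @return An `hpa_two_stage_result`: list with per-basin entries (each
#'   carrying the trajectory and stressor-window statistics) and a `summary`
#'   data frame with `pre_stressor_o`, `peak_o`, `response` (peak minus
#'   pre-stressor level) per basin.
#' @export
run_two_stage_test <- function(params, dex_protocol = dst_protocol(),
                               stressor_amplitude = 0.5,
                               stressor_start = minutes_to_dimensionless(540),
                               stressor_duration = minutes_to_dimensionless(60),
                               basins = c("normal", "diseased"),
                               fixed_points = NULL) {
  stopifnot(inherits(params, "hpa_params"))
  if (stressor_amplitude < 0) stop("stressor amplitude must be nonnegative")
  if (stressor_duration <= 0) stop("stressor duration must be positive")
  fps <- fixed_points %||% find_fixed_points(params)

  runs <- lapply(basins, function(basin) {
    i <- pick_basin(fps, basin)
    cyc <- attr(fps, "cycles")[[i]]
    eq <- equilibrate_attractor(params, fps[i, ], cyc,
                                dex_protocol$equilibration, dex_protocol$step)
    T <- eq$period
    t_dose <- phase_time_after(eq$t_peak, T, 0, eq$t_eq + T + 1)
    t_on <- t_dose + stressor_start
    t_off <- t_on + stressor_duration
    pulse <- dose_pulse("dex", start = t_dose, width = dex_protocol$dose_width,
                        height = dex_protocol$dose_height)
    input <- input_signal(params[["I0"]],
                          if (stressor_amplitude > 0)
                            data.frame(start = t_on,
                                       duration = stressor_duration,
                                       amplitude = stressor_amplitude)
                          else NULL)
    tr <- hpa_integrate(params,
                        trajectory_history(eq$trajectory,
                                           lookback = max(params[["t_d"]], 1) + 1),
                        c(eq$t_eq, t_off + 5), input = input,
                        pulses = list(pulse), step = dex_protocol$step)
    sol <- trajectory_solution(tr)
    pre_stress <- trajectory_at(tr, t_on)$o
    stress <- window_stats(sol, t_on, t_off)
    list(basin = basin, trajectory = tr, period = T, t_dose = t_dose,
         t_stress_on = t_on, t_stress_off = t_off,
         pre_stressor_o = pre_stress, peak_o = stress$max_o,
         response = stress$max_o - pre_stress)
  })
  names(runs) <- basins
  summary <- data.frame(
    basin = basins,
    pre_stressor_o = vapply(runs, `[[`, numeric(1), "pre_stressor_o"),
    peak_o = vapply(runs, `[[`, numeric(1), "peak_o"),
    response = vapply(runs, `[[`, numeric(1), "response"))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary,
                 stressor_amplitude = stressor_amplitude),
            class = "hpa_two_stage_result")
}

#' @export
print.hpa_two_stage_result <- function(x, ...) {
  cat(sprintf("<hpa_two_stage_result> Iext = %g\n", x$stressor_amplitude))
  print(x$summary, digits = 4)
  invisible(x)
}

## --- stress-induced basin transitions ---------------------------------------

#' Test whether a stressor drives a transition between basins
#'
#' Integrates the full system from the chosen basin under a given input
#' signal, then relaxes it under basal input and reports which stable fixed
#' point the slow variables converge to (nearest attractor in the (cs, c)
#' plane). Captures the model's central mechanism: prolonged stress-induced
#' CRH secretion can move the system from one basin to the other without any
#' parameter change.
#'
#' @param params an [hpa_params()] object (bistable).
#' @param basin starting basin.
#' @param input an [input_signal()] describing the stressor episode.
#' @param horizon total integration time; defaults to the input's end plus
#'   ten stored-CRH relaxation times.
#' @param fixed_points optionally precomputed [find_fixed_points()].
#' @return A list with `final_basin` (`"normal"`, `"diseased"`, or
#'   `"unresolved"` if the slow variables were still moving at the horizon),
#'   `final_cs`, `final_c`, and the `trajectory`.
#' @export
stress_transition <- function(params, basin = c("normal", "diseased"),
                              input = NULL, horizon = NULL,
                              fixed_points = NULL) {
  stopifnot(inherits(params, "hpa_params"))
  basin <- match.arg(basin)
  fps <- fixed_points %||% find_fixed_points(params)
  i <- pick_basin(fps, basin)
  cyc <- attr(fps, "cycles")[[i]]
  if (is.null(input)) input <- input_signal(params[["I0"]])
  t_input_end <- if (nrow(input$steps))
    max(input$steps$start + input$steps$duration) else 0
  if (is.null(horizon)) horizon <- t_input_end + 10 * params[["t_c"]]

  init <- hpa_state(cs = fps$cs[i], c = fps$c[i], a = cyc$state[["a"]],
                    r = cyc$state[["r"]], o = cyc$state[["o"]])
  tr <- hpa_integrate(params, init, c(0, horizon), input = input)
  sol <- trajectory_solution(tr)

  w <- max(10, diff(range(sol$time)) / 50)
  late <- window_stats(sol, horizon - w, horizon)
  earlier <- window_stats(sol, horizon - 2 * w, horizon - w)
  moving <- abs(late$mean_cs - earlier$mean_cs) > 1e-3

  stable <- fps[fps$stability %in% "stable", , drop = FALSE]
  d2 <- (stable$cs - late$mean_cs)^2 + ((stable$c - late$mean_c) / 10)^2
  nearest <- stable$regime[which.min(d2)]
  list(final_basin = if (moving) "unresolved" else nearest,
       final_cs = late$mean_cs, final_c = late$mean_c, trajectory = tr)
}
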