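#' Characterize the pituitary-adrenal subsystem at fixed CRH
#'
#' With circulating CRH `c` clamped, the ACTH / receptor / cortisol equations
#' form an autonomous delayed subsystem whose attractor — for the delays of
#' interest — is either a fixed point or a limit cycle. This function
#' integrates the clamped subsystem past a burn-in, detects periodicity from
#' successive upward crossings of cortisol through its running mean
#' (a Poincare-style section), anchors phase `theta = 0` at the cortisol
#' maximum, and computes the cycle averages that the cs-nullcline needs.
#'
#' Non-oscillatory attractors are declared when the peak-to-trough cortisol
#' amplitude falls below `tol` relative to the mean; the orbit then collapses
#' to the fixed point and all averages equal point values.
#'
#' @param c_level the clamped circulating CRH level (>= 0).
#' @param params an [hpa_params()] object.
#' @param transient burn-in time discarded before measurement (dimensionless;
#'   long relative to the ultradian period).
#' @param tol relative amplitude below which the attractor is declared
#'   non-oscillatory.
#' @param step integrator step size.
#' @param window measurement window length after burn-in; extended
#'   automatically (up to `max_window`) if too few cycles close.
#' @param max_window give up and error ("unresolved attractor") beyond this.
#' @param n_phase number of phase samples stored for the orbit.
#' @return An object of class `pa_cycle` with fields `c`, `oscillatory`,
#'   `period`, `orbit` (data frame `theta`, `a`, `r`, `o`), `mean_o`,
#'   `mean_a`, `mean_r`, `mean_or`, `mean_exp_bo`, `amplitude_o`, and the
#'   final full state `state`.
#' @examples
#' \donttest{
#' cyc <- pa_characterize(20, hpa_params())
#' cyc$oscillatory
#' cyc$period
#' }
#' @export
pa_characterize <- function(c_level, params, transient = 200, tol = 1e-6,
                            step = 0.01, window = 60, max_window = 480,
                            n_phase = 256) {
  stopifnot(inherits(params, "hpa_params"))
  if (c_level < 0) stop("clamped CRH level must be nonnegative")
  if (transient <= 0) stop("transient must be positive")

  s0 <- hpa_state(cs = params[["c_inf_bar"]] + 0.5, c = c_level,
                  a = 0.5, r = 0.3, o = 0.5)
  burn <- hpa_integrate(params, s0, c(0, transient), step = step,
                        clamp_c = TRUE)

  win <- window
  repeat {
    tr <- hpa_integrate(params, trajectory_history(burn,
                                                   lookback = max(params[["t_d"]], 1) + 1),
                        c(transient, transient + win), step = step,
                        clamp_c = TRUE)
    sol <- trajectory_solution(tr)
    o <- sol$o
    m <- mean(o)
    amp <- max(o) - min(o)
    rel_amp <- amp / max(m, .Machine$double.eps)

    if (rel_amp < tol) {
      fixed <- sol[nrow(sol), ]
      orbit <- data.frame(theta = seq(0, 2 * pi, length.out = n_phase + 1)[-(n_phase + 1)],
                          a = fixed$a, r = fixed$r, o = fixed$o)
      return(structure(list(
        c = c_level, oscillatory = FALSE, period = NA_real_, orbit = orbit,
        mean_o = fixed$o, mean_a = fixed$a, mean_r = fixed$r,
        mean_or = fixed$o * fixed$r,
        mean_exp_bo = exp(-params[["b"]] * fixed$o),
        amplitude_o = amp,
        state = hpa_state(cs = fixed$cs, c = fixed$c, a = fixed$a,
                          r = fixed$r, o = fixed$o),
        params = params), class = "pa_cycle"))
    }

    cross <- upward_crossings(sol$time, o, m)
    if (length(cross) >= 4) {
      periods <- diff(cross)
      use <- utils::tail(periods, 8)
      period <- mean(use)
      if (stats::sd(use) / period < 0.01) {
        return(build_cycle(tr, sol, cross, period, c_level, params, n_phase, amp))
      }
    }
    if (win >= max_window)
      stop("unresolved attractor at c = ", c_level,
           ": no consistent cycle closure within ", max_window,
           " time units after burn-in")
    burn <- tr
    transient <- transient + win
    win <- min(2 * win, max_window)
  }
}

upward_crossings <- function(t, x, level) {
  below <- x < level
  idx <- which(below[-length(below)] & !below[-1])
  if (!length(idx)) return(numeric(0))
  # linear interpolation of the crossing time
  t[idx] + (level - x[idx]) * (t[idx + 1] - t[idx]) / (x[idx + 1] - x[idx])
}

build_cycle <- function(tr, sol, cross, period, c_level, params, n_phase, amp) {
  t_end <- cross[length(cross)]
  ts <- seq(t_end - period, t_end, length.out = n_phase + 1)[-(n_phase + 1)]
  samp <- trajectory_at(tr, ts)
  i_max <- which.max(samp$o)
  rot <- c(i_max:n_phase, seq_len(i_max - 1))
  orbit <- data.frame(theta = seq(0, 2 * pi, length.out = n_phase + 1)[-(n_phase + 1)],
                      a = samp$a[rot], r = samp$r[rot], o = samp$o[rot])
  # evenly spaced samples over one period: the periodic trapezoid rule
  # reduces to the plain mean
  structure(list(
    c = c_level, oscillatory = TRUE, period = period, orbit = orbit,
    mean_o = mean(orbit$o), mean_a = mean(orbit$a), mean_r = mean(orbit$r),
    mean_or = mean(orbit$o * orbit$r),
    mean_exp_bo = mean(exp(-params[["b"]] * orbit$o)),
    amplitude_o = amp,
    state = hpa_state(cs = sol$cs[nrow(sol)], c = c_level,
                      a = sol$a[nrow(sol)], r = sol$r[nrow(sol)],
                      o = sol$o[nrow(sol)]),
    params = params), class = "pa_cycle")
}

#' @export
print.pa_cycle <- function(x, ...) {
  if (x$oscillatory) {
    cat(sprintf(paste0("<pa_cycle> c = %g: limit cycle, period %.4f, ",
                       "<o> = %.4f, amplitude %.4f\n"),
                x$c, x$period, x$mean_o, x$amplitude_o))
  } else {
    cat(sprintf("<pa_cycle> c = %g: fixed point, o* = %.6f\n", x$c, x$mean_o))
  }
  invisible(x)
}

#' Period-averaged stored-CRH synthesis target
#'
#' The cs-nullcline relation averages the synthesis target `c_inf(o)` over
#' one cycle of the pituitary-adrenal attractor at clamped CRH `c`:
#' `<c_inf>(c) = c_inf_bar + <exp(-b o)>`, the average taken over phase.
#' At a non-oscillatory attractor this reduces to the point value.
#'
#' @param c_level clamped CRH level.
#' @param params an [hpa_params()] object.
#' @param cycle optionally, a precomputed [pa_characterize()] result for this
#'   `c_level` (avoids recomputation).
#' @param ... passed to [pa_characterize()].
#' @return The averaged target, a single number.
#' @export
averaged_crh_target <- function(c_level, params, cycle = NULL, ...) {
  if (is.null(cycle)) cycle <- pa_characterize(c_level, params, ...)
  stopifnot(inherits(cycle, "pa_cycle"))
  params[["c_inf_bar"]] + cycle$mean_exp_bo
}

#' Serialize a PA-subsystem cycle summary to JSON
#'
#' Includes the sampled orbit so downstream protocols can phase their dosing.
#'
#' @param cycle a `pa_cycle`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly if written to file).
#' @export
write_cycle_json <- function(cycle, path = NULL) {
  stopifnot(inherits(cycle, "pa_cycle"))
  obj <- cycle[c("c", "oscillatory", "period", "mean_o", "mean_a", "mean_r",
                 "mean_or", "mean_exp_bo", "amplitude_o")]
  obj$orbit <- cycle$orbit
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
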