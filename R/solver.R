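#' Integrate the delayed HPA-axis system
#'
#' Method-of-steps integration of the full seven-component system (five
#' endogenous variables plus the dexamethasone and cosyntropin compartments)
#' with fixed-step explicit fourth-order Runge-Kutta. The delayed adrenal
#' drive `a(t - t_d) + a_exo(t - t_d)` is read from a dense history built by
#' cubic Hermite interpolation of the stored solution, which preserves the
#' solver's fourth-order accuracy. Every rectangle edge (stressor step or
#' dose pulse) is a mandatory restart point, so discontinuous forcing is
#' never straddled by a step and runs are bit-reproducible.
#'
#' @param params an [hpa_params()] object.
#' @param history an `hpa_history` (see [constant_history()]) covering
#'   `[t_span[1] - t_d, t_span[1]]`, or an [hpa_state()] which is promoted to
#'   a constant history.
#' @param t_span numeric length-2, integration interval (dimensionless time).
#' @param input an [input_signal()]; defaults to constant basal input `I0`
#'   from `params`.
#' @param pulses a list of [dose_pulse()] objects (or a single pulse).
#' @param step maximum step size; must not exceed the delay `t_d`. The
#'   default 0.01 corresponds to about 6 s of real time.
#' @param clamp_c if `TRUE`, hold circulating CRH `c` fixed at its initial
#'   value (used to study the pituitary-adrenal subsystem in isolation).
#' @return An `hpa_trajectory`: a data frame with columns `time`, `cs`, `c`,
#'   `a`, `r`, `o`, `o_exo`, `a_exo`, `I`, carrying the node derivatives and
#'   run metadata as attributes. Breakpoint nodes appear twice (left/right
#'   derivative); [trajectory_history()] consumes them for exact
#'   continuation.
#' @examples
#' p <- hpa_params()
#' h <- constant_history(hpa_state(cs = 0.7, c = 15, a = 1, r = 0.4, o = 1))
#' tr <- hpa_integrate(p, h, c(0, 20))
#' tail(tr[, c("time", "o")])
#' @export
hpa_integrate <- function(params, history, t_span, input = NULL,
                          pulses = list(), step = 0.01, clamp_c = FALSE) {
  stopifnot(inherits(params, "hpa_params"))
  validate_params(params)
  if (length(t_span) != 2 || !all(is.finite(t_span)))
    stop("t_span must be two finite times")
  if (inherits(history, "hpa_state") ||
      (is.numeric(history) && !is.null(names(history)))) {
    history <- constant_history(history, t0 = t_span[1],
                                lookback = max(params[["t_d"]], 1))
  }
  stopifnot(inherits(history, "hpa_history"))
  if (is.null(input)) input <- input_signal(baseline = params[["I0"]])
  stopifnot(inherits(input, "hpa_input"))
  if (abs(input$baseline - params[["I0"]]) > 1e-12) {
    # the signal's own baseline wins; fold it into the parameter passed down
    params <- update_params(params, I0 = input$baseline)
  }

  res <- .integrate_core(unclass(params),
                         history$times, history$states, history$derivs,
                         t_span[1], t_span[2],
                         input_steps_matrix(input),
                         pulses_matrix(pulses),
                         step, clamp_c)

  new_trajectory(res, params, step, input, pulses)
}

new_trajectory <- function(res, params, step, input, pulses) {
  df <- data.frame(time = res$times, res$states)
  names(df) <- c("time", state_names())
  df$I <- res$I
  derivs <- res$derivs
  colnames(derivs) <- state_names()
  structure(df,
            class = c("hpa_trajectory", "data.frame"),
            derivs = derivs,
            params = params,
            step = step,
            input = input,
            pulses = pulses,
            n_history = res$n_history)
}

#' @export
print.hpa_trajectory <- function(x, ...) {
  n_hist <- attr(x, "n_history")
  cat(sprintf("<hpa_trajectory> %d nodes (%d history) on t = [%g, %g]\n",
              nrow(x), n_hist, x$time[1], x$time[nrow(x)]))
  invisible(x)
}

#' @export
plot.hpa_trajectory <- function(x, vars = c("o", "a", "c"), ...) {
  sol <- trajectory_solution(x)
  graphics::matplot(sol$time, as.matrix(sol[, vars, drop = FALSE]),
                    type = "l", lty = 1, xlab = "time (dimensionless)",
                    ylab = "level", ...)
  graphics::legend("topright", legend = vars, lty = 1,
                   col = seq_along(vars), bty = "n")
  invisible(x)
}

#' Solution part of a trajectory
#'
#' Drops the history knots and collapses duplicated breakpoint nodes,
#' returning the integrated solution only.
#'
#' @param trajectory an `hpa_trajectory`.
#' @return A data frame with one row per distinct solution time.
#' @export
trajectory_solution <- function(trajectory) {
  stopifnot(inherits(trajectory, "hpa_trajectory"))
  n_hist <- attr(trajectory, "n_history")
  df <- as.data.frame(trajectory)[-seq_len(max(0, n_hist - 1)), , drop = FALSE]
  df <- df[!duplicated(df$time, fromLast = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Interpolate a trajectory at arbitrary times
#'
#' Cubic Hermite interpolation on the stored nodes, the same rule the
#' integrator uses for its delayed lookups.
#'
#' @param trajectory an `hpa_trajectory`.
#' @param t times within the trajectory's span.
#' @return A data frame with columns `time` and the seven state components.
#' @export
trajectory_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "hpa_trajectory"))
  hist <- new_history(trajectory$time,
                      as.matrix(trajectory[, state_names()]),
                      attr(trajectory, "derivs"))
  data.frame(time = t, history_value(hist, t))
}

#' Write / read a trajectory as delimited text
#'
#' CSV with columns `time, cs, c, a, r, o, o_exo, a_exo, I`; a `#`-prefixed
#' header line fingerprints the parameter set and step size so a file can be
#' traced back to its configuration.
#'
#' @param trajectory an `hpa_trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a data frame (solution values only, not a resumable object).
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "hpa_trajectory"))
  p <- attr(trajectory, "params")
  fp <- paste(sprintf("%s=%.10g", names(p), unclass(p)), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hpaxis trajectory; step=%g; %s",
                     attr(trajectory, "step"), fp), con)
  utils::write.csv(trajectory_solution(trajectory), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
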