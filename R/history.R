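#' History functions for the delayed system
#'
#' A delay-differential system needs its state on the whole lookback window
#' `[t0 - t_d, t0]` before integration can start. A history object stores
#' interpolation knots `(t, state, derivative)`; the integrator densifies them
#' with cubic Hermite interpolation.
#'
#' `constant_history()` builds the default: the system held at a fixed
#' nonnegative state for all past times. `trajectory_history()` turns the tail
#' of a finished [hpa_integrate()] run into the history of a continuation run,
#' so a long simulation can be split and resumed exactly.
#'
#' @param state an [hpa_state()] (or named vector) for the constant history.
#' @param t0 the start time of the upcoming integration.
#' @param lookback how far back the window must reach (at least the delay
#'   `t_d` of the run to come).
#' @return An object of class `hpa_history` with fields `times`, `states`
#'   (matrix), `derivs` (matrix).
#' @examples
#' h <- constant_history(hpa_state(cs = 0.7, c = 15, a = 1, r = 0.4, o = 1))
#' @export
constant_history <- function(state, t0 = 0, lookback = 10) {
  s <- as_state_vector(state)
  if (any(s < 0)) stop("history state must be nonnegative")
  if (lookback <= 0) stop("lookback must be positive")
  times <- c(t0 - lookback, t0)
  states <- rbind(s, s)
  derivs <- matrix(0, 2, 7)
  new_history(times, states, derivs)
}

new_history <- function(times, states, derivs) {
  colnames(states) <- state_names()
  colnames(derivs) <- state_names()
  rownames(states) <- NULL
  rownames(derivs) <- NULL
  structure(list(times = as.numeric(times), states = states, derivs = derivs),
            class = "hpa_history")
}

#' @rdname constant_history
#' @param trajectory an `hpa_trajectory` from [hpa_integrate()].
#' @export
trajectory_history <- function(trajectory, lookback = 10) {
  stopifnot(inherits(trajectory, "hpa_trajectory"))
  times <- trajectory$time
  t_end <- times[length(times)]
  keep <- times >= t_end - lookback - 1e-9
  if (sum(keep) < 2) stop("trajectory too short for the requested lookback")
  sm <- as.matrix(trajectory[keep, state_names()])
  dm <- attr(trajectory, "derivs")[keep, , drop = FALSE]
  new_history(times[keep], sm, dm)
}

#' Evaluate a history at given times
#'
#' Cubic Hermite interpolation of the stored knots; constant extrapolation
#' outside the knot range.
#'
#' @param history an `hpa_history`.
#' @param t times at which to evaluate.
#' @return A matrix (length(t) x 7) of states.
#' @export
history_value <- function(history, t) {
  stopifnot(inherits(history, "hpa_history"))
  ht <- history$times
  out <- matrix(NA_real_, length(t), 7,
                dimnames = list(NULL, state_names()))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= ht[1]) { out[i, ] <- history$states[1, ]; next }
    if (ti >= ht[length(ht)]) { out[i, ] <- history$states[nrow(history$states), ]; next }
    j <- findInterval(ti, ht)
    # skip over duplicated breakpoint knots
    while (j + 1 <= length(ht) && ht[j + 1] <= ht[j]) j <- j + 1
    h <- ht[j + 1] - ht[j]
    if (h <= 0) { out[i, ] <- history$states[j, ]; next }
    u <- (ti - ht[j]) / h
    h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2;    h11 <- u^3 - u^2
    out[i, ] <- h00 * history$states[j, ] + h * h10 * history$derivs[j, ] +
      h01 * history$states[j + 1, ] + h * h11 * history$derivs[j + 1, ]
  }
  out
}
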