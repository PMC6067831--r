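#' Synaptic input signal with rectangle stressor steps
#'
#' The synaptic drive onto the CRH neurons is `I(t) = I0 + sum of active
#' steps`, where each step is a rectangle of given start, duration and
#' amplitude (`Iext`). A constant basal input is the default; stressors are
#' added as steps.
#'
#' @param baseline basal input level `I0` (> 0 typically; >= 0 accepted).
#' @param steps a data frame with columns `start`, `duration`, `amplitude`
#'   (all in dimensionless time/units), or `NULL` for no stressor.
#' @return An object of class `hpa_input`.
#' @examples
#' sig <- input_signal(1, data.frame(start = 10, duration = 5.77, amplitude = 0.5))
#' input_value(sig, c(9, 12, 20))
#' @export
input_signal <- function(baseline = 1, steps = NULL) {
  if (baseline < 0) stop("baseline input must be nonnegative")
  if (is.null(steps)) {
    steps <- data.frame(start = numeric(0), duration = numeric(0),
                        amplitude = numeric(0))
  }
  steps <- as.data.frame(steps)
  req <- c("start", "duration", "amplitude")
  if (!all(req %in% names(steps)))
    stop("steps must have columns start, duration, amplitude")
  steps <- steps[, req, drop = FALSE]
  if (nrow(steps)) {
    if (any(steps$duration <= 0)) stop("step durations must be positive")
    if (any(steps$amplitude < 0)) stop("step amplitudes must be nonnegative")
  }
  structure(list(baseline = baseline, steps = steps), class = "hpa_input")
}

#' @rdname input_signal
#' @param input an `hpa_input` object.
#' @param t time(s) at which to evaluate the signal; steps are active on
#'   `[start, start + duration)`.
#' @export
input_value <- function(input, t) {
  stopifnot(inherits(input, "hpa_input"))
  v <- rep(input$baseline, length(t))
  if (nrow(input$steps)) {
    for (i in seq_len(nrow(input$steps))) {
      s <- input$steps[i, ]
      v <- v + ifelse(t >= s$start & t < s$start + s$duration, s$amplitude, 0)
    }
  }
  v
}

#' @export
print.hpa_input <- function(x, ...) {
  cat("<hpa_input> baseline I0 =", x$baseline, "with", nrow(x$steps),
      "stressor step(s)\n")
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

input_steps_matrix <- function(input) {
  if (is.null(input)) return(matrix(numeric(0), 0, 3))
  stopifnot(inherits(input, "hpa_input"))
  if (!nrow(input$steps)) return(matrix(numeric(0), 0, 3))
  cbind(start = input$steps$start,
        end = input$steps$start + input$steps$duration,
        amp = input$steps$amplitude)
}

#' Rectangle dose pulse for a drug compartment
#'
#' A dose of dexamethasone or cosyntropin is modelled as a rectangle infusion
#' into its exogenous compartment: constant rate `height` over
#' `[start, start + width)`. The dexamethasone protocol uses width 30 min
#' (2.888 dimensionless) and height 2.
#'
#' @param compartment `"dex"` (feeds `o_exo`) or `"acth"` (feeds `a_exo`).
#' @param start pulse onset (dimensionless time).
#' @param width pulse duration (> 0, dimensionless).
#' @param height infusion rate amplitude (>= 0, nondimensional units per
#'   unit time).
#' @return An object of class `hpa_pulse`.
#' @examples
#' dose_pulse("dex", start = 0, width = minutes_to_dimensionless(30), height = 2)
#' @export
dose_pulse <- function(compartment = c("dex", "acth"), start, width, height) {
  compartment <- match.arg(compartment)
  if (width <= 0) stop("pulse width must be positive")
  if (height < 0) stop("pulse height must be nonnegative")
  structure(list(compartment = compartment, start = start, width = width,
                 height = height), class = "hpa_pulse")
}

#' @export
print.hpa_pulse <- function(x, ...) {
  cat(sprintf("<hpa_pulse> %s: rate %g on [%g, %g)\n", x$compartment,
              x$height, x$start, x$start + x$width))
  invisible(x)
}

pulses_matrix <- function(pulses) {
  if (is.null(pulses) || length(pulses) == 0) return(matrix(numeric(0), 0, 4))
  if (inherits(pulses, "hpa_pulse")) pulses <- list(pulses)
  do.call(rbind, lapply(pulses, function(p) {
    stopifnot(inherits(p, "hpa_pulse"))
    c(comp = if (p$compartment == "dex") 0 else 1,
      start = p$start, end = p$start + p$width, height = p$height)
  }))
}
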