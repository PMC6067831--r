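#' System state of the HPA-axis model
#'
#' Bundles the five endogenous state variables — stored CRH `cs`, circulating
#' CRH `c`, ACTH `a`, available pituitary glucocorticoid receptor `r`,
#' cortisol `o` — together with the two exogenous drug compartments `o_exo`
#' (dexamethasone, in cortisol equivalents) and `a_exo` (cosyntropin, in ACTH
#' equivalents). All components must be nonnegative.
#'
#' @param cs,c,a,r,o endogenous levels (nonnegative).
#' @param o_exo,a_exo exogenous drug levels (nonnegative).
#' @return A named numeric vector of class `hpa_state`.
#' @examples
#' hpa_state(cs = 0.8, c = 20, a = 1, r = 0.5, o = 2)
#' @export
hpa_state <- function(cs = 0, c = 0, a = 0, r = 0, o = 0,
                      o_exo = 0, a_exo = 0) {
  s <- c(cs = cs, c = c, a = a, r = r, o = o, o_exo = o_exo, a_exo = a_exo)
  if (any(!is.finite(s))) stop("state components must be finite")
  if (any(s < 0)) stop("state components must be nonnegative")
  structure(s, class = "hpa_state")
}

state_names <- function() c("cs", "c", "a", "r", "o", "o_exo", "a_exo")

as_state_vector <- function(state) {
  if (inherits(state, "hpa_state")) return(unclass(state))
  if (is.numeric(state) && !is.null(names(state))) {
    out <- stats::setNames(numeric(7), state_names())
    known <- intersect(names(state), state_names())
    if (length(known) == 0) stop("state has no recognized component names")
    out[known] <- state[known]
    if (any(out < 0)) stop("state components must be nonnegative")
    return(out)
  }
  stop("state must be an hpa_state or a named numeric vector")
}

#' Regulatory functions of the HPA-axis model
#'
#' The five smooth input-output relations that shape the model:
#'
#' * `release_fraction(cs, k)`: fraction `h(cs) = 1 - exp(-k * cs)` of the
#'   maximal CRH release rate realized at stored-CRH level `cs`; increasing,
#'   saturating below 1.
#' * `autocrine_upregulation(c, params)`: Hill-type auto/paracrine boost of
#'   CRH activity in the pituitary,
#'   `gc(c) = gc_max (q1 c)^n / (1 + (q1 c)^n)`.
#' * `pituitary_feedback(or_product, p2)`: cortisol's negative feedback on
#'   ACTH secretion, `fa(or) = 1 / (1 + p2 or)`; decreasing and convex in the
#'   cortisol-receptor complex level `or`. The convexity is what makes equal
#'   drug increments bite harder from a low starting complex level.
#' * `gr_production(or_product, p4, p5)`: glucocorticoid-receptor synthesis
#'   `gr(or) = (or)^2 / (p4 + (or)^2) + p5`, basal rate `p5`, saturating at
#'   `1 + p5`.
#' * `crh_synthesis_target(o, b, c_inf_bar)`: the stored-CRH target
#'   `c_inf(o) = c_inf_bar + exp(-b o)` toward which `cs` relaxes; strictly
#'   decreasing in cortisol.
#'
#' @param cs stored CRH level(s), nonnegative.
#' @param k stored-CRH release coupling (> 0).
#' @param c circulating CRH level(s), nonnegative.
#' @param params an [hpa_params()] object (uses `gc_max`, `q1`, `n`).
#' @param or_product cortisol-receptor complex level(s) `o * r`, nonnegative.
#' @param p2,p4,p5 see [hpa_params()].
#' @param o cortisol level(s), nonnegative.
#' @param b,c_inf_bar see [hpa_params()].
#' @return Numeric vector of function values.
#' @examples
#' release_fraction(1, 2.83)
#' pituitary_feedback(1 / 15, 15) # half-suppression
#' @name regulatory-functions
NULL

#' @rdname regulatory-functions
#' @export
release_fraction <- function(cs, k) {
  if (any(cs < 0)) stop("stored CRH level cs must be nonnegative")
  if (any(k <= 0)) stop("coupling k must be positive")
  1 - exp(-k * cs)
}

#' @rdname regulatory-functions
#' @export
autocrine_upregulation <- function(c, params) {
  if (any(c < 0)) stop("CRH level must be nonnegative")
  x <- (params[["q1"]] * c)^params[["n"]]
  params[["gc_max"]] * x / (1 + x)
}

#' @rdname regulatory-functions
#' @export
pituitary_feedback <- function(or_product, p2) {
  if (any(or_product < 0)) stop("complex level must be nonnegative")
  1 / (1 + p2 * or_product)
}

#' @rdname regulatory-functions
#' @export
gr_production <- function(or_product, p4, p5) {
  if (any(or_product < 0)) stop("complex level must be nonnegative")
  or_product^2 / (p4 + or_product^2) + p5
}

#' @rdname regulatory-functions
#' @export
crh_synthesis_target <- function(o, b, c_inf_bar) {
  if (any(o < 0)) stop("cortisol level must be nonnegative")
  c_inf_bar + exp(-b * o)
}

#' Right-hand side of the delayed HPA-axis system
#'
#' Evaluates the time derivatives of the five endogenous state variables at a
#' given state, delayed ACTH values, and synaptic input. The delayed terms
#' `a(t - t_d)` and `a_exo(t - t_d)` must be supplied by the caller (the
#' integrator reads them from its dense history). Dexamethasone (`o_exo`)
#' enters only the pituitary feedback and receptor equations — it is excluded
#' from the stored-CRH synthesis target because dexamethasone penetrates the
#' brain poorly — while cosyntropin (`a_exo`) enters only the adrenal drive.
#'
#' @param state an [hpa_state()] or named vector with components
#'   `cs, c, a, r, o, o_exo, a_exo`.
#' @param a_delayed endogenous ACTH level at `t - t_d`.
#' @param a_exo_delayed cosyntropin level at `t - t_d`.
#' @param I_now synaptic input level at `t`.
#' @param params an [hpa_params()] object.
#' @return Named numeric vector of the five derivatives
#'   `(dcs, dc, da, dr, do)`.
#' @examples
#' p <- hpa_params()
#' system_rhs(hpa_state(), a_delayed = 0, a_exo_delayed = 0, I_now = 1, p)
#' @export
system_rhs <- function(state, a_delayed, a_exo_delayed, I_now, params) {
  s <- as_state_vector(state)
  if (a_delayed < 0 || a_exo_delayed < 0)
    stop("delayed ACTH values must be nonnegative")
  or_tot <- (s[["o"]] + s[["o_exo"]]) * s[["r"]]
  c(dcs = (crh_synthesis_target(s[["o"]], params[["b"]], params[["c_inf_bar"]]) -
             s[["cs"]]) / params[["t_c"]],
    dc = params[["q0"]] * I_now * release_fraction(s[["cs"]], params[["k"]]) +
      autocrine_upregulation(s[["c"]], params) - params[["q2"]] * s[["c"]],
    da = s[["c"]] * pituitary_feedback(or_tot, params[["p2"]]) -
      params[["p3"]] * s[["a"]],
    dr = gr_production(or_tot, params[["p4"]], params[["p5"]]) -
      params[["p6"]] * s[["r"]],
    do = a_delayed + a_exo_delayed - s[["o"]])
}

#' One-compartment pharmacokinetics of an exogenous drug
#'
#' Derivative of a drug compartment under rectangle infusion and first-order
#' elimination: `dx/dt = pulse_rate - decay * x`. Used for circulating
#' dexamethasone (decay `p7`) and cosyntropin (decay `p8`).
#'
#' @param x_exo current drug level (nonnegative).
#' @param pulse_rate infusion rate at the current time (nonnegative).
#' @param decay first-order elimination rate relative to cortisol (> 0).
#' @return The derivative `pulse_rate - decay * x_exo`.
#' @export
pharmacokinetics_rhs <- function(x_exo, pulse_rate, decay) {
  if (any(x_exo < 0)) stop("drug level must be nonnegative")
  if (any(decay <= 0)) stop("decay rate must be positive")
  pulse_rate - decay * x_exo
}
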