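#' Nondimensional parameter set for the HPA-axis model
#'
#' Constructs and validates the full set of nondimensional constants of the
#' delayed HPA-axis model. Time is measured in units of the cortisol
#' elimination timescale (half-life 7.2 min divided by log 2), concentrations
#' in the model's nondimensional hormone units.
#'
#' The defaults are the reference set used throughout: the CRH release/decay
#' block (`q0`, `q1`, `q2`, `gc_max`, `n`, `k`, `I0`), the pituitary-adrenal
#' block (`p2`...`p6`, delay `t_d`), the stored-CRH synthesis block (`b`,
#' `c_inf_bar`, `t_c`) and the exogenous-drug clearances (`p7` for
#' dexamethasone, `p8` for cosyntropin). `c_inf_bar` and `t_c` are calibrated
#' constants of this package (see the methods vignette): `c_inf_bar` places
#' the cs-nullcline so that the reference set is bistable, `t_c` sets the slow
#' stored-CRH relaxation timescale.
#'
#' The default Hill coefficient is `n = 5`; one published sweep of the
#' c-nullcline uses `n = 6` as its base value, which can be reproduced by
#' overriding `n`.
#'
#' @param q0 maximum basal CRH release rate.
#' @param q1 circulating CRH level giving half-maximum self-upregulation.
#' @param q2 ratio of CRH to cortisol decay rates.
#' @param gc_max maximum auto/paracrine CRH effect in the pituitary.
#' @param n Hill coefficient of the CRH self-upregulation function (>= 1).
#' @param k coupling from stored CRH to release fraction.
#' @param b strength of cortisol suppression of CRH synthesis.
#' @param c_inf_bar asymptotic stored-CRH target under full suppression (>= 0).
#' @param t_c relaxation timescale of stored CRH (slow relative to the
#'   ultradian period).
#' @param p2 cortisol-GR complex level for half-maximum negative feedback.
#' @param p3 ratio of ACTH to cortisol decay rates.
#' @param p4 complex level (squared scale) for half-maximum GR upregulation.
#' @param p5 basal GR production rate.
#' @param p6 ratio of GR to cortisol decay rates.
#' @param t_d adrenal delay between ACTH stimulation and cortisol release
#'   (dimensionless; 15 min corresponds to 1.44).
#' @param I0 basal synaptic input to the PVN.
#' @param p7 dexamethasone clearance rate relative to cortisol.
#' @param p8 cosyntropin clearance rate relative to cortisol.
#' @param ... overrides of any of the above by name.
#'
#' @return An object of class `hpa_params`: a named numeric vector with all
#'   18 constants.
#' @examples
#' p <- hpa_params()
#' p["n"]
#' hpa_params(n = 6, q0 = 33.6)
#' @export
hpa_params <- function(q0 = 28.0, q1 = 0.04, q2 = 1.8, gc_max = 42,
                       n = 5, k = 2.83, b = 0.6,
                       c_inf_bar = 0.25, t_c = 150,
                       p2 = 15, p3 = 7.2, p4 = 0.05, p5 = 0.11, p6 = 2.9,
                       t_d = 1.44, I0 = 1, p7 = 0.03, p8 = 1.7, ...) {
  extra <- list(...)
  p <- c(q0 = q0, q1 = q1, q2 = q2, gc_max = gc_max, n = n, k = k, b = b,
         c_inf_bar = c_inf_bar, t_c = t_c,
         p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6,
         t_d = t_d, I0 = I0, p7 = p7, p8 = p8)
  if (length(extra)) {
    bad <- setdiff(names(extra), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; valid names are: ", paste(names(p), collapse = ", "))
    p[names(extra)] <- vapply(extra, as.numeric, numeric(1))
  }
  validate_params(p)
  structure(p, class = "hpa_params")
}

validate_params <- function(p) {
  needed <- c("q0", "q1", "q2", "gc_max", "n", "k", "b", "c_inf_bar", "t_c",
              "p2", "p3", "p4", "p5", "p6", "t_d", "I0", "p7", "p8")
  missing <- setdiff(needed, names(p))
  if (length(missing))
    stop("parameter set is missing: ", paste(missing, collapse = ", "))
  if (any(!is.finite(p)))
    stop("all parameters must be finite")
  strict_pos <- setdiff(needed, c("c_inf_bar", "t_d"))
  for (nm in strict_pos)
    if (p[[nm]] <= 0) stop("parameter ", nm, " must be strictly positive")
  if (p[["c_inf_bar"]] < 0) stop("parameter c_inf_bar must be >= 0")
  if (p[["t_d"]] < 0) stop("parameter t_d must be >= 0")
  if (p[["n"]] < 1) stop("Hill coefficient n must be >= 1")
  invisible(p)
}

#' @export
print.hpa_params <- function(x, ...) {
  cat("<hpa_params> nondimensional HPA-axis parameter set\n")
  v <- unclass(x)
  print(round(v, 6))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named entries replaced, re-validated.
#'
#' @param params an [hpa_params()] object.
#' @param ... named replacements, e.g. `update_params(p, q0 = 33.6)`.
#' @return An `hpa_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "hpa_params"))
  repl <- list(...)
  p <- unclass(params)
  bad <- setdiff(names(repl), names(p))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(repl)] <- vapply(repl, as.numeric, numeric(1))
  validate_params(p)
  structure(p, class = "hpa_params")
}

#' Relative decay-rate ratio from two half-lives
#'
#' First-order elimination rates are log(2)/half-life, so the ratio of a
#' reference hormone's decay rate to a drug's is the inverse ratio of their
#' half-lives; log(2) cancels. Used to derive the nondimensional clearances
#' `p7` (dexamethasone, half-life ~240 min vs cortisol ~7.2 min) and `p8`
#' (cosyntropin, half-life ~4.1 min).
#'
#' @param halflife_ref_minutes half-life of the reference hormone (cortisol).
#' @param halflife_drug_minutes half-life of the drug.
#' @return The dimensionless decay-rate ratio `halflife_ref / halflife_drug`.
#' @examples
#' rate_ratio_from_halflives(7.2, 240) # 0.03
#' @export
rate_ratio_from_halflives <- function(halflife_ref_minutes,
                                      halflife_drug_minutes) {
  if (any(halflife_ref_minutes <= 0) || any(halflife_drug_minutes <= 0))
    stop("half-lives must be strictly positive")
  halflife_ref_minutes / halflife_drug_minutes
}

#' Convert clock time in minutes to dimensionless model time
#'
#' The model's unit of time is the cortisol elimination timescale,
#' `halflife / log(2)`; 15 minutes corresponds to 1.44 dimensionless units at
#' the 7.2-min cortisol half-life.
#'
#' @param t_minutes time in minutes.
#' @param cortisol_halflife_minutes cortisol half-life in minutes.
#' @return Dimensionless time `t_minutes * log(2) / halflife`.
#' @examples
#' minutes_to_dimensionless(15)  # 1.44
#' minutes_to_dimensionless(540) # the 9-h post-dose DST window
#' @export
minutes_to_dimensionless <- function(t_minutes, cortisol_halflife_minutes = 7.2) {
  if (cortisol_halflife_minutes <= 0)
    stop("cortisol half-life must be strictly positive")
  if (any(t_minutes < 0)) stop("time must be nonnegative")
  t_minutes * log(2) / cortisol_halflife_minutes
}

#' @rdname minutes_to_dimensionless
#' @param t_dimensionless dimensionless model time.
#' @export
dimensionless_to_minutes <- function(t_dimensionless,
                                     cortisol_halflife_minutes = 7.2) {
  if (cortisol_halflife_minutes <= 0)
    stop("cortisol half-life must be strictly positive")
  t_dimensionless * cortisol_halflife_minutes / log(2)
}
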