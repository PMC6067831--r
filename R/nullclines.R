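#' The c-nullcline of the HPA-axis model
#'
#' The locus in the (cs, c)-plane where circulating CRH is stationary:
#' `0 = q0 I h(cs) + gc(c) - q2 c`. Parameterizing by `c` gives a closed
#' form: with `u = (q2 c - gc(c)) / (q0 I0)`, a point exists iff
#' `0 <= u < 1`, and then `cs = -log(1 - u) / k`. Folds (knees) appear as
#' local extrema of `cs` along the curve; a folded (S-shaped) c-nullcline is
#' the backbone of bistability.
#'
#' @param params an [hpa_params()] object.
#' @param c_grid nonnegative, increasing grid of circulating-CRH values. The
#'   default spans 0-60 at spacing 0.02, fine enough to resolve the folds of
#'   the reference set.
#' @return An object of class `hpa_nullcline` (`which = "c"`): a data frame
#'   with columns `c`, `cs`, `branch`, plus attributes `knees` (data frame of
#'   refined fold points) and `params`. Rows where the relation has no
#'   solution are dropped; an empty curve is returned as a zero-row frame.
#' @examples
#' nc <- c_nullcline(hpa_params())
#' attr(nc, "knees")
#' @export
c_nullcline <- function(params, c_grid = seq(0, 60, by = 0.02)) {
  stopifnot(inherits(params, "hpa_params"))
  if (any(c_grid < 0)) stop("c_grid must be nonnegative")
  cs <- c_nullcline_cs(c_grid, params)
  keep <- !is.na(cs)
  df <- data.frame(c = c_grid[keep], cs = cs[keep])
  knees <- locate_knees(df, params)
  df$branch <- branch_labels(df, knees)
  structure(df, class = c("hpa_nullcline", "data.frame"),
            which = "c", knees = knees, params = params)
}

#' @rdname c_nullcline
#' @param c circulating CRH value(s).
#' @return `c_nullcline_cs` returns the closed-form `cs` values (`NA` where
#'   the relation has no solution).
#' @export
c_nullcline_cs <- function(c, params) {
  u <- (params[["q2"]] * c - autocrine_upregulation(c, params)) /
    (params[["q0"]] * params[["I0"]])
  out <- rep(NA_real_, length(u))
  ok <- !is.na(u) & u >= 0 & u < 1
  out[ok] <- -log1p(-u[ok]) / params[["k"]]
  out
}

locate_knees <- function(df, params) {
  empty <- data.frame(c = numeric(0), cs = numeric(0), type = character(0))
  n <- nrow(df)
  if (n < 3) return(empty)
  # 3-point slope stencil; a sign change brackets a local extremum of cs
  slope <- (df$cs[c(2:n, n)] - df$cs[c(1, 1:(n - 1))]) /
    (df$c[c(2:n, n)] - df$c[c(1, 1:(n - 1))])
  sgn <- sign(slope)
  flips <- which(sgn[-n] * sgn[-1] < 0)
  if (!length(flips)) return(empty)
  knees <- lapply(flips, function(i) {
    lo <- df$c[max(1, i - 1)]; hi <- df$c[min(n, i + 2)]
    maximum <- sgn[i] > 0
    # finite sentinel where the relation has no solution keeps the search
    # inside the admissible range
    objective <- function(cc) {
      v <- c_nullcline_cs(cc, params)
      if (is.na(v)) (if (maximum) -1 else 1) * 1e10 else v
    }
    opt <- stats::optimize(objective, c(lo, hi), maximum = maximum,
                           tol = 1e-10)
    cc <- if (maximum) opt$maximum else opt$minimum
    data.frame(c = cc, cs = c_nullcline_cs(cc, params),
               type = if (maximum) "upper" else "lower")
  })
  out <- do.call(rbind, knees)
  # "upper"/"lower" name the knee's position in c: the fold at smaller c is
  # the lower knee
  out[order(out$c), , drop = FALSE]
}

branch_labels <- function(df, knees) {
  if (nrow(knees) < 2) return(rep("monotone", nrow(df)))
  c_lo <- knees$c[1]; c_hi <- knees$c[nrow(knees)]
  ifelse(df$c < c_lo, "lower", ifelse(df$c > c_hi, "upper", "middle"))
}

#' The cs-nullcline by limit-cycle averaging
#'
#' The stored-CRH nullcline couples `cs` to `c` through cortisol: at each
#' clamped `c`, the pituitary-adrenal attractor is characterized
#' ([pa_characterize()]) and `cs = c_inf_bar + <exp(-b o)>`, the synthesis
#' target averaged over one cycle (or the point value at a non-oscillatory
#' attractor). Samples over oscillatory attractors are flagged — they are
#' the period-averaged (conventionally dashed) part of the curve.
#'
#' @param params an [hpa_params()] object.
#' @param c_grid grid of circulating-CRH values (default 0-40, spacing 0.5).
#' @param ... passed to [pa_characterize()].
#' @return An `hpa_nullcline` (`which = "cs"`): data frame with columns `c`,
#'   `cs`, `oscillatory`, `period`, `mean_o`, `mean_or`; attribute `cycles`
#'   holds the underlying `pa_cycle` list.
#' @export
cs_nullcline <- function(params, c_grid = seq(0, 40, by = 0.5), ...) {
  stopifnot(inherits(params, "hpa_params"))
  if (any(c_grid < 0)) stop("c_grid must be nonnegative")
  cycles <- lapply(c_grid, function(cv) pa_characterize(cv, params, ...))
  df <- data.frame(
    c = c_grid,
    cs = params[["c_inf_bar"]] + vapply(cycles, `[[`, numeric(1), "mean_exp_bo"),
    oscillatory = vapply(cycles, `[[`, logical(1), "oscillatory"),
    period = vapply(cycles, `[[`, numeric(1), "period"),
    mean_o = vapply(cycles, `[[`, numeric(1), "mean_o"),
    mean_or = vapply(cycles, `[[`, numeric(1), "mean_or"))
  structure(df, class = c("hpa_nullcline", "data.frame"),
            which = "cs", params = params, cycles = cycles)
}

#' @export
print.hpa_nullcline <- function(x, ...) {
  kind <- attr(x, "which")
  cat(sprintf("<hpa_nullcline> %s-nullcline, %d samples", kind, nrow(x)))
  if (kind == "c") {
    kn <- attr(x, "knees")
    cat(sprintf(", %d knee(s)", nrow(kn)))
    if (nrow(kn) >= 2)
      cat(sprintf(" (folded over cs in [%.3f, %.3f])",
                  min(kn$cs), max(kn$cs)))
  } else {
    cat(sprintf(", oscillatory over c in [%s]",
                paste(round(range(x$c[x$oscillatory]), 2), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Residual of a nullcline sample set against its defining relation
#'
#' For the c-nullcline, the residual of `q0 I h(cs) + gc(c) - q2 c`; for the
#' cs-nullcline, `cs - (c_inf_bar + <exp(-b o)>)` recomputed from the stored
#' cycles. Part of the public contract: emitted samples satisfy their
#' relation to high accuracy.
#'
#' @param curve an `hpa_nullcline`.
#' @return Numeric vector of residuals, one per sample.
#' @export
nullcline_residual <- function(curve) {
  stopifnot(inherits(curve, "hpa_nullcline"))
  params <- attr(curve, "params")
  if (attr(curve, "which") == "c") {
    params[["q0"]] * params[["I0"]] * release_fraction(curve$cs, params[["k"]]) +
      autocrine_upregulation(curve$c, params) - params[["q2"]] * curve$c
  } else {
    cycles <- attr(curve, "cycles")
    curve$cs - (params[["c_inf_bar"]] +
                  vapply(cycles, `[[`, numeric(1), "mean_exp_bo"))
  }
}

#' Locate and classify the fixed points of the reduced (cs, c) system
#'
#' Intersections of the c- and cs-nullclines determine the long-term states
#' of the full system. Both curves are parameterized by `c`, so crossings are
#' sign changes of the gap `cs_c(c) - cs_s(c)`, refined by bisection with
#' fresh limit-cycle characterizations. Stability is classified dynamically:
#' the full delayed system is integrated from small cs-perturbations on
#' either side of each intersection, and the point is stable iff both runs
#' return. Among stable points, the one with the larger cycle-averaged
#' cortisol is labelled `normal`, the smaller `diseased`.
#'
#' @param params an [hpa_params()] object.
#' @param c_curve,cs_curve optionally precomputed [c_nullcline()] /
#'   [cs_nullcline()] for these parameters.
#' @param refine_tol bisection tolerance on `c`.
#' @param perturb cs-offset used for the stability probe.
#' @param classify if `FALSE`, skip the (relatively costly) stability
#'   integrations and return `stability = NA`.
#' @param ... passed to [pa_characterize()] during refinement.
#' @return An object of class `hpa_fixed_points`: a data frame with columns
#'   `cs`, `c`, `stability`, `regime`, `mean_o`, `oscillatory`, `residual_c`,
#'   `residual_cs`. Tangential near-crossings (gap extrema within
#'   `1e-4` of zero that do not change sign) are reported via the
#'   `degenerate` attribute.
#' @examples
#' \donttest{
#' find_fixed_points(hpa_params())
#' }
#' @export
find_fixed_points <- function(params, c_curve = NULL, cs_curve = NULL,
                              refine_tol = 1e-9, perturb = 0.02,
                              classify = TRUE, ...) {
  stopifnot(inherits(params, "hpa_params"))
  if (is.null(c_curve)) c_curve <- c_nullcline(params)
  if (is.null(cs_curve)) cs_curve <- cs_nullcline(params, ...)
  if (!nrow(c_curve) || !nrow(cs_curve))
    stop("both nullclines must be non-empty on an overlapping range")

  gap_grid <- function(cg) c_nullcline_cs(cg, params)
  cg <- cs_curve$c
  gap <- gap_grid(cg) - cs_curve$cs
  ok <- !is.na(gap)
  cg <- cg[ok]; gap <- gap[ok]
  if (length(cg) < 2) stop("nullclines do not overlap")

  gap_fun <- function(cc) {
    c_nullcline_cs(cc, params) -
      averaged_crh_target(cc, params, ...)
  }

  flips <- which(gap[-length(gap)] * gap[-1] < 0)
  roots <- vapply(flips, function(i) {
    lo <- cg[i]; hi <- cg[i + 1]
    flo <- gap[i]
    while (hi - lo > refine_tol) {
      mid <- 0.5 * (lo + hi)
      fm <- gap_fun(mid)
      if (fm == 0) return(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    0.5 * (lo + hi)
  }, numeric(1))
  # points sitting exactly on a grid node
  exact <- cg[gap == 0]
  roots <- sort(unique(c(roots, exact)))

  # tangential near-crossings: interior local minima of |gap| that come close
  # to zero without a sign change
  degen <- c()
  ag <- abs(gap)
  for (i in 2:(length(ag) - 1)) {
    if (ag[i] < ag[i - 1] && ag[i] < ag[i + 1] && ag[i] < 1e-4 &&
        sign(gap[i - 1]) == sign(gap[i + 1]) && gap[i] != 0)
      degen <- c(degen, cg[i])
  }

  if (!length(roots)) {
    out <- data.frame(cs = numeric(0), c = numeric(0),
                      stability = character(0), regime = character(0),
                      mean_o = numeric(0), oscillatory = logical(0),
                      residual_c = numeric(0), residual_cs = numeric(0))
    return(structure(out, class = c("hpa_fixed_points", "data.frame"),
                     degenerate = degen, params = params))
  }

  cycles <- lapply(roots, function(cc) pa_characterize(cc, params, ...))
  cs_star <- vapply(roots, function(cc) c_nullcline_cs(cc, params), numeric(1))
  res_cs <- cs_star - (params[["c_inf_bar"]] +
                         vapply(cycles, `[[`, numeric(1), "mean_exp_bo"))
  res_c <- params[["q0"]] * params[["I0"]] *
    release_fraction(cs_star, params[["k"]]) +
    autocrine_upregulation(roots, params) - params[["q2"]] * roots

  stability <- rep(NA_character_, length(roots))
  if (classify) {
    stability <- vapply(seq_along(roots), function(i) {
      probe_stability(params, roots[i], cs_star[i], cycles[[i]], perturb)
    }, character(1))
  }

  mean_o <- vapply(cycles, `[[`, numeric(1), "mean_o")
  regime <- rep(NA_character_, length(roots))
  stab_idx <- which(stability == "stable")
  if (length(stab_idx)) {
    regime[stab_idx[which.max(mean_o[stab_idx])]] <- "normal"
    if (length(stab_idx) > 1)
      regime[stab_idx[which.min(mean_o[stab_idx])]] <- "diseased"
  }

  out <- data.frame(cs = cs_star, c = roots, stability = stability,
                    regime = regime, mean_o = mean_o,
                    oscillatory = vapply(cycles, `[[`, logical(1), "oscillatory"),
                    residual_c = res_c, residual_cs = res_cs)
  structure(out, class = c("hpa_fixed_points", "data.frame"),
            degenerate = degen, params = params, cycles = cycles)
}

probe_stability <- function(params, c_star, cs_star, cycle, perturb) {
  horizon <- max(8 * params[["t_c"]], 120)
  settle <- function(sign_dir) {
    s0 <- cycle$state
    s0["cs"] <- max(cs_star + sign_dir * perturb, 0)
    s0["c"] <- c_star
    tr <- hpa_integrate(params, hpa_state(cs = s0[["cs"]], c = s0[["c"]],
                                          a = s0[["a"]], r = s0[["r"]],
                                          o = s0[["o"]]),
                        c(0, horizon))
    sol <- trajectory_solution(tr)
    utils::tail(sol$cs, 1)
  }
  up <- settle(+1); dn <- settle(-1)
  if (abs(up - cs_star) < 2 * perturb && abs(dn - cs_star) < 2 * perturb)
    "stable" else "unstable"
}

#' @export
print.hpa_fixed_points <- function(x, ...) {
  cat(sprintf("<hpa_fixed_points> %d intersection(s)\n", nrow(x)))
  if (nrow(x)) print(as.data.frame(x), digits = 4)
  dg <- attr(x, "degenerate")
  if (length(dg))
    cat("degenerate near-crossings flagged at c =",
        paste(round(dg, 4), collapse = ", "), "\n")
  invisible(x)
}

#' One-parameter nullcline sweeps
#'
#' Recomputes a nullcline over a family of values of one parameter and
#' summarizes each curve (knee positions, branch extents, oscillatory
#' range), the machinery behind qualitative parameter-dependence ledgers.
#'
#' @param params base [hpa_params()].
#' @param target name of the parameter to vary.
#' @param values vector of values it takes (e.g. 80%-120% of reference).
#' @param curve `"c"` or `"cs"` — which nullcline to rebuild.
#' @param c_grid optional grid forwarded to the curve constructor.
#' @param ... passed to [cs_nullcline()].
#' @return An `hpa_sweep`: list with `curves` (one `hpa_nullcline` per value)
#'   and `summary` (data frame of per-value descriptors).
#' @export
nullcline_sweep <- function(params, target, values, curve = c("c", "cs"),
                            c_grid = NULL, ...) {
  stopifnot(inherits(params, "hpa_params"))
  curve <- match.arg(curve)
  if (!target %in% names(params))
    stop("unknown parameter '", target, "'; valid names: ",
         paste(names(params), collapse = ", "))
  if (any(values <= 0)) stop("sweep values must be positive")
  curves <- lapply(values, function(v) {
    pv <- unclass(params)
    pv[[target]] <- v
    pv <- structure(pv, class = "hpa_params")
    validate_params(pv)
    if (curve == "c") {
      if (is.null(c_grid)) c_nullcline(pv) else c_nullcline(pv, c_grid)
    } else {
      if (is.null(c_grid)) cs_nullcline(pv, ...) else cs_nullcline(pv, c_grid, ...)
    }
  })
  summ <- do.call(rbind, lapply(seq_along(values), function(i) {
    s <- nullcline_summary(curves[[i]])
    cbind(data.frame(value = values[i]), s)
  }))
  structure(list(target = target, curve = curve, values = values,
                 curves = curves, summary = summ),
            class = "hpa_sweep")
}

#' Scalar descriptors of a nullcline curve
#'
#' For a c-nullcline: knee coordinates and branch extents. For a
#' cs-nullcline: the oscillatory c-range and the cs-range of its oscillatory
#' (period-averaged) segment. These are the quantities whose direction of
#' motion under parameter changes characterizes the model's parameter
#' dependencies.
#'
#' @param curve an `hpa_nullcline`.
#' @return A one-row data frame.
#' @export
nullcline_summary <- function(curve) {
  stopifnot(inherits(curve, "hpa_nullcline"))
  if (attr(curve, "which") == "c") {
    kn <- attr(curve, "knees")
    folded <- nrow(kn) >= 2
    data.frame(
      folded = folded,
      knee_lower_cs = if (folded) kn$cs[1] else NA_real_,
      knee_lower_c = if (folded) kn$c[1] else NA_real_,
      knee_upper_cs = if (folded) kn$cs[nrow(kn)] else NA_real_,
      knee_upper_c = if (folded) kn$c[nrow(kn)] else NA_real_,
      c_max = max(curve$c),
      cs_at_cmax = curve$cs[which.max(curve$c)],
      upper_branch_c_mid = {
        # c on the upper branch at the cs midway between the knees
        if (folded) {
          cs_mid <- mean(range(kn$cs))
          ub <- curve[curve$branch == "upper", ]
          ub$c[which.min(abs(ub$cs - cs_mid))]
        } else NA_real_
      })
  } else {
    osc <- curve$oscillatory
    data.frame(
      osc_c_min = if (any(osc)) min(curve$c[osc]) else NA_real_,
      osc_c_max = if (any(osc)) max(curve$c[osc]) else NA_real_,
      osc_c_len = if (any(osc)) diff(range(curve$c[osc])) else 0,
      osc_cs_mean = if (any(osc)) mean(curve$cs[osc]) else NA_real_,
      cs_mean = mean(curve$cs))
  }
}

#' @export
print.hpa_sweep <- function(x, ...) {
  cat(sprintf("<hpa_sweep> %s-nullcline, %s in {%s}\n", x$curve, x$target,
              paste(signif(x$values, 4), collapse = ", ")))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
plot.hpa_nullcline <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    graphics::plot(x$cs, x$c, type = "l", col = col,
                   xlab = "stored CRH (cs)", ylab = "circulating CRH (c)", ...)
  } else {
    graphics::lines(x$cs, x$c, col = col, ...)
  }
  invisible(x)
}

#' Export nullclines and fixed points
#'
#' Curves go to CSV (one row per sample); knees and fixed points to JSON.
#'
#' @param curve an `hpa_nullcline`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nullcline_csv <- function(curve, path) {
  stopifnot(inherits(curve, "hpa_nullcline"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nullcline_csv
#' @param fixed_points an `hpa_fixed_points`.
#' @export
write_fixed_points_json <- function(fixed_points, path) {
  stopifnot(inherits(fixed_points, "hpa_fixed_points"))
  obj <- list(fixed_points = as.data.frame(fixed_points),
              degenerate = attr(fixed_points, "degenerate"))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}
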