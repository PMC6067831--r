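#!/usr/bin/env Rscript
# Calibration of the two stored-CRH constants (c_inf_bar, t_c) that the
# reference parameter set does not fix.
#
# Procedure (deterministic, no RNG):
#   1. The c-nullcline fold of the reference set spans cs in about
#      [0.65, 0.88]; the gap between the closed-form c-nullcline and the
#      period-averaged synthesis term <exp(-b o)>(c) shows that any
#      c_inf_bar in about (0.16, 0.33) yields three intersections.
#      c_inf_bar = 0.25 centres the cs-nullcline in that window, giving
#      well-separated normal / diseased states.
#   2. t_c sets how far the stored-CRH pool drifts during the 9-h
#      dexamethasone suppression window. Scanning t_c shows a sharp change
#      below ~120: the diseased state slides past the lower knee and the
#      suppression ordering s_D > s_N is lost. t_c = 150 sits above that
#      threshold while keeping relaxation experiments tractable.
#
# Running this script reproduces the scan and prints the chosen defaults,
# which are recorded in hpa_params().

library(hpaxis)

cat("c_inf_bar window giving three intersections\n")
p0 <- hpa_params(c_inf_bar = 1)  # placeholder; gap computed relative to it
cs_curve <- cs_nullcline(p0, c_grid = seq(10, 36, by = 1))
gap <- c_nullcline_cs(cs_curve$c, p0) - (cs_curve$cs - p0[["c_inf_bar"]])
ok <- is.finite(gap)
cat(sprintf("  local max of gap: %.3f, local min: %.3f -> window (%.3f, %.3f)\n",
            max(gap[ok]), min(gap[ok & cs_curve$c > 20 & cs_curve$c < 31]),
            min(gap[ok & cs_curve$c > 20 & cs_curve$c < 31]), max(gap[ok])))

cat("\nDST suppression versus t_c at c_inf_bar = 0.25\n")
for (tc in c(80, 120, 150, 300)) {
  p <- hpa_params(c_inf_bar = 0.25, t_c = tc)
  fps <- find_fixed_points(p)
  rn <- run_dex_test(p, "normal", fixed_points = fps)
  rd <- run_dex_test(p, "diseased", fixed_points = fps)
  cat(sprintf("  t_c = %4d: s_N = %.1f%%  s_D = %.1f%%  (ordering %s)\n",
              tc, rn$s, rd$s, ifelse(rd$s > rn$s, "ok", "inverted")))
}

cat("\nchosen defaults: c_inf_bar = 0.25, t_c = 150\n")
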