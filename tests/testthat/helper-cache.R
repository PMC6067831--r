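# Shared, lazily computed fixtures. Test files in one run share the session,
# so expensive objects (fixed points, ACTH baselines) are built once.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

ref_params <- function() hpa_params()

ref_fixed_points <- function() {
  cached("fps_ref", find_fixed_points(ref_params()))
}

ref_dex <- function(basin, mode = "period_averaged") {
  key <- paste0("dex_", basin, "_", mode)
  cached(key, run_dex_test(ref_params(), basin,
                           dst_protocol(measurement_mode = mode),
                           fixed_points = ref_fixed_points()))
}

ref_acth_sweep <- function(reactivity) {
  key <- paste0("acth_sweep_", reactivity)
  cached(key, phase_sweep_acth(ref_params(), reactivity, n_phases = 16))
}

# a generic mid-basin state used as integration seed in solver tests
seed_state <- function() {
  hpa_state(cs = 0.7, c = 20, a = 1, r = 0.4, o = 1)
}
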