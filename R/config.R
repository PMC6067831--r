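#' Load a run configuration
#'
#' Reads a YAML configuration with up to four sections — `parameters`
#' (flat key-value overrides of [hpa_params()], keys named after the model
#' symbols), `solver` (`step`), `protocol` (`kind` plus the fields of
#' [dst_protocol()] / [acth_protocol()] or the two-stage settings), and
#' `output` (`prefix`) — merges it over the package defaults, and validates
#' it. Unknown sections or keys are rejected by name. An empty file yields
#' the pure reference configuration. Runs are seedless: a resolved
#' configuration reproduces its run bit-for-bit.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param overrides a named list merged on top of the file (CLI flags),
#'   using `section.key` names, e.g. `list("parameters.q0" = 33.6)`.
#' @return An object of class `hpa_config`: list with elements `parameters`
#'   (an `hpa_params`), `solver`, `protocol`, `output`.
#' @examples
#' cfg <- load_config(NULL)
#' cfg$parameters[["q0"]]
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) stop("config must be a YAML mapping")
  }
  known_sections <- c("parameters", "solver", "protocol", "output")
  bad <- setdiff(names(raw), known_sections)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         "; valid sections: ", paste(known_sections, collapse = ", "))

  for (ov in names(overrides)) {
    parts <- strsplit(ov, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% known_sections)
      stop("override must be of the form section.key: ", ov)
    raw[[parts[1]]][[parts[2]]] <- overrides[[ov]]
  }

  pdef <- unclass(hpa_params())
  pars <- raw$parameters %||% list()
  badp <- setdiff(names(pars), names(pdef))
  if (length(badp))
    stop("unknown parameter key(s): ", paste(badp, collapse = ", "))
  for (nm in names(pars)) {
    v <- pars[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter ", nm, " must be a single finite number")
    pdef[[nm]] <- v
  }
  params <- structure(pdef, class = "hpa_params")
  validate_params(params)  # names the offending key on violation

  solver <- list(step = 0.01)
  sv <- raw$solver %||% list()
  bads <- setdiff(names(sv), names(solver))
  if (length(bads)) stop("unknown solver key(s): ", paste(bads, collapse = ", "))
  solver[names(sv)] <- sv
  if (!is.numeric(solver$step) || solver$step <= 0)
    stop("solver key step must be a positive number")

  proto_def <- list(kind = "dst", basin = "normal",
                    dose_height = 2, dose_width = minutes_to_dimensionless(30),
                    post_delay = minutes_to_dimensionless(540),
                    measurement_mode = "period_averaged",
                    equilibration = 150,
                    adrenal_reactivity = 1, phase_at_dose = 0, n_phases = 16,
                    stressor_amplitude = 0.5,
                    stressor_start = minutes_to_dimensionless(540),
                    stressor_duration = minutes_to_dimensionless(60),
                    t_end = 100)
  pr <- raw$protocol %||% list()
  badk <- setdiff(names(pr), names(proto_def))
  if (length(badk))
    stop("unknown protocol key(s): ", paste(badk, collapse = ", "))
  protocol <- proto_def
  protocol[names(pr)] <- pr
  if (!protocol$kind %in% c("dst", "acth", "two_stage", "simulate"))
    stop("protocol key kind must be one of dst, acth, two_stage, simulate")
  if (!protocol$basin %in% c("normal", "diseased"))
    stop("protocol key basin must be normal or diseased")

  output <- list(prefix = "hpaxis_run")
  out <- raw$output %||% list()
  bado <- setdiff(names(out), names(output))
  if (length(bado)) stop("unknown output key(s): ", paste(bado, collapse = ", "))
  output[names(out)] <- out

  structure(list(parameters = params, solver = solver, protocol = protocol,
                 output = output), class = "hpa_config")
}

#' @rdname load_config
#' @param config an `hpa_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "hpa_config"))
  obj <- list(parameters = as.list(unclass(config$parameters)),
              solver = config$solver,
              protocol = config$protocol,
              output = config$output)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @export
print.hpa_config <- function(x, ...) {
  cat("<hpa_config> protocol:", x$protocol$kind, "| basin:",
      x$protocol$basin, "| step:", x$solver$step, "\n")
  invisible(x)
}

#' Ready-made scenario configurations
#'
#' Named fixtures encoding the standard study scenarios:
#'
#' * `bistable_reference` — the reference parameter set (bistable; three
#'   nullcline intersections).
#' * `monostable_low_n` — Hill coefficient `n = 4`, below the saddle-node:
#'   monotone c-nullcline, single intersection.
#' * `dst_normal` / `dst_diseased` — the dexamethasone suppression test from
#'   either basin (identical parameters; they differ only in basin).
#' * `acth_hypo` — cosyntropin stimulation with 10% reduced adrenal
#'   reactivity.
#' * `two_stage` — dexamethasone followed by a 60-min `Iext = 0.5` stressor
#'   9 h post-dose.
#'
#' @param name one of the fixture names above.
#' @return An `hpa_config`.
#' @examples
#' make_fixture("monostable_low_n")$parameters[["n"]]
#' @export
make_fixture <- function(name) {
  fixtures <- c("bistable_reference", "monostable_low_n", "dst_normal",
                "dst_diseased", "acth_hypo", "two_stage")
  if (!is.character(name) || length(name) != 1 || !name %in% fixtures)
    stop("unknown fixture; valid names: ", paste(fixtures, collapse = ", "))
  switch(name,
    bistable_reference = load_config(NULL,
      list("protocol.kind" = "simulate")),
    monostable_low_n = load_config(NULL,
      list("parameters.n" = 4, "protocol.kind" = "simulate")),
    dst_normal = load_config(NULL,
      list("protocol.kind" = "dst", "protocol.basin" = "normal")),
    dst_diseased = load_config(NULL,
      list("protocol.kind" = "dst", "protocol.basin" = "diseased")),
    acth_hypo = load_config(NULL,
      list("protocol.kind" = "acth", "protocol.adrenal_reactivity" = 0.9,
           "protocol.dose_height" = 14)),
    two_stage = load_config(NULL,
      list("protocol.kind" = "two_stage")))
}

#' Execute a configured run
#'
#' Dispatches on the configuration's protocol kind, writes the resolved
#' configuration next to the outputs, and returns the protocol result. This
#' is the engine behind the command-line interface.
#'
#' @param config an `hpa_config`.
#' @param out_dir directory for outputs (created if missing); `NULL` writes
#'   nothing.
#' @return The protocol result object, invisibly for `simulate`.
#' @export
run_config <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "hpa_config"))
  params <- config$parameters
  pr <- config$protocol
  emit <- function(result, traj) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prefix <- file.path(out_dir, config$output$prefix)
    write_config(config, paste0(prefix, "_config.yaml"))
    if (!is.null(traj)) write_trajectory(traj, paste0(prefix, "_trajectory.csv"))
    if (!is.null(result))
      writeLines(jsonlite::toJSON(result, auto_unbox = TRUE, digits = NA,
                                  na = "null", force = TRUE),
                 paste0(prefix, "_summary.json"))
    invisible(NULL)
  }

  if (pr$kind == "simulate") {
    fps <- find_fixed_points(params)
    i <- pick_basin(fps, pr$basin)
    cyc <- attr(fps, "cycles")[[i]]
    init <- hpa_state(cs = fps$cs[i], c = fps$c[i], a = cyc$state[["a"]],
                      r = cyc$state[["r"]], o = cyc$state[["o"]])
    tr <- hpa_integrate(params, init, c(0, pr$t_end), step = config$solver$step)
    emit(NULL, tr)
    return(invisible(tr))
  }
  if (pr$kind == "dst") {
    res <- run_dex_test(params, pr$basin,
                        dst_protocol(dose_height = pr$dose_height,
                                     dose_width = pr$dose_width,
                                     post_delay = pr$post_delay,
                                     measurement_mode = pr$measurement_mode,
                                     equilibration = pr$equilibration,
                                     step = config$solver$step))
    emit(res[c("s", "pre_o", "post_o", "delta_fa", "pre_amplitude",
               "post_amplitude", "period", "basin", "measurement_mode")],
         res$trajectory)
    return(res)
  }
  if (pr$kind == "acth") {
    res <- run_acth_test(params, pr$adrenal_reactivity, pr$phase_at_dose,
                         acth_protocol(dose_height = pr$dose_height,
                                       dose_width = pr$dose_width,
                                       equilibration = pr$equilibration,
                                       step = config$solver$step),
                         basin = pr$basin)
    emit(res[c("peak_o", "baseline_mean_o", "baseline_max_o",
               "peak_o_model", "baseline_mean_o_model", "phase_at_dose",
               "reactivity", "period")],
         res$trajectory)
    return(res)
  }
  # two-stage
  res <- run_two_stage_test(params,
                            dst_protocol(dose_height = pr$dose_height,
                                         dose_width = pr$dose_width,
                                         equilibration = pr$equilibration,
                                         step = config$solver$step),
                            stressor_amplitude = pr$stressor_amplitude,
                            stressor_start = pr$stressor_start,
                            stressor_duration = pr$stressor_duration)
  emit(res$summary, res$runs[[1]]$trajectory)
  res
}
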