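#' Validate a run configuration
#'
#' A run configuration names the task, the kinetic parameter set (plus
#' overrides), the grid, the schedule and the output directory; every run
#' writes the fully resolved configuration next to its results so any
#' output can be regenerated from its manifest.  All randomness flows from
#' the single `seed` field.
#'
#' @param config named list, or path to a YAML file.
#' @return validated config of class `min_run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("task", "param_set", "overrides", "ratio", "v_f", "grid",
             "schedule", "seed", "out_dir", "ratios", "v_fs", "q_max",
             "n_q", "stack", "stack_path", "pixel_size", "interval",
             "flow_angle", "t_relax", "t_measure", "path", "control")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  tasks <- c("simulate", "dispersion", "phasediagram", "hysteresis",
             "ablation", "synth", "analyze")
  if (is.null(config$task) || !config$task %in% tasks)
    stop("config$task must be one of: ", paste(tasks, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$param_set)) config$param_set <- "invitro_switch_v1"
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  structure(config, class = "min_run_config")
}

.config_params <- function(config) {
  over <- config$overrides
  if (is.null(over)) over <- list()
  if (!is.null(config$v_f)) over$v_f <- config$v_f
  p <- do.call(min_param_set, c(list(name = config$param_set), over))
  if (!is.null(config$ratio)) p$n_E_mean <- config$ratio * p$n_D_mean
  p
}

.config_grid <- function(config) {
  g <- config$grid
  if (is.null(g)) g <- list(L = 200, N = 256)
  min_grid(g$L, g$N)
}

.config_schedule <- function(config) {
  s <- config$schedule
  if (is.null(s)) s <- list()
  min_schedule(dt = s$dt %||% 0.02, t_end = s$t_end %||% 600,
               save_every = s$save_every %||% 250L, seed = config$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured pipeline stage
#'
#' Dispatches a validated configuration to the corresponding stage
#' (simulation, dispersion relation, phase diagram, hysteresis sweep, MinE
#' advection ablation, synthetic stack generation, or crest analysis) and
#' writes its outputs plus the resolved configuration under
#' `config$out_dir`.
#'
#' @param config a `min_run_config` (or anything [run_config()] accepts).
#' @return the stage result, invisibly; side effect: files in `out_dir`.
#' @export
run <- function(config) {
  config <- run_config(unclass(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config),
                   file.path(config$out_dir, "config_resolved.yaml"))
  res <- switch(config$task,
    simulate = .run_simulate(config),
    dispersion = .run_dispersion(config),
    phasediagram = .run_phasediagram(config),
    hysteresis = .run_hysteresis(config),
    ablation = .run_ablation(config),
    synth = .run_synth(config),
    analyze = .run_analyze(config))
  invisible(res)
}

.run_simulate <- function(config) {
  p <- .config_params(config); g <- .config_grid(config)
  sc <- .config_schedule(config)
  init <- noisy_homogeneous_state(p, g, seed = config$seed)
  tr <- simulate_min(init, p, g, sc)
  k <- kymograph(tr)
  kn <- (k - min(k)) / max(diff(range(k)), .Machine$double.eps)
  tiff::writeTIFF(kn, file.path(config$out_dir, "kymograph.tif"),
                  bits.per.sample = 16L)
  utils::write.csv(data.frame(t = tr$times, tr$conservation),
                   file.path(config$out_dir, "conservation.csv"),
                   row.names = FALSE)
  pv <- pattern_velocity(tr)
  jsonlite::write_json(pv, file.path(config$out_dir, "measurement.json"),
                       auto_unbox = TRUE, digits = NA)
  tr
}

.run_dispersion <- function(config) {
  p <- .config_params(config)
  qs <- seq(1e-3, config$q_max %||% 1.5, length.out = config$n_q %||% 200)
  d <- dispersion_relation(p, qs)
  utils::write.csv(data.frame(q = d$q, re_sigma = Re(d$sigma),
                              im_sigma = Im(d$sigma)),
                   file.path(config$out_dir, "dispersion.csv"),
                   row.names = FALSE)
  jsonlite::write_json(instability_bands(d),
                       file.path(config$out_dir, "bands.json"),
                       auto_unbox = TRUE, digits = NA)
  d
}

.run_phasediagram <- function(config) {
  p <- .config_params(config); g <- .config_grid(config)
  pd <- phase_diagram(p, g, config$ratios %||% c(0.05, 0.3, 1),
                      config$v_fs %||% c(1, 3), seed = config$seed)
  utils::write.csv(pd, file.path(config$out_dir, "phase_diagram.csv"),
                   row.names = FALSE)
  pd
}

.run_hysteresis <- function(config) {
  p <- .config_params(config); g <- .config_grid(config)
  path <- config$path %||% seq(0.5, 4, by = 0.5)
  up <- adiabatic_sweep(p, g, config$control %||% "v_f", path,
                        t_relax = config$t_relax %||% 400,
                        t_measure = config$t_measure %||% 400,
                        seed = config$seed)
  down <- adiabatic_sweep(p, g, config$control %||% "v_f", rev(path),
                          init = attr(up, "final_state"),
                          t_relax = config$t_relax %||% 400,
                          t_measure = config$t_measure %||% 400,
                          seed = config$seed)
  up$direction_of_sweep <- "up"; down$direction_of_sweep <- "down"
  out <- rbind(up, down)
  utils::write.csv(out, file.path(config$out_dir, "hysteresis.csv"),
                   row.names = FALSE)
  out
}

.run_ablation <- function(config) {
  p <- .config_params(config); g <- .config_grid(config)
  ab <- minE_advection_ablation(p, g, seed = config$seed)
  utils::write.csv(ab, file.path(config$out_dir, "ablation.csv"),
                   row.names = FALSE)
  ab
}

.run_synth <- function(config) {
  sp <- do.call(synthetic_stack_spec,
                c(config$stack %||% list(), list(seed = config$seed)))
  gen <- switch(sp$kind, planar = planar_wave_stack(sp),
                spiral = spiral_stack(sp), static = static_stack(sp))
  write_stack_tiff(gen$stack, file.path(config$out_dir, "stack.tif"))
  truth <- gen$truth; truth$aggregate_mask <- NULL
  jsonlite::write_json(truth, file.path(config$out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  gen
}

.run_analyze <- function(config) {
  if (is.null(config$stack_path)) stop("config$stack_path is required")
  st <- read_stack_tiff(config$stack_path,
                        pixel_size = config$pixel_size %||% 2,
                        interval = config$interval %||% 15,
                        flow_angle = config$flow_angle %||% 0)
  res <- analyze_crests(st)
  utils::write.csv(res$records,
                   file.path(config$out_dir, "crest_velocities.csv"),
                   row.names = FALSE)
  s <- res$summary
  jsonlite::write_json(list(n = s$n,
                            downstream_fraction = s$downstream_fraction,
                            upstream_fraction = s$upstream_fraction,
                            peak_speed = s$peak_speed, fwhm = s$fwhm,
                            low_confidence = s$low_confidence),
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(s$angular,
                   file.path(config$out_dir, "angular_histogram.csv"),
                   row.names = FALSE)
  res
}
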