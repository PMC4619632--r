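#' Canonical experiment presets
#'
#' Named run configurations reproducing the package's reference
#' experiments: the ring-model bump construction (`fig5_ring`), the
#' coupled 1D traveling wave and its feedforward-ablation variant
#' (`fig6_wave`, `fig7_ablation`), the 2D plane- and target-wave
#' experiments with anisotropic or isotropic horizontal connections
#' (`fig9_plane_aniso`, `fig9_plane_iso`, `fig10_target_aniso`,
#' `fig10_target_iso`), and the exponential-kernel Heaviside front used
#' for closed-form speed checks (`heaviside_theory`).
#'
#' The 1D presets carry the canonical coupled parameter set (Gaussian
#' kernels of mass 2 and 0.1, ring kernel `w0 = -1`, `w1 = 2`,
#' thresholds 0.5, couplings 1, time constants 0.1, sigmoid gain 10);
#' the 2D presets reuse it with domain sizes adapted to each
#' experiment (see the package vignette for the reasoning).
#'
#' @param name optional preset name; omit to get the full named list.
#' @return A run-config list (or list of them): fields `name`,
#'   `experiment`, `params`, `grid`, initial-condition settings, `T`,
#'   `snapshot_times`, `ablations`, `noise_amplitude`, `noise_seed`.
#' @examples
#' names(fixtures())
#' fixtures("fig6_wave")$params$w_d0
#' @export
fixtures <- function(name = NULL) {
  p1 <- laminar_params(w_d0 = 2, sigma_d = 0.1, w_s0 = 0.1, sigma_s = 1,
                       w0 = -1, w1 = 2, kappa_d = 0.5, kappa_s = 0.5,
                       gamma_d = 1, gamma_s = 1, tau_d = 0.1, tau_s = 0.1,
                       eta_d = 10, eta_s = 10, rate_mode = "sigmoid",
                       kernel_d = "gaussian", kernel_s = "gaussian")
  g1 <- list(dim = 1L, extent = 12, nx = 1200, ntheta = 100, dt = 0.001,
             x0 = 0)
  p2a <- p1; p2a$anisotropy <- "cosine"
  p2i <- p1; p2i$anisotropy <- "isotropic"
  fx <- list(
    fig5_ring = list(
      name = "fig5_ring", experiment = "theory_report",
      params = laminar_params(w0 = -2, w1 = 8, w_s0 = 0,
                              kappa_s = 0.5, gamma_d = 1)),
    fig6_wave = list(
      name = "fig6_wave", experiment = "laminar_1d",
      params = p1, grid = g1, x0 = 2, v_mode = "bump", T = 1.5,
      snapshot_times = c(0.5, 1), ablations = list(),
      noise_amplitude = 0, noise_seed = 1L),
    fig7_ablation = list(
      name = "fig7_ablation", experiment = "laminar_1d",
      params = p1, grid = g1, x0 = 2, v_mode = "bump", T = 2,
      snapshot_times = c(0.9, 1.1, 1.5),
      ablations = list(list(time = 1, set = list(gamma_d = 0))),
      noise_amplitude = 0, noise_seed = 1L),
    fig9_plane_aniso = list(
      name = "fig9_plane_aniso", experiment = "plane_2d",
      params = p2a,
      grid = list(dim = 2L, extent = 7.5, nx = 96, ny = 96, ntheta = 24,
                  dt = 0.002),
      x0 = -0.5, T = 1.2, snapshot_times = NULL, ablations = list(),
      noise_amplitude = 1e-4, noise_seed = 1L),
    fig9_plane_iso = list(
      name = "fig9_plane_iso", experiment = "plane_2d",
      params = p2i,
      grid = list(dim = 2L, extent = 2.56, nx = 48, ny = 48, ntheta = 16,
                  dt = 0.004),
      x0 = -0.5, T = 8, snapshot_times = NULL, ablations = list(),
      noise_amplitude = 1e-4, noise_seed = 1L),
    fig10_target_aniso = list(
      name = "fig10_target_aniso", experiment = "target_2d",
      params = p2a,
      grid = list(dim = 2L, extent = 4, nx = 64, ny = 64, ntheta = 24,
                  dt = 0.002),
      r0 = 0.1, T = 1.2, snapshot_times = NULL, ablations = list(),
      noise_amplitude = 1e-4, noise_seed = 1L),
    fig10_target_iso = list(
      name = "fig10_target_iso", experiment = "target_2d",
      params = p2i,
      grid = list(dim = 2L, extent = 2.56, nx = 48, ny = 48, ntheta = 16,
                  dt = 0.004),
      r0 = 0.1, T = 8, snapshot_times = NULL, ablations = list(),
      noise_amplitude = 1e-4, noise_seed = 1L),
    heaviside_theory = list(
      name = "heaviside_theory", experiment = "deep_front",
      params = laminar_params(w_d0 = 2, sigma_d = 1, kappa_d = 0.5,
                              tau_d = 1, w_s0 = 0, rate_mode = "heaviside",
                              kernel_d = "exponential"),
      grid = list(dim = 1L, extent = 30, nx = 1500, ntheta = 10,
                  dt = 0.005, x0 = 0),
      x0 = 8, T = 6, snapshot_times = NULL, ablations = list(),
      noise_amplitude = 0, noise_seed = 1L))
  if (is.null(name)) return(fx)
  if (!name %in% names(fx))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fx), collapse = ", "), call. = FALSE)
  fx[[name]]
}

# Rebuild a laminar_grid from its serialized argument list.
grid_from_config <- function(gc) {
  if (gc$dim == 1L)
    grid_1d(extent = gc$extent, nx = gc$nx, ntheta = gc$ntheta,
            dt = gc$dt, x0 = if (is.null(gc$x0)) 0 else gc$x0)
  else
    grid_2d(extent = gc$extent, nx = gc$nx,
            ny = if (is.null(gc$ny)) gc$nx else gc$ny,
            ntheta = gc$ntheta, dt = gc$dt)
}

#' Run a configured experiment
#'
#' Dispatches a run configuration (from [fixtures()] or
#' [read_run_config()]) to the appropriate engine: the closed-form
#' theory report, the scalar deep-layer front, the coupled 1D model, or
#' a 2D plane/target wave.
#'
#' @param config a run-config list.
#' @return The engine's result (`theory_report` data frame,
#'   `run_deep` list, `sim_result_1d` or `sim_result_2d`), with the
#'   config attached as attribute `"config"`.
#' @export
run_experiment <- function(config) {
  params <- do.call(laminar_params, unclass_params(config$params))
  res <- switch(
    config$experiment,
    theory_report = theory_report(params),
    deep_front = {
      grid <- grid_from_config(config$grid)
      run_deep(params, grid, x0 = config$x0, T = config$T)
    },
    laminar_1d = {
      grid <- grid_from_config(config$grid)
      init <- init_front(params, grid, x0 = config$x0,
                         v_mode = if (is.null(config$v_mode)) "bump"
                                  else config$v_mode)
      run_1d(params, grid, init, T = config$T,
             snapshot_times = config$snapshot_times,
             ablations = if (is.null(config$ablations)) list()
                         else config$ablations,
             noise_amplitude = config$noise_amplitude %||% 0,
             noise_seed = config$noise_seed %||% 1L)
    },
    plane_2d = ,
    target_2d = {
      grid <- grid_from_config(config$grid)
      init <- if (config$experiment == "plane_2d")
        init_plane(params, grid, x0 = config$x0)
      else
        init_target(params, grid, r0 = config$r0)
      run_2d(params, grid, init, T = config$T,
             snapshot_times = config$snapshot_times,
             noise_amplitude = config$noise_amplitude %||% 0,
             noise_seed = config$noise_seed %||% 1L)
    },
    stop("unknown experiment '", config$experiment, "'", call. = FALSE))
  attr(res, "config") <- config
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_params <- function(p) {
  p <- unclass(p)
  p[names(p) %in% names(formals(laminar_params))]
}

#' Read and write run configurations as JSON
#'
#' Configurations round-trip losslessly through JSON; reading validates
#' the parameter block with [laminar_params()] (so missing or invalid
#' entries produce itemized errors) and the grid block with the grid
#' constructors.
#'
#' @param config a run-config list.
#' @param path file path.
#' @return `read_run_config` returns the validated config;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  config$params <- unclass_params(config$params)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  required <- c("experiment", "params")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  # a stored config must be complete: no silent default filling
  par_missing <- setdiff(names(formals(laminar_params)),
                         names(cfg$params))
  if (length(par_missing))
    stop("config parameter block is missing: ",
         paste(par_missing, collapse = ", "), call. = FALSE)
  cfg$params <- do.call(laminar_params, unclass_params(cfg$params))
  if (!is.null(cfg$grid)) {
    cfg$grid <- lapply(cfg$grid, function(x) x)  # plain list
    cfg$grid$dim <- as.integer(cfg$grid$dim)
    grid_from_config(cfg$grid)  # validation only
  }
  if (!is.null(cfg$ablations))
    cfg$ablations <- lapply(cfg$ablations, function(a)
      list(time = a$time, set = as.list(a$set)))
  cfg
}

#' Persist and reload simulation results
#'
#' `save_result` writes a result directory: the full result object in R
#' native serialization (`result.rds`, lossless and bit-exact), the
#' resolved configuration as JSON when available (`config.json`), and
#' the interface trajectory as `summary.csv`. `load_result` reads it
#' back and verifies completeness.
#'
#' @param result a result from [run_experiment()], [run_1d()],
#'   [run_2d()] or [run_deep()].
#' @param dir output directory (created if needed).
#' @return `save_result` returns `dir` invisibly; `load_result` returns
#'   the result object.
#' @export
save_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(result, file.path(dir, "result.rds"))
  cfg <- attr(result, "config")
  if (!is.null(cfg)) write_run_config(cfg, file.path(dir, "config.json"))
  if (!is.null(result$trajectory))
    utils::write.csv(result$trajectory, file.path(dir, "summary.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname save_result
#' @export
load_result <- function(dir) {
  rds <- file.path(dir, "result.rds")
  if (!file.exists(rds))
    stop("no result.rds in '", dir, "' (missing or corrupt result)",
         call. = FALSE)
  res <- tryCatch(readRDS(rds), error = function(e)
    stop("corrupt result file in '", dir, "': ", conditionMessage(e),
         call. = FALSE))
  res
}
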