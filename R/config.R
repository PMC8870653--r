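# Plain hierarchical (JSON) serialization for scenes, scenarios and
# experiment configurations; the manifest written by a run is built from
# the same representation, so a run is reproducible from its manifest.

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @rdname save_config
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- strip_class(unclass(config))
  out$conditions <- lapply(config$conditions, function(cn)
    list(label = cn$label, concentration_ug_per_ml =
           cn$concentration_ug_per_ml, control = cn$control,
         scenario = strip_class(unclass(cn$scenario))))
  out
}

#' @rdname save_config
#' @export
config_from_list <- function(x) {
  conds <- lapply(x$conditions, function(cn)
    condition_arm(cn$label,
                  do.call(scenario_spec, cn$scenario),
                  concentration_ug_per_ml = cn$concentration_ug_per_ml,
                  control = isTRUE(cn$control)))
  experiment_config(
    conditions = conds,
    n_positions = x$n_positions %||% 4L,
    n_experiments = x$n_experiments %||% 3L,
    times_h = unlist(x$times_h %||% seq(0, 24, 0.5)),
    mode = x$mode %||% "series",
    optical = do.call(optical_config, x$optical %||% list()),
    recon = do.call(recon_params, x$recon %||% list()),
    background = do.call(background_params, x$background %||% list()),
    drymass = do.call(drymass_params, {
      dp <- x$drymass %||% list()
      # jsonlite serializes a NULL S_FOV as an empty object; drop it
      if (!is.null(dp$s_fov_um2) && !is_scalar_num(dp$s_fov_um2))
        dp$s_fov_um2 <- NULL
      dp
    }),
    grid = do.call(scene_grid, x$grid %||% list()),
    n_cells = x$n_cells %||% 90L,
    m0_ng = x$m0_ng %||% 25, m0_sd_ng = x$m0_sd_ng %||% 2,
    measurement_sd_ng = x$measurement_sd_ng %||% 0.5,
    seed = x$seed %||% 1L,
    outdir = if (is.character(x$outdir)) x$outdir else NULL,
    write_holograms = isTRUE(x$write_holograms),
    write_phase = isTRUE(x$write_phase),
    write_plots = isTRUE(x$write_plots))
}

#' Save / load an experiment configuration as JSON
#'
#' @param config an [experiment_config()].
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the reconstructed [experiment_config()].
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: %s", path)
  x <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                error = function(e)
                  stop_config("malformed config JSON: %s",
                              conditionMessage(e)))
  config_from_list(x)
}

#' Save / load a scene as JSON
#'
#' @param scene a `dhm_scene`.
#' @param path JSON file path.
#' @return `save_scene` returns `path` invisibly; `load_scene` the
#'   reconstructed scene.
#' @export
save_scene <- function(scene, path) {
  stopifnot(inherits(scene, "dhm_scene"))
  x <- list(n_medium = scene$n_medium,
            grid = strip_class(unclass(scene$grid)),
            cells = lapply(scene$cells, strip_class),
            debris = lapply(scene$debris, strip_class))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_scene
#' @export
load_scene <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  as_cell <- function(cl)
    phantom_cell(unlist(cl$center), cl$footprint_radius_um,
                 cl$thickness_um, cl$n_cell, cl$profile)
  scene(cells = lapply(x$cells, as_cell),
        grid = do.call(scene_grid, x$grid),
        n_medium = x$n_medium,
        debris = lapply(x$debris, as_cell))
}
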