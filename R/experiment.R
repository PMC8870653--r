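# Seeded end-to-end "virtual experiment": plate layout of conditions,
# n positions (FOVs) per well across N independent experiments, a
# dry-mass time course per FOV and endpoint statistics per condition.

#' Define one condition arm
#'
#' @param label condition label (e.g. "medium control", "lysis 32").
#' @param scenario a [scenario_spec()] describing the population dynamics
#'   of this arm.
#' @param concentration_ug_per_ml nominal agent concentration.
#' @param control whether this arm is the medium control (exactly one
#'   arm per experiment must be).
#' @return a `condition_arm` list.
#' @export
condition_arm <- function(label, scenario,
                          concentration_ug_per_ml = 0, control = FALSE) {
  stopifnot(inherits(scenario, "scenario_spec"))
  structure(list(label = label, scenario = scenario,
                 concentration_ug_per_ml = concentration_ug_per_ml,
                 control = isTRUE(control)),
            class = "condition_arm")
}

#' Configure a virtual experiment
#'
#' Defaults mirror the assay layout: n = 4 measurement positions per
#' well, N = 3 independent experiments, acquisitions every 30 min for
#' 24 h (49 timepoints), 15 hologram frames per position and timepoint.
#'
#' @param conditions list of [condition_arm()]s; exactly one must be the
#'   medium control.
#' @param n_positions FOVs per well (n).
#' @param n_experiments independent experiments (N).
#' @param times_h acquisition times (h), strictly increasing in [0, 24].
#' @param mode fidelity of the simulation: `"series"` draws dry-mass
#'   series directly from the scenario laws plus measurement noise (fast;
#'   used for endpoint-statistics studies), `"phantom"` renders phase
#'   maps and quantifies them without holography, `"full"` runs the whole
#'   hologram/reconstruction/background chain per timepoint.
#' @param optical,recon,background,drymass stage parameter objects.
#' @param grid scene raster for phantom/full modes.
#' @param n_cells cells per FOV in phantom/full modes.
#' @param m0_ng mean initial population dry mass per FOV (ng).
#' @param m0_sd_ng FOV-to-FOV std of the initial mass (series mode).
#' @param measurement_sd_ng per-timepoint measurement noise (series mode).
#' @param seed master seed; the whole run is a pure function of it.
#' @param outdir output directory (NULL = return results only).
#' @param write_holograms,write_phase,write_plots optional artifacts.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(conditions,
                              n_positions = 4L, n_experiments = 3L,
                              times_h = seq(0, 24, by = 0.5),
                              mode = c("series", "phantom", "full"),
                              optical = optical_config(),
                              recon = recon_params(),
                              background = background_params(),
                              drymass = drymass_params(),
                              grid = scene_grid(),
                              n_cells = 70L,
                              m0_ng = 25, m0_sd_ng = 2,
                              measurement_sd_ng = 0.5,
                              seed = 1L, outdir = NULL,
                              write_holograms = FALSE,
                              write_phase = TRUE,
                              write_plots = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.list(conditions), length(conditions) >= 1)
  for (cn in conditions)
    if (!inherits(cn, "condition_arm"))
      stop_config("conditions must be condition_arm objects")
  n_ctrl <- sum(vapply(conditions, function(cn) cn$control, logical(1)))
  if (n_ctrl != 1L)
    stop_config("exactly one condition must be the medium control (got %d)",
                n_ctrl)
  if (any(diff(times_h) <= 0) || min(times_h) < 0 || max(times_h) > 24)
    stop_config("times must be strictly increasing within [0, 24] h")
  structure(list(conditions = conditions,
                 n_positions = as.integer(n_positions),
                 n_experiments = as.integer(n_experiments),
                 times_h = times_h, mode = mode, optical = optical,
                 recon = recon, background = background, drymass = drymass,
                 grid = grid, n_cells = as.integer(n_cells),
                 m0_ng = m0_ng, m0_sd_ng = m0_sd_ng,
                 measurement_sd_ng = measurement_sd_ng,
                 seed = as.integer(seed), outdir = outdir,
                 write_holograms = isTRUE(write_holograms),
                 write_phase = isTRUE(write_phase),
                 write_plots = isTRUE(write_plots)),
            class = "experiment_config")
}

# one FOV's dry-mass series under a given fidelity mode
simulate_fov_series <- function(config, arm, seed_fov, tag = NULL) {
  times <- config$times_h
  if (config$mode == "series") {
    with_seed(seed_fov, {
      m0 <- max(1, rnorm(1, config$m0_ng, config$m0_sd_ng))
      m <- scenario_mass(arm$scenario, m0, times) +
        rnorm(length(times), 0, config$measurement_sd_ng)
      list(times = times, dm = m, phase_maps = NULL)
    })
  } else {
    sc0 <- random_scene(config$n_cells, config$grid, seed = seed_fov)
    maps <- lapply(times, function(t) {
      sct <- evolve(sc0, arm$scenario, t)
      if (config$mode == "phantom") {
        pm <- render_phase(sct, config$optical$wavelength_nm)
      } else {
        holos <- acquire_timepoint(sct, config$optical, t,
                                   seed = derive_seed(seed_fov, t * 2))
        if (config$write_holograms && !is.null(config$outdir) &&
            !is.null(tag)) {
          hdir <- file.path(config$outdir, "holograms")
          dir.create(hdir, recursive = TRUE, showWarnings = FALSE)
          write_stack(
            file.path(hdir, sprintf("%s_t%04.1f.tif", tag, t)),
            lapply(holos, function(h) h$intensity),
            metadata = list(
              pixel_pitch_um = config$optical$pixel_pitch_um,
              wavelength_nm = config$optical$wavelength_nm,
              time_h = t))
        }
        pm <- reconstruct_stack(holos, config$recon)
        pm <- rolling_ball_subtract(pm, config$background)
      }
      pm$time_h <- t
      pm
    })
    dm <- vapply(maps, dry_mass_map, numeric(1), params = config$drymass)
    list(times = times, dm = dm, phase_maps = maps)
  }
}

#' Run a virtual experiment
#'
#' Simulates every (condition, experiment, FOV) cell of the layout,
#' assembles the three result tables (time courses, per-FOV 24-h
#' increments, per-condition statistics vs the medium control with
#' Bonferroni correction over the non-control arms) and, when `outdir`
#' is set, writes them as CSV together with a machine-readable manifest.
#' Fully deterministic given the master seed.  A FOV whose simulation
#' fails is logged and excluded, never imputed.
#'
#' @param config an [experiment_config()].
#' @return (invisibly) list with `courses`, `increments`, `stats` data
#'   frames and `outdir`.
#' @export
run_virtual_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  courses <- list(); increments <- list(); failures <- character(0)
  has_endpoints <- any(abs(config$times_h - 0) < 1e-9) &&
    any(abs(config$times_h - 24) < 1e-9)
  for (ci in seq_along(config$conditions)) {
    arm <- config$conditions[[ci]]
    for (ex in seq_len(config$n_experiments)) {
      for (fov in seq_len(config$n_positions)) {
        seed_fov <- derive_seed(config$seed, ci, ex, fov)
        res <- tryCatch(
          simulate_fov_series(config, arm, seed_fov,
                              tag = sprintf("cond%d_exp%d_fov%d",
                                            ci, ex, fov)),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures, sprintf(
            "%s / experiment %d / FOV %d: %s", arm$label, ex, fov,
            conditionMessage(res)))
          next
        }
        key <- sprintf("%d_%d_%d", ci, ex, fov)
        courses[[key]] <- data.frame(
          experiment = ex, condition = arm$label,
          concentration_ug_per_ml = arm$concentration_ug_per_ml,
          fov_id = fov, time_h = res$times, dry_mass_ng = res$dm)
        if (has_endpoints) {
          ser <- dry_mass_series(res$times, res$dm, arm$label,
                                 arm$concentration_ug_per_ml, fov, ex)
          increments[[key]] <- data.frame(
            experiment = ex, condition = arm$label,
            concentration_ug_per_ml = arm$concentration_ug_per_ml,
            fov_id = fov, increment_ng = dm_increment(ser))
        }
        if (!is.null(config$outdir) && !is.null(res$phase_maps) &&
            config$write_phase) {
          dir.create(file.path(config$outdir, "phase"), recursive = TRUE,
                     showWarnings = FALSE)
          write_stack(
            file.path(config$outdir, "phase",
                      sprintf("cond%d_exp%d_fov%d.tif", ci, ex, fov)),
            lapply(res$phase_maps, function(p) p$phase),
            metadata = list(
              pixel_pitch_um = res$phase_maps[[1]]$pixel_pitch_um,
              wavelength_nm = config$optical$wavelength_nm,
              time_h = res$times,
              condition = arm$label, experiment = ex, fov_id = fov))
        }
      }
    }
  }
  for (f in failures) warning("FOV excluded: ", f)
  courses <- do.call(rbind, c(courses, list(make.row.names = FALSE)))
  increments <- if (length(increments))
    do.call(rbind, c(increments, list(make.row.names = FALSE))) else NULL

  stats_df <- NULL
  if (!is.null(increments)) {
    ctrl_label <- vapply(config$conditions, function(cn) cn$label,
                         character(1))[
      vapply(config$conditions, function(cn) cn$control, logical(1))]
    ctrl <- increments$increment_ng[increments$condition == ctrl_label]
    others <- unique(increments$condition[
      increments$condition != ctrl_label])
    rows <- lapply(others, function(lab) {
      tr <- increments$increment_ng[increments$condition == lab]
      st <- compare_conditions(tr, ctrl, n_comparisons = length(others))
      data.frame(condition = lab,
                 concentration_ug_per_ml = increments$
                   concentration_ug_per_ml[
                     increments$condition == lab][1],
                 n = length(tr), mean_ng = st$mean_treated,
                 sd_ng = st$sd_treated, t = st$t, p = st$p,
                 p_adj = st$p_adj, stars = st$stars)
    })
    ctrl_row <- data.frame(condition = ctrl_label,
                           concentration_ug_per_ml = 0,
                           n = length(ctrl), mean_ng = mean(ctrl),
                           sd_ng = sd(ctrl), t = NA_real_, p = NA_real_,
                           p_adj = NA_real_, stars = NA_character_)
    stats_df <- rbind(ctrl_row, do.call(rbind, rows))
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(courses, file.path(config$outdir, "courses.csv"),
              row.names = FALSE)
    if (!is.null(increments))
      write.csv(increments, file.path(config$outdir, "increments.csv"),
                row.names = FALSE)
    if (!is.null(stats_df))
      write.csv(stats_df, file.path(config$outdir, "stats.csv"),
                row.names = FALSE)
    manifest <- list(package = "holomass",
                     version = as.character(
                       utils::packageVersion("holomass")),
                     seed = config$seed,
                     config = config_to_list(config),
                     failures = failures)
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$write_plots) {
      grDevices::png(file.path(config$outdir, "courses.png"),
                     width = 900, height = 600)
      plot_dm_courses(courses)
      grDevices::dev.off()
      if (!is.null(increments)) {
        grDevices::png(file.path(config$outdir, "increments.png"),
                       width = 900, height = 600)
        plot_increments(increments, stats_df)
        grDevices::dev.off()
      }
    }
  }
  invisible(list(courses = courses, increments = increments,
                 stats = stats_df, outdir = config$outdir))
}

#' Plot mean dry-mass time courses per condition
#'
#' @param courses the `courses` data frame of [run_virtual_experiment()].
#' @export
plot_dm_courses <- function(courses) {
  conds <- unique(courses$condition)
  agg <- stats::aggregate(dry_mass_ng ~ condition + time_h, courses, mean)
  graphics::plot(NULL, xlim = range(agg$time_h),
                 ylim = range(agg$dry_mass_ng),
                 xlab = "time (h)", ylab = "dry mass (ng)",
                 main = "population dry-mass course per condition")
  for (i in seq_along(conds)) {
    sub <- agg[agg$condition == conds[i], ]
    graphics::lines(sub$time_h, sub$dry_mass_ng, col = i, lwd = 2)
  }
  graphics::legend("topleft", legend = conds, col = seq_along(conds),
                   lwd = 2, bty = "n")
}

#' Scatterplot of per-FOV 24-h increments with significance stars
#'
#' @param increments,stats data frames from [run_virtual_experiment()].
#' @export
plot_increments <- function(increments, stats = NULL) {
  conds <- unique(increments$condition)
  x <- match(increments$condition, conds)
  graphics::plot(jitter(x, amount = 0.1), increments$increment_ng,
                 xaxt = "n", xlab = "", ylab = "24-h dry-mass increment (ng)",
                 main = "endpoint increments per FOV", pch = 19,
                 col = grDevices::adjustcolor(x, 0.6))
  graphics::axis(1, at = seq_along(conds), labels = conds, las = 2,
                 cex.axis = 0.8)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(stats)) {
    for (i in seq_along(conds)) {
      s <- stats$stars[stats$condition == conds[i]]
      if (length(s) && !is.na(s))
        graphics::mtext(s, side = 3, at = i, line = -1.2)
    }
  }
}
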