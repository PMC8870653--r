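# Dry-mass quantification: dm = lambda / (2 * pi * alpha) * mean_phase *
# S_FOV, time courses per FOV, 24-h increments, and the endpoint
# statistics (two-sided t-test, Bonferroni correction, star labels).

#' Dry-mass conversion parameters
#'
#' @param wavelength_nm light wavelength (nm); 532 by default.
#' @param alpha_ml_per_g specific refractive increment relating phase to
#'   intracellular protein content (mL/g); 0.19 by default.
#' @param s_fov_um2 area of the observed field of view (um^2); when NULL
#'   it is derived from the phase-map grid (pixels x pitch^2).
#' @return a `drymass_params` object.
#' @export
drymass_params <- function(wavelength_nm = 532, alpha_ml_per_g = 0.19,
                           s_fov_um2 = NULL) {
  if (wavelength_nm <= 0) stop_config("wavelength must be > 0")
  if (alpha_ml_per_g <= 0) stop_config("alpha must be > 0")
  if (!is.null(s_fov_um2) && s_fov_um2 <= 0)
    stop_config("S_FOV must be > 0")
  structure(list(wavelength_nm = wavelength_nm,
                 alpha_ml_per_g = alpha_ml_per_g, s_fov_um2 = s_fov_um2),
            class = "drymass_params")
}

#' Field-of-view area
#'
#' @param width_um,height_um FOV dimensions in micrometres (> 0).
#' @return area in um^2 (e.g. 450 x 338 um -> 152,100 um^2).
#' @export
fov_area <- function(width_um, height_um) {
  if (!is_scalar_num(width_um) || !is_scalar_num(height_um) ||
      width_um <= 0 || height_um <= 0)
    stop_config("FOV dimensions must be > 0")
  width_um * height_um
}

#' Mean phase over the field of view
#'
#' Arithmetic mean over all pixels, cell and background alike; after
#' background correction the background contributes about zero, so this
#' is the population signal.
#'
#' @param phase a [phase_map()] or matrix.
#' @return mean phase in radians.
#' @export
mean_phase <- function(phase) {
  m <- if (inherits(phase, "phase_map")) phase$phase else phase
  if (!is.matrix(m) || length(m) == 0) stop_data("empty phase raster")
  mean(m)
}

#' Convert mean phase to population dry mass
#'
#' \eqn{dm = \frac{\lambda}{2\pi\alpha}\, \bar{\Delta\varphi}\, S_{FOV}}.
#' Units: with lambda in um, alpha in mL/g (= um^3/pg) and S_FOV in um^2
#' the result is in pg, reported in ng.  Linear in both the mean phase
#' and the FOV area.
#'
#' @param mean_phase_rad mean phase shift over the FOV (radians).
#' @param params a [drymass_params()]; `s_fov_um2` must be set here.
#' @return dry mass in nanograms (may be negative for phase dips).
#' @export
dry_mass <- function(mean_phase_rad, params = drymass_params(
                       s_fov_um2 = fov_area(450, 338))) {
  stopifnot(inherits(params, "drymass_params"))
  if (is.null(params$s_fov_um2))
    stop_config("S_FOV is required (set s_fov_um2 or use dry_mass_map)")
  lam_um <- params$wavelength_nm / 1000
  pg <- lam_um / (2 * pi * params$alpha_ml_per_g) * mean_phase_rad *
    params$s_fov_um2
  pg / 1000
}

#' Dry mass of a phase map
#'
#' Convenience wrapper deriving S_FOV from the map's own grid
#' (pixels x pitch^2), so that the mean-phase formulation and the
#' pixelwise sum x pixel-area formulation agree to machine precision.
#'
#' @param phase a [phase_map()].
#' @param params a [drymass_params()] (its `s_fov_um2` is ignored).
#' @return dry mass in nanograms.
#' @export
dry_mass_map <- function(phase, params = drymass_params()) {
  stopifnot(inherits(phase, "phase_map"))
  s <- length(phase$phase) * phase$pixel_pitch_um^2
  p <- params
  p$s_fov_um2 <- s
  dry_mass(mean_phase(phase), p)
}

#' Dry-mass time course for one FOV
#'
#' @param maps time-ordered list of [phase_map()] objects for one FOV
#'   (each should carry `time_h`; >= 2 timepoints).
#' @param params a [drymass_params()].
#' @param condition,concentration_ug_per_ml,fov_id,experiment labels.
#' @return a `dry_mass_series`: data frame with columns `time_h`,
#'   `dry_mass_ng` plus label attributes.
#' @export
dm_course <- function(maps, params = drymass_params(),
                      condition = "medium control",
                      concentration_ug_per_ml = 0,
                      fov_id = 1L, experiment = 1L) {
  stopifnot(is.list(maps), length(maps) >= 2)
  dims <- dim(maps[[1]]$phase)
  times <- vapply(maps, function(m) {
    if (!inherits(m, "phase_map") || !all(dim(m$phase) == dims))
      stop_data("inconsistent geometry across timepoints")
    m$time_h %||% NA_real_
  }, numeric(1))
  if (anyNA(times)) times <- seq(0, 24, length.out = length(maps))
  if (any(diff(times) <= 0)) stop_data("times must be strictly increasing")
  dm <- vapply(maps, dry_mass_map, numeric(1), params = params)
  dry_mass_series(times, dm, condition, concentration_ug_per_ml,
                  fov_id, experiment)
}

#' Construct a dry-mass series
#'
#' @param time_h,dry_mass_ng numeric vectors of equal length; times must
#'   be strictly increasing.
#' @param condition,concentration_ug_per_ml,fov_id,experiment labels.
#' @return a `dry_mass_series` data frame.
#' @export
dry_mass_series <- function(time_h, dry_mass_ng,
                            condition = "medium control",
                            concentration_ug_per_ml = 0,
                            fov_id = 1L, experiment = 1L) {
  if (length(time_h) != length(dry_mass_ng))
    stop_data("time and mass vectors differ in length")
  if (any(diff(time_h) <= 0)) stop_data("times must be strictly increasing")
  structure(data.frame(time_h = time_h, dry_mass_ng = dry_mass_ng),
            condition = condition,
            concentration_ug_per_ml = concentration_ug_per_ml,
            fov_id = fov_id, experiment = experiment,
            class = c("dry_mass_series", "data.frame"))
}

#' 24-h dry-mass increment of a series
#'
#' dm(24 h) - dm(0 h) for one FOV; negative under lysis (no clipping).
#'
#' @param series a `dry_mass_series` spanning t = 0 and t = 24 h.
#' @return increment in nanograms.
#' @export
dm_increment <- function(series) {
  stopifnot(inherits(series, "dry_mass_series"))
  i0 <- which(abs(series$time_h - 0) < 1e-9)
  i24 <- which(abs(series$time_h - 24) < 1e-9)
  if (!length(i0) || !length(i24))
    stop_data("series must contain samples at t = 0 and t = 24 h")
  series$dry_mass_ng[i24[1]] - series$dry_mass_ng[i0[1]]
}

#' Significance-star label from an (adjusted) p-value
#'
#' p < 0.005 -> `***`, p < 0.01 -> `**`, p < 0.05 -> `*`, else `ns`.
#'
#' @param p p-value.
#' @return character label.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.005) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Compare 24-h increments of a treated group against control
#'
#' Two-sided two-sample Student's t-test (pooled variance) with
#' Bonferroni correction `p_adj = min(1, p * n_comparisons)` and the
#' star convention of [significance_stars()] applied to the adjusted
#' p-value.  When both groups have zero variance, p is defined as 1 for
#' equal means and 0 otherwise.  An optional variance-homogeneity
#' pre-test (F-test) warns but never changes the reported test.
#'
#' @param treated,control numeric vectors of per-FOV increments (ng),
#'   each of length >= 2.
#' @param n_comparisons number of simultaneous comparisons for the
#'   Bonferroni correction.
#' @param pretest run the variance-homogeneity check (warning only).
#' @return an `increment_stats` list: group summaries, `t`, `df`, `p`,
#'   `p_adj`, `stars`.
#' @export
compare_conditions <- function(treated, control, n_comparisons = 1L,
                               pretest = FALSE) {
  if (length(treated) < 2 || length(control) < 2)
    stop_data("each group needs at least 2 increments")
  if (pretest && sd(treated) > 0 && sd(control) > 0) {
    ft <- var.test(treated, control)
    if (ft$p.value < 0.05)
      warning(sprintf(
        "variance-homogeneity pre-test failed (F-test p = %.3g)",
        ft$p.value))
  }
  if (sd(treated) == 0 && sd(control) == 0) {
    p <- if (isTRUE(all.equal(mean(treated), mean(control)))) 1 else 0
    tt <- list(statistic = c(t = 0), parameter =
                 c(df = length(treated) + length(control) - 2),
               p.value = p)
  } else {
    tt <- t.test(treated, control, var.equal = TRUE)
  }
  p_adj <- min(1, tt$p.value * n_comparisons)
  structure(list(treated = treated, control = control,
                 mean_treated = mean(treated), sd_treated = sd(treated),
                 mean_control = mean(control), sd_control = sd(control),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, p_adj = p_adj,
                 n_comparisons = as.integer(n_comparisons),
                 stars = significance_stars(p_adj)),
            class = "increment_stats")
}

#' @export
print.increment_stats <- function(x, ...) {
  cat(sprintf(
    "treated %.1f +/- %.1f ng vs control %.1f +/- %.1f ng: t = %.2f, p = %.3g, p_adj = %.3g (%s)\n",
    x$mean_treated, x$sd_treated, x$mean_control, x$sd_control,
    x$t, x$p, x$p_adj, x$stars))
  invisible(x)
}
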