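# Synthetic cell populations rendered as phase objects with closed-form
# dry mass, standing in for live-cell specimens in a virtual DHM assay.

#' Construct a phantom cell
#'
#' A phantom cell is a rotationally symmetric phase object defined by its
#' footprint radius, maximum optical thickness and integral refractive
#' index.  Its phase contribution at wavelength \eqn{\lambda} is
#' \eqn{\Delta\varphi = (2\pi/\lambda)\, d(x,y)\, (n_{cell} - n_{medium})}.
#'
#' @param center numeric length-2, cell centre (x, y) in micrometres.
#' @param footprint_radius_um footprint radius in micrometres (> 0).
#' @param thickness_um maximum thickness \eqn{d_{cell}} in micrometres
#'   (>= 0).
#' @param n_cell integral cellular refractive index (dimensionless).
#' @param profile thickness profile: truncated paraboloid (default),
#'   hemi-ellipsoid ("hemisphere") or flat disc.
#' @return an object of class `phantom_cell`.
#' @export
phantom_cell <- function(center, footprint_radius_um, thickness_um,
                         n_cell,
                         profile = c("paraboloid", "hemisphere", "disc")) {
  profile <- match.arg(profile)
  if (!is.numeric(center) || length(center) != 2L)
    stop_config("cell center must be a numeric (x, y) pair")
  if (!is_scalar_num(footprint_radius_um) || footprint_radius_um <= 0)
    stop_config("footprint radius must be > 0")
  if (!is_scalar_num(thickness_um) || thickness_um < 0)
    stop_config("cell thickness must be >= 0")
  if (!is_scalar_num(n_cell))
    stop_config("n_cell must be a finite number")
  structure(list(center = as.numeric(center),
                 footprint_radius_um = footprint_radius_um,
                 thickness_um = thickness_um,
                 n_cell = n_cell,
                 profile = profile),
            class = "phantom_cell")
}

# closed-form volume of the thickness profile (um^3)
cell_volume_um3 <- function(cell) {
  R <- cell$footprint_radius_um
  d <- cell$thickness_um
  switch(cell$profile,
         paraboloid = pi * R^2 * d / 2,
         hemisphere = 2 * pi * R^2 * d / 3,
         disc       = pi * R^2 * d)
}

#' Raster grid geometry for a scene
#'
#' @param nx,ny raster dimensions in pixels (>= 64 each).
#' @param pixel_pitch_um pixel pitch in the sample plane (micrometres per
#'   pixel).  The default grid, 512 x 384 at 0.879 um/pixel, covers a
#'   450 um x 338 um field of view.
#' @return a `scene_grid` list.
#' @export
scene_grid <- function(nx = 512L, ny = 384L, pixel_pitch_um = 0.879) {
  if (!is_scalar_num(nx) || !is_scalar_num(ny) || nx < 64 || ny < 64)
    stop_config("grid dimensions must be >= 64 x 64 pixels")
  if (!is_scalar_num(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop_config("pixel pitch must be > 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_pitch_um = pixel_pitch_um),
            class = "scene_grid")
}

#' Construct a synthetic scene
#'
#' A scene is a population of phantom cells (plus optional debris
#' fragments) suspended in culture medium over a raster grid.  Where cell
#' footprints overlap, phase contributions add (cells may cluster).
#'
#' @param cells list of [phantom_cell()] objects.
#' @param grid a [scene_grid()].
#' @param n_medium refractive index of the culture medium.
#' @param debris list of `phantom_cell` fragments (lysis remnants).
#' @return an object of class `dhm_scene`.
#' @export
scene <- function(cells = list(), grid = scene_grid(),
                  n_medium = 1.337, debris = list()) {
  if (!inherits(grid, "scene_grid")) grid <- do.call(scene_grid, grid)
  fov <- c(grid$nx, grid$ny) * grid$pixel_pitch_um
  for (cl in c(cells, debris)) {
    if (!inherits(cl, "phantom_cell"))
      stop_config("all scene members must be phantom_cell objects")
    if (cl$n_cell < n_medium)
      stop_config("n_cell (%.4f) must be >= n_medium (%.4f)",
                  cl$n_cell, n_medium)
    if (any(cl$center < 0) || cl$center[1] > fov[1] || cl$center[2] > fov[2])
      stop_config("cell center (%.1f, %.1f) lies outside the FOV",
                  cl$center[1], cl$center[2])
  }
  structure(list(cells = cells, debris = debris, grid = grid,
                 n_medium = n_medium),
            class = "dhm_scene")
}

#' Generate a random subconfluent cell population
#'
#' Defaults emulate a subconfluent macrophage-like population: 70 cells
#' of 10-15 um footprint radius over a 450 um x 338 um field of view,
#' per-cell dry mass near 0.36 ng, so the population starts around 25 ng
#' per FOV.  Cells are placed wholly inside the FOV so the closed-form
#' ground-truth mass matches what the raster sees.
#'
#' @param n_cells number of cells.
#' @param grid a [scene_grid()].
#' @param seed integer seed (scene generation is deterministic given it).
#' @param n_medium medium refractive index.
#' @param radius_range_um,thickness_range_um,n_cell_range sampling ranges.
#' @param profile thickness profile for all cells.
#' @return a `dhm_scene`.
#' @export
random_scene <- function(n_cells = 70L, grid = scene_grid(), seed = 1L,
                         n_medium = 1.337,
                         radius_range_um = c(10, 15),
                         thickness_range_um = c(5, 8),
                         n_cell_range = c(1.372, 1.387),
                         profile = "paraboloid") {
  if (!inherits(grid, "scene_grid")) grid <- do.call(scene_grid, grid)
  fov <- c(grid$nx, grid$ny) * grid$pixel_pitch_um
  cells <- with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      R <- runif(1, radius_range_um[1], radius_range_um[2])
      phantom_cell(center = c(runif(1, R, fov[1] - R),
                              runif(1, R, fov[2] - R)),
                   footprint_radius_um = R,
                   thickness_um = runif(1, thickness_range_um[1],
                                        thickness_range_um[2]),
                   n_cell = runif(1, n_cell_range[1], n_cell_range[2]),
                   profile = profile)
    })
  })
  scene(cells = cells, grid = grid, n_medium = n_medium)
}

#' Render the phase map of a scene
#'
#' Evaluates the cell-induced phase shift per pixel,
#' \eqn{\Delta\varphi(x,y) = (2\pi/\lambda) \sum_k d_k(x,y)\,
#' (n_{cell,k} - n_{medium})}, summing contributions of overlapping cells
#' and debris.  The rendered phase is non-negative for valid scenes.
#'
#' @param scene a `dhm_scene`.
#' @param wavelength_nm illumination wavelength in nanometres.
#' @return a `phase_map` carrying the scene's grid geometry.
#' @export
render_phase <- function(scene, wavelength_nm = 532) {
  stopifnot(inherits(scene, "dhm_scene"))
  if (!is_scalar_num(wavelength_nm) || wavelength_nm <= 0)
    stop_config("wavelength must be > 0")
  g <- scene$grid
  lam_um <- wavelength_nm / 1000
  pitch <- g$pixel_pitch_um
  phase <- matrix(0, nrow = g$ny, ncol = g$nx)
  # pixel-centre coordinates in micrometres
  xs <- (seq_len(g$nx) - 0.5) * pitch
  ys <- (seq_len(g$ny) - 0.5) * pitch
  for (cl in c(scene$cells, scene$debris)) {
    dn <- cl$n_cell - scene$n_medium
    if (dn == 0 || cl$thickness_um == 0) next
    R <- cl$footprint_radius_um
    jr <- which(abs(xs - cl$center[1]) <= R)
    ir <- which(abs(ys - cl$center[2]) <= R)
    if (!length(jr) || !length(ir)) next
    dx <- xs[jr] - cl$center[1]
    dy <- ys[ir] - cl$center[2]
    r2 <- outer(dy^2, dx^2, `+`) / R^2
    thick <- switch(cl$profile,
                    paraboloid = cl$thickness_um * pmax(0, 1 - r2),
                    hemisphere = cl$thickness_um * sqrt(pmax(0, 1 - r2)),
                    disc       = cl$thickness_um * (r2 <= 1))
    phase[ir, jr] <- phase[ir, jr] + (2 * pi / lam_um) * dn * thick
  }
  phase_map(phase, pixel_pitch_um = pitch, wavelength_nm = wavelength_nm)
}

#' Analytic (ground-truth) dry mass of a scene
#'
#' Evaluates the population dry mass from the cells' closed-form volumes,
#' \eqn{dm = \sum_k (n_{cell,k} - n_{medium}) V_k / \alpha}, which equals
#' \eqn{\lambda/(2\pi\alpha)} times the continuous phase integral over the
#' FOV.  The wavelength cancels exactly; the argument is retained so the
#' signature mirrors the raster-based pipeline it validates.
#'
#' @param scene a `dhm_scene`.
#' @param wavelength_nm wavelength in nanometres (cancels; see details).
#' @param alpha_ml_per_g specific refractive increment, mL/g.
#' @return dry mass in nanograms.
#' @export
analytic_dry_mass <- function(scene, wavelength_nm = 532,
                              alpha_ml_per_g = 0.19) {
  stopifnot(inherits(scene, "dhm_scene"))
  if (!is_scalar_num(alpha_ml_per_g) || alpha_ml_per_g <= 0)
    stop_config("alpha must be > 0")
  # 1 mL/g == 1 um^3/pg, so dn * V[um^3] / alpha is in pg
  pg <- 0
  for (cl in c(scene$cells, scene$debris))
    pg <- pg + (cl$n_cell - scene$n_medium) * cell_volume_um3(cl) /
      alpha_ml_per_g
  pg / 1000  # ng
}

#' Specify a 24-h population dynamics scenario
#'
#' The five laws mirror the temporal dry-mass courses seen in time-lapse
#' cytotoxicity experiments: exponential growth (macrophage-like),
#' linear growth, growth arrest (cytostatic control), lysis (detergent or
#' membrane-damaging particles; mass decreases and debris appears), and
#' delayed toxicity (growth up to an onset, then decline).
#'
#' @param kind scenario kind.
#' @param doubling_time_h doubling time for exponential growth (h).
#' @param slope_ng_per_h linear growth slope (ng/h).
#' @param onset_h decline onset within [0, 24] h (lysis and
#'   delayed-toxicity).
#' @param decline_rate_per_h exponential decline rate after onset (1/h).
#' @param debris_fraction fraction of lysed cell mass retained in the FOV
#'   as debris fragments; the remainder is considered dissolved.
#' @param seed integer seed controlling debris placement.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("control-exponential", "control-linear",
                                   "arrest", "lysis", "delayed-toxicity"),
                          doubling_time_h = 24,
                          slope_ng_per_h = 0.2,
                          onset_h = NULL,
                          decline_rate_per_h = NULL,
                          debris_fraction = 0.3,
                          seed = 1L) {
  kind <- match.arg(kind)
  onset_h <- onset_h %||% if (kind == "lysis") 1 else 10
  decline_rate_per_h <- decline_rate_per_h %||%
    if (kind == "lysis") 0.0165 else 0.0207
  if (kind == "control-exponential" && doubling_time_h <= 0)
    stop_config("doubling time must be > 0")
  if (onset_h < 0 || onset_h > 24)
    stop_config("decline onset must lie within [0, 24] h")
  if (debris_fraction < 0 || debris_fraction >= 1)
    stop_config("debris fraction must be in [0, 1)")
  structure(list(kind = kind, doubling_time_h = doubling_time_h,
                 slope_ng_per_h = slope_ng_per_h, onset_h = onset_h,
                 decline_rate_per_h = decline_rate_per_h,
                 debris_fraction = debris_fraction,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Scenario dry-mass law
#'
#' Target total FOV dry mass at time `t` for a population starting at
#' `m0`: exponential \eqn{m_0 2^{t/T_d}}; linear \eqn{m_0 + rt}; arrest
#' \eqn{m_0}; lysis \eqn{m_0 e^{-k(t - t_0)}} after onset; delayed
#' toxicity grows exponentially to the onset then declines.
#'
#' @param scenario a [scenario_spec()].
#' @param m0 dry mass at t = 0 (ng).
#' @param t time in hours.
#' @return dry mass in ng (vectorised over `t`).
#' @export
scenario_mass <- function(scenario, m0, t) {
  stopifnot(inherits(scenario, "scenario_spec"))
  switch(scenario$kind,
    "control-exponential" = m0 * 2^(t / scenario$doubling_time_h),
    "control-linear"      = m0 + scenario$slope_ng_per_h * t,
    "arrest"              = rep(m0, length(t)),
    "lysis"               = ifelse(t <= scenario$onset_h, m0,
      m0 * exp(-scenario$decline_rate_per_h * (t - scenario$onset_h))),
    "delayed-toxicity"    = {
      mpeak <- m0 * 2^(pmin(t, scenario$onset_h) / scenario$doubling_time_h)
      ifelse(t <= scenario$onset_h, mpeak,
             mpeak * exp(-scenario$decline_rate_per_h *
                           (t - scenario$onset_h)))
    })
}

#' Evolve a scene along a scenario
#'
#' Returns a new scene whose analytic dry mass equals the scenario law at
#' time `t`.  Growth and arrest scale cell thicknesses (mass is linear in
#' thickness, so the target is met exactly).  Under lysis, the mass lost
#' from cells is split between debris fragments retained in the FOV
#' (`debris_fraction` of the loss) and dissolved material; the visible
#' total follows the law.  Deterministic given the scenario seed.
#'
#' @param scene a `dhm_scene` (state at t = 0).
#' @param scenario a [scenario_spec()].
#' @param t time in hours, within [0, 24].
#' @return a new `dhm_scene`.
#' @export
evolve <- function(scene, scenario, t) {
  stopifnot(inherits(scene, "dhm_scene"), inherits(scenario, "scenario_spec"))
  if (!is_scalar_num(t) || t < 0 || t > 24)
    stop_config("t must lie within [0, 24] h")
  m0 <- analytic_dry_mass(scene)
  mt <- scenario_mass(scenario, m0, t)
  if (m0 <= 0) return(scene)
  if (mt >= m0) {
    return(scale_cells(scene, mt / m0))
  }
  # mass decline: cells shrink; a fraction of the loss stays as debris
  frac <- scenario$debris_fraction
  loss_cells <- (m0 - mt) / (1 - frac)
  if (loss_cells >= m0) loss_cells <- m0  # fully lysed
  out <- scale_cells(scene, (m0 - loss_cells) / m0)
  debris_mass <- frac * loss_cells
  if (debris_mass > 0)
    out$debris <- make_debris(scene, debris_mass,
                              derive_seed(scenario$seed, t))
  out
}

scale_cells <- function(scene, factor) {
  scene$cells <- lapply(scene$cells, function(cl) {
    cl$thickness_um <- cl$thickness_um * factor
    cl
  })
  scene
}

# small low-phase disc fragments with a prescribed total dry mass (ng);
# the fragment count scales with the mass so individual fragments stay
# optically gentle (~15 pg, about 1 rad peak phase)
make_debris <- function(scene, total_ng, seed) {
  g <- scene$grid
  fov <- c(g$nx, g$ny) * g$pixel_pitch_um
  n_frag <- max(10L, min(400L, as.integer(round(total_ng / 0.015))))
  frags <- with_seed(seed, {
    lapply(seq_len(n_frag), function(i) {
      phantom_cell(center = c(runif(1, 0, fov[1]), runif(1, 0, fov[2])),
                   footprint_radius_um = runif(1, 3, 6),
                   thickness_um = 2,
                   n_cell = scene$n_medium + 0.03,
                   profile = "paraboloid")
    })
  })
  # same mass convention as analytic_dry_mass() defaults (alpha = 0.19)
  raw_ng <- sum(vapply(frags, function(f)
    (f$n_cell - scene$n_medium) * cell_volume_um3(f), numeric(1))) /
    0.19 / 1000
  scale <- total_ng / raw_ng
  lapply(frags, function(f) { f$thickness_um <- f$thickness_um * scale; f })
}
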