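# Shared fixtures, all built in code at test time.

# small grid used where full resolution is not the point
tiny_grid <- function(nx = 256L, ny = 192L) scene_grid(nx, ny, 0.879)

# a smooth, unwrapping-free phantom (spread-cell morphology, < pi peak)
smooth_scene <- function(seed = 3, grid = scene_grid(), n_cells = 70L)
  random_scene(n_cells, grid, seed = seed,
               thickness_range_um = c(1.5, 2.5))

# nearest integer-bin carrier so tilt removal is exact on this grid
int_carrier <- function(grid, fx = 0.25, fy = 0.25)
  c(round(fx * grid$nx) / grid$nx, round(fy * grid$ny) / grid$ny)

# single noise-free hologram of a scene
one_hologram <- function(scene, config = optical_config(), seed = 1L)
  interfere(object_wave(render_phase(scene, config$wavelength_nm), config),
            config, seed = seed)

# RMS after piston (median) removal
piston_rms <- function(a, b) {
  d <- a - b
  d <- d - median(d)
  sqrt(mean(d^2))
}

# naive reference opening with the same spherical-cap element, written
# as plain double loops: the independent oracle for the rolling ball
oracle_opening <- function(img, radius, scale) {
  nr <- nrow(img); nc <- ncol(img)
  r <- floor(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  off$h <- scale * sqrt(radius^2 - off$dx^2 - off$dy^2)
  ero <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    ii <- i + off$dy; jj <- j + off$dx
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    ero[i, j] <- min(img[cbind(ii[ok], jj[ok])] - off$h[ok])
  }
  dil <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    ii <- i - off$dy; jj <- j - off$dx
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    dil[i, j] <- max(ero[cbind(ii[ok], jj[ok])] + off$h[ok])
  }
  dil
}
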