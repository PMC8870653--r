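# recon module: sideband location, extraction, aberration compensation,
# refocusing, unwrapping, averaging, and the end-to-end oracles

test_that("locate_sideband finds the carrier and rejects non-holograms", {
  g <- tiny_grid()
  cfg <- optical_config(carrier_cpp = int_carrier(g))
  sc <- smooth_scene(1, g, n_cells = 10)
  h <- one_hologram(sc, cfg)
  sb <- locate_sideband(h)
  expect_lt(max(abs(sb$peak_cpp - cfg$carrier_cpp)),
            1 / min(g$nx, g$ny) + 1e-12)

  expect_error(locate_sideband(matrix(1, 192, 256)), "no sideband")

  # mirrored carrier: the detected order always lies in the canonical
  # half-plane (positive first spectral axis)
  cfgm <- optical_config(carrier_cpp = c(-0.2, 0.1))
  hm <- one_hologram(sc, cfgm)
  sbm <- locate_sideband(hm)
  expect_gt(sbm$peak_cpp[1], 0)
  # within one spectral bin per axis of the mirrored-to-canonical carrier
  expect_lt(abs(abs(sbm$peak_cpp[1]) - 0.2), 1 / 256 + 1e-9)
  expect_lt(abs(abs(sbm$peak_cpp[2]) - 0.1), 1 / 192 + 1e-9)
})

test_that("extract_object_wave recovers flat and smooth phantom phase", {
  g <- scene_grid()
  cfg <- optical_config()
  p <- recon_params()

  flat <- phase_map(matrix(0, g$ny, g$nx), g$pixel_pitch_um)
  hf <- interfere(object_wave(flat, cfg), cfg, seed = 1)
  ff <- extract_object_wave(hf, NULL, p)
  expect_lt(piston_rms(Arg(ff$field), flat$phase), 1e-3)

  sc <- smooth_scene(3, g)
  ph <- render_phase(sc)
  expect_lt(max(ph$phase), pi)
  h <- one_hologram(sc, cfg)
  fld <- extract_object_wave(h, NULL, p)
  expect_lt(piston_rms(unwrap_phase(Arg(fld$field), 0.879)$phase,
                       ph$phase), 0.01)
})

test_that("subpixel carrier leaves at most one fringe of residual tilt", {
  g <- tiny_grid()
  cfg <- optical_config(carrier_cpp = int_carrier(g) + 0.5 / c(g$nx, g$ny))
  flat <- phase_map(matrix(0, g$ny, g$nx), 0.879)
  h <- interfere(object_wave(flat, cfg), cfg, seed = 1)
  fld <- extract_object_wave(h, NULL, recon_params())
  un <- unwrap_phase(Arg(fld$field), 0.879)$phase
  expect_lt(diff(range(un[20:172, 20:236])), 2 * pi + 0.3)
})

test_that("sideband mask must exclude DC", {
  g <- tiny_grid()
  cfg <- optical_config(carrier_cpp = int_carrier(g))
  h <- one_hologram(smooth_scene(1, g, n_cells = 5), cfg)
  sb <- locate_sideband(h)
  # a mask filling almost the whole carrier distance reaches the
  # zero-order region and must be rejected with a diagnostic
  expect_error(extract_object_wave(h, sb,
                                   recon_params(mask_fraction = 0.99)),
               "zero-order", class = "holomass_config_error")
})

test_that("spherical aberration is compensated from the sideband size", {
  g <- scene_grid()
  flat <- phase_map(matrix(0, g$ny, g$nx), g$pixel_pitch_um)
  p <- recon_params()

  # zero injected aberration passes through bit-exactly
  cfg0 <- optical_config()
  h0 <- interfere(object_wave(flat, cfg0), cfg0, seed = 1)
  sb0 <- locate_sideband(h0, p)
  f0 <- extract_object_wave(h0, sb0, p)
  c0 <- compensate_spherical(f0, sb0, p)
  expect_lt(max(abs(Arg(c0$field) - Arg(f0$field))), 1e-6)

  # injected quadratic phase on a flat object: residual std < 0.02 rad
  # (central 80%; the masked field's border amplitude is apodized)
  a <- 2e-4
  cfga <- optical_config(aberration_rad_px2 = a)
  ha <- interfere(object_wave(flat, cfga), cfga, seed = 1)
  sba <- locate_sideband(ha, p)
  ca <- compensate_spherical(extract_object_wave(ha, sba, p), sba, p)
  expect_equal(attr(ca, "curvature"), a, tolerance = 1e-3)
  res <- Arg(ca$field)[39:346, 52:461]
  res <- res - median(res)
  expect_lt(sd(res), 0.02)
})

test_that("aberrated phantom keeps its dry mass through compensation", {
  g <- scene_grid()
  sc <- smooth_scene(3, g)
  bp <- background_params()
  p <- recon_params()

  run_dm <- function(a) {
    cfg <- optical_config(aberration_rad_px2 = a,
                          frames_per_timepoint = 1)
    pm <- reconstruct_stack(acquire_timepoint(sc, cfg, 0, seed = 11), p)
    dry_mass_map(rolling_ball_subtract(pm, bp))
  }
  expect_equal(run_dm(2e-4), run_dm(0), tolerance = 0.03)
})

test_that("refocus is the inverse-propagation convolution it claims to be", {
  g <- tiny_grid()
  sc <- smooth_scene(4, g, n_cells = 10)
  fld <- complex_field(exp(1i * render_phase(sc)$phase), 0.879, 532)

  expect_identical(refocus(fld, 0)$field, fld$field)

  # plane wave is a propagation eigenfunction
  pw <- complex_field(matrix(1 + 0i, g$ny, g$nx), 0.879, 532)
  out <- refocus(pw, 55)
  expect_lt(diff(range(Arg(out$field))), 1e-9)
  expect_equal(Mod(out$field), Mod(pw$field), tolerance = 1e-9)

  # unitarity and exact inversion
  fwd <- refocus(fld, 40)
  expect_equal(sum(Mod(fwd$field)^2) / sum(Mod(fld$field)^2), 1,
               tolerance = 1e-6)
  expect_lt(max(Mod(refocus(fwd, -40)$field - fld$field)), 1e-9)
})

test_that("a defocused hologram refocuses onto the in-focus truth", {
  g <- scene_grid()
  sc <- smooth_scene(3, g)
  ph <- render_phase(sc)
  cfg <- optical_config(defocus_um = 40, frames_per_timepoint = 1)
  holos <- acquire_timepoint(sc, cfg, 0, seed = 11)
  pm <- reconstruct_stack(holos, recon_params(refocus_um = -40))
  expect_lt(piston_rms(pm$phase, ph$phase), 0.02)
})

test_that("unwrap_phase restores ramps and wrapped cells", {
  # already-continuous input returns unchanged (up to a global 2*pi*k)
  g <- tiny_grid(128, 96)
  w <- matrix(runif(96 * 128, -3, 3) * 0.4, 96, 128)
  un <- unwrap_phase(w, 0.879)$phase
  expect_lt(max(abs((un - w) - 2 * pi * round(mean(un - w) / (2 * pi)))),
            1e-9)

  # 6*pi ramp wrapped analytically
  ramp <- matrix(seq(0, 6 * pi, length.out = 256), 128, 256, byrow = TRUE)
  wr <- pi - (pi - ramp) %% (2 * pi)
  unr <- unwrap_phase(wr, 0.879)$phase
  d <- unr - ramp
  expect_lt(max(abs(d - 2 * pi * round(median(d) / (2 * pi)))), 1e-6)

  # synthetic cell with ~7 rad peak (wraps once) through the full chain
  gc <- tiny_grid()
  cell <- phantom_cell(c(112, 84), 40, 11.85, 1.387)
  scw <- scene(list(cell), gc)
  phw <- render_phase(scw)
  expect_gt(max(phw$phase), 2 * pi)
  cfg <- optical_config()
  pm <- reconstruct_stack(list(one_hologram(scw, cfg)), recon_params())
  expect_equal(max(pm$phase), max(phw$phase), tolerance = 0.05 / 7)
})

test_that("average_phases is the pixelwise mean with geometry checks", {
  m <- matrix(rnorm(48 * 64), 48, 64)
  pm <- phase_map(m, 0.879)
  expect_equal(average_phases(rep(list(pm), 15))$phase, m)

  pm2 <- phase_map(m + 1, 0.879)
  expect_equal(average_phases(list(pm, pm2))$phase, m + 0.5)

  bad <- phase_map(matrix(0, 10, 10), 0.879)
  expect_error(average_phases(list(pm, bad)), "geometry")

  # noise-reduction law: 15 maps of truth + iid noise
  set.seed(42)
  sigma <- 0.2
  maps <- lapply(1:15, function(i)
    phase_map(m + matrix(rnorm(48 * 64, sd = sigma), 48, 64), 0.879))
  resid <- average_phases(maps)$phase - m
  expect_equal(sd(resid), sigma / sqrt(15), tolerance = 0.15)
})

test_that("reconstruction is linear and tilt-invariant", {
  g <- tiny_grid()
  sc <- smooth_scene(8, g, n_cells = 10)
  ph <- render_phase(sc)
  ph$phase <- ph$phase * (1.0 / max(ph$phase))  # keep 2x well below pi
  p <- recon_params()
  recon_of <- function(phm, carrier) {
    cfg <- optical_config(carrier_cpp = carrier)
    h <- interfere(object_wave(phm, cfg), cfg, seed = 1)
    unwrap_phase(Arg(extract_object_wave(h, NULL, p)$field), 0.879)$phase
  }
  ph2 <- ph; ph2$phase <- 2 * ph$phase
  r1 <- recon_of(ph, int_carrier(g))
  r2 <- recon_of(ph2, int_carrier(g))
  expect_lt(piston_rms(r2, 2 * r1) / sd(2 * r1), 0.01)

  r_alt <- recon_of(ph, int_carrier(g, 0.3, 0.2))
  expect_lt(piston_rms(r_alt, r1), 0.01)
})
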