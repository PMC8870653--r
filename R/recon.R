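# Fourier-method reconstruction of off-axis holograms: FFT, sideband
# isolation (removes twin image and zero order), spectrum re-centering
# (removes the off-axis tilt), inverse FFT, atan2 phase, quadratic
# aberration compensation, optional angular-spectrum refocusing,
# reliability-sorted unwrapping and multi-frame averaging.

#' Reconstruction parameters
#'
#' @param wavelength_nm wavelength (nm).
#' @param pixel_pitch_um pixel pitch (um/pixel).
#' @param mask_shape spectral mask around the sideband peak: hard disc
#'   (default) or raised-cosine edge.
#' @param mask_fraction mask radius as a fraction of the carrier distance
#'   (0 < fraction < 1; default 0.4 guarantees DC exclusion while keeping
#'   object bandwidth).
#' @param support_threshold fraction of the sideband peak magnitude at
#'   which the radially averaged spectrum defines the sideband support
#'   radius (default 1\%).
#' @param dc_exclude_cpp radius of the DC exclusion zone used when
#'   searching for the sideband peak (cycles/pixel).
#' @param refocus_um numerical refocusing distance applied after
#'   extraction (um; 0 disables).
#' @param compensate logical; run quadratic aberration compensation.
#' @return a `recon_params` object.
#' @export
recon_params <- function(wavelength_nm = 532, pixel_pitch_um = 0.879,
                         mask_shape = c("hard", "raised-cosine"),
                         mask_fraction = 0.4, support_threshold = 0.01,
                         dc_exclude_cpp = 0.05, refocus_um = 0,
                         compensate = TRUE) {
  mask_shape <- match.arg(mask_shape)
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stop_config("mask fraction must lie in (0, 1)")
  if (wavelength_nm <= 0 || pixel_pitch_um <= 0)
    stop_config("wavelength and pixel pitch must be > 0")
  structure(list(wavelength_nm = wavelength_nm,
                 pixel_pitch_um = pixel_pitch_um, mask_shape = mask_shape,
                 mask_fraction = mask_fraction,
                 support_threshold = support_threshold,
                 dc_exclude_cpp = dc_exclude_cpp, refocus_um = refocus_um,
                 compensate = isTRUE(compensate)),
            class = "recon_params")
}

holo_intensity <- function(holo) {
  if (inherits(holo, "hologram")) holo$intensity
  else if (is.matrix(holo)) holo
  else stop_data("expected a hologram or an intensity matrix")
}

# wrapped spectral distance grids (cycles/pixel) from a given bin
spectral_dist2 <- function(ny, nx, bin_y, bin_x) {
  fy <- freq_axis(ny); fx <- freq_axis(nx)
  dy <- fy - fy[bin_y]; dy <- dy - round(dy)     # wrap to [-0.5, 0.5)
  dx <- fx - fx[bin_x]; dx <- dx - round(dx)
  outer(dy^2, dx^2, `+`)
}

#' Locate the real-image sideband in the hologram spectrum
#'
#' Finds the magnitude-spectrum maximum outside a DC exclusion zone,
#' restricted to the canonical half-plane (positive first spectral axis)
#' to fix the +/-1-order ambiguity, and measures the sideband support
#' radius: the radius at which the radially averaged magnitude falls
#' below `support_threshold` of the peak, capped at half the carrier
#' distance.
#'
#' @param holo a `hologram` or intensity matrix.
#' @param params a [recon_params()].
#' @return a `sideband_info` list: `peak_cpp` (fx, fy), `peak_bin`
#'   (row, col 1-based), `support_radius_cpp`, `peak_mag`,
#'   `carrier_dist_cpp`.
#' @export
locate_sideband <- function(holo, params = recon_params()) {
  I <- holo_intensity(holo)
  ny <- nrow(I); nx <- ncol(I)
  S <- fft(I)
  mag <- Mod(S)
  fy <- freq_axis(ny); fx <- freq_axis(nx)
  fxm <- matrix(fx, ny, nx, byrow = TRUE)
  fym <- matrix(fy, ny, nx)
  allowed <- (fxm^2 + fym^2) > params$dc_exclude_cpp^2 &
    (fxm > 0 | (fxm == 0 & fym > 0))
  if (!any(allowed)) stop_data("grid too small for sideband search")
  cand <- mag * allowed
  peak <- which.max(cand)
  floor_mag <- median(mag[allowed])
  if (!(cand[peak] > 10 * floor_mag) || cand[peak] <= 0)
    stop_data("no sideband found outside the DC zone (not an off-axis hologram?)")
  pb <- arrayInd(peak, dim(mag))
  peak_cpp <- c(fx[pb[2]], fy[pb[1]])
  carrier_dist <- sqrt(sum(peak_cpp^2))
  # radially averaged magnitude about the peak, annuli one bin wide
  d <- sqrt(spectral_dist2(ny, nx, pb[1], pb[2]))
  cap <- carrier_dist / 2
  bin_w <- 1 / max(ny, nx)
  radii <- seq(bin_w, cap, by = bin_w)
  thr <- params$support_threshold * mag[peak]
  support <- cap
  prev <- 0
  for (r in radii) {
    sel <- d > prev & d <= r
    prev <- r
    if (!any(sel)) next
    if (mean(mag[sel]) < thr) { support <- r; break }
  }
  # refine the carrier to the magnitude centroid of the sideband support:
  # with strong aberration the sideband is a broad chirp disc whose
  # maximum bin wanders, while its centroid stays on the carrier
  sel <- d <= support
  w <- mag[sel]^2
  dfy <- fy - fy[pb[1]]; dfy <- dfy - round(dfy)
  dfx <- fx - fx[pb[2]]; dfx <- dfx - round(dfx)
  cy <- sum(matrix(dfy, ny, nx)[sel] * w) / sum(w)
  cx <- sum(matrix(dfx, ny, nx, byrow = TRUE)[sel] * w) / sum(w)
  pb_ref <- c(((pb[1] - 1 + round(cy * ny)) %% ny) + 1,
              ((pb[2] - 1 + round(cx * nx)) %% nx) + 1)
  peak_cpp <- c(fx[pb_ref[2]], fy[pb_ref[1]])
  carrier_dist <- sqrt(sum(peak_cpp^2))
  structure(list(peak_cpp = peak_cpp, peak_bin = as.integer(pb_ref),
                 support_radius_cpp = support, peak_mag = mag[peak],
                 carrier_dist_cpp = carrier_dist),
            class = "sideband_info")
}

# spectral mask of radius r_cpp about a bin, hard or raised-cosine edge
sideband_mask <- function(ny, nx, bin_y, bin_x, r_cpp, shape) {
  d <- sqrt(spectral_dist2(ny, nx, bin_y, bin_x))
  if (shape == "hard") {
    (d <= r_cpp) * 1
  } else {
    r0 <- 0.8 * r_cpp
    m <- matrix(0, ny, nx)
    m[d <= r0] <- 1
    tr <- d > r0 & d <= r_cpp
    m[tr] <- 0.5 * (1 + cos(pi * (d[tr] - r0) / (r_cpp - r0)))
    m
  }
}

#' Extract the complex object wave from an off-axis hologram
#'
#' Masks the spectrum around the sideband peak, re-centres the masked
#' region on DC (removing the linear phase of the off-axis tilt down to
#' its sub-bin residual) and inverse-transforms.  The returned field's
#' phase (atan2, in (-pi, pi]) is the wrapped object phase.
#'
#' @param holo a `hologram` or intensity matrix.
#' @param sb a `sideband_info` from [locate_sideband()] (located
#'   automatically when `NULL`).
#' @param params a [recon_params()].
#' @return a [complex_field()].
#' @export
extract_object_wave <- function(holo, sb = NULL, params = recon_params()) {
  I <- holo_intensity(holo)
  ny <- nrow(I); nx <- ncol(I)
  if (is.null(sb)) sb <- locate_sideband(I, params)
  r_mask <- params$mask_fraction * sb$carrier_dist_cpp
  if (sb$carrier_dist_cpp - r_mask <= params$dc_exclude_cpp)
    stop_config(paste0("sideband mask (radius %.3f cyc/px) would reach into",
                       " the zero-order region (carrier distance %.3f,",
                       " DC zone %.3f cyc/px)"),
                r_mask, sb$carrier_dist_cpp, params$dc_exclude_cpp)
  S <- fft(I)
  S <- S * sideband_mask(ny, nx, sb$peak_bin[1], sb$peak_bin[2],
                         r_mask, params$mask_shape)
  # shift the peak bin onto DC: removes the integer part of the carrier
  S <- circshift(S, -(sb$peak_bin[1] - 1L), -(sb$peak_bin[2] - 1L))
  fld <- fft(S, inverse = TRUE) / (ny * nx)
  pitch <- if (inherits(holo, "hologram")) holo$config$pixel_pitch_um
           else params$pixel_pitch_um
  complex_field(fld, pixel_pitch_um = pitch,
                wavelength_nm = params$wavelength_nm)
}

# spectral concentration metric used for curvature refinement
spectral_sharpness <- function(field, a, r2) {
  max(Mod(fft(field * exp(-1i * a * r2))))
}

#' Compensate the quadratic (spherical) phase aberration
#'
#' The coarse curvature estimate follows from the sideband size: a
#' quadratic phase `a * r^2` (r in pixels) broadens the sideband to a
#' radius of about `a * N / (2 * pi)` cycles/pixel, so
#' `a0 = 2 * pi * support_radius / N`.  The estimate is refined by
#' maximizing the spectral concentration (peak magnitude) of the
#' compensated field over a bracket around `a0`, and the correction
#' `exp(-i * a * r^2)` is applied only when it concentrates the spectrum
#' appreciably (> 10\%) over the uncompensated field, so aberration-free
#' input passes through unchanged.
#'
#' @param field a [complex_field()] from [extract_object_wave()].
#' @param sb the `sideband_info` used for extraction.
#' @param params a [recon_params()].
#' @return a [complex_field()]; attribute `"curvature"` holds the applied
#'   coefficient (rad/pixel^2, 0 when not applied).
#' @export
compensate_spherical <- function(field, sb, params = recon_params()) {
  stopifnot(inherits(field, "complex_field"))
  F <- field$field
  ny <- nrow(F); nx <- ncol(F)
  n_eff <- max(ny, nx)
  a_bound <- pi / n_eff        # Nyquist-consistent curvature bound
  a0 <- 2 * pi * sb$support_radius_cpp / n_eff
  if (sb$support_radius_cpp <= 2 / n_eff) {
    attr(field, "curvature") <- 0
    return(field)              # support within two bins: nothing to fit
  }
  if (a0 > a_bound) {
    warning("estimated aberration curvature exceeds the Nyquist bound; ",
            "compensation skipped")
    attr(field, "curvature") <- 0
    return(field)
  }
  r2 <- radius2_px(ny, nx)
  a_hi <- min(a_bound, 1.5 * a0)
  grid <- seq(0, a_hi, length.out = 41)
  sharp <- vapply(grid, function(a) spectral_sharpness(F, a, r2), numeric(1))
  i_best <- which.max(sharp)
  lo <- grid[max(1, i_best - 1)]; hi <- grid[min(length(grid), i_best + 1)]
  opt <- optimize(function(a) spectral_sharpness(F, a, r2),
                  interval = c(lo, hi), maximum = TRUE,
                  tol = 1e-6 * max(a_hi, 1e-12))
  a_hat <- opt$maximum
  if (opt$objective <= 1.1 * sharp[1]) {
    attr(field, "curvature") <- 0
    return(field)              # no appreciable aberration present
  }
  out <- complex_field(F * exp(-1i * a_hat * r2),
                       pixel_pitch_um = field$pixel_pitch_um,
                       wavelength_nm = field$wavelength_nm)
  attr(out, "curvature") <- a_hat
  out
}

# free-space angular-spectrum propagation by z micrometres
propagate <- function(field, z_um) {
  stopifnot(inherits(field, "complex_field"))
  if (z_um == 0) return(field)
  F <- field$field
  ny <- nrow(F); nx <- ncol(F)
  lam <- field$wavelength_nm / 1000           # um
  fy <- freq_axis(ny) / field$pixel_pitch_um  # cycles/um
  fx <- freq_axis(nx) / field$pixel_pitch_um
  f2 <- outer(fy^2, fx^2, `+`)
  arg <- 1 / lam^2 - f2
  kern <- matrix(0 + 0i, ny, nx)
  ok <- arg > 0                               # evanescent frequencies zeroed
  kern[ok] <- exp(2i * pi * z_um * sqrt(arg[ok]))
  out <- fft(fft(F) * kern, inverse = TRUE) / (ny * nx)
  complex_field(out, pixel_pitch_um = field$pixel_pitch_um,
                wavelength_nm = field$wavelength_nm)
}

#' Numerically refocus an object wave
#'
#' Multiplies the field's spectrum by the free-space transfer kernel for
#' distance `z_um` (convolution approach) and inverse-transforms.
#' Frequencies beyond 1/lambda (evanescent) are zeroed.
#' `refocus(refocus(U, z), -z)` recovers `U` for band-limited fields.
#'
#' @param field a [complex_field()].
#' @param z_um propagation distance (um; positive = away from camera).
#' @param params optional [recon_params()] supplying wavelength/pitch when
#'   the field lacks them.
#' @return a [complex_field()].
#' @export
refocus <- function(field, z_um, params = NULL) {
  if (!is.null(params)) {
    field$wavelength_nm <- field$wavelength_nm %||% params$wavelength_nm
    field$pixel_pitch_um <- field$pixel_pitch_um %||% params$pixel_pitch_um
  }
  propagate(field, z_um)
}

#' Unwrap a modulo-2*pi phase image
#'
#' Two-dimensional reliability-sorted (quality-guided) unwrapping.  The
#' result is congruent to the input modulo 2*pi at every pixel and is
#' normalized by a global 2*pi*k shift so the background mode lies near
#' zero.
#'
#' @param phase_mod_2pi matrix of wrapped phase in (-pi, pi], or a
#'   [phase_map()].
#' @param pixel_pitch_um pitch for the returned map when a bare matrix is
#'   given.
#' @return a [phase_map()] of continuous phase.
#' @export
unwrap_phase <- function(phase_mod_2pi, pixel_pitch_um = 0.879) {
  if (inherits(phase_mod_2pi, "phase_map")) {
    pm <- phase_mod_2pi
    w <- pm$phase
  } else {
    pm <- NULL
    w <- phase_mod_2pi
  }
  stopifnot(is.matrix(w))
  un <- .unwrap2d_cpp(w)
  # global 2*pi*k normalization: background mode near zero
  h <- hist(un, breaks = seq(min(un) - 0.1, max(un) + 0.2, by = 0.1),
            plot = FALSE)
  mode_val <- h$mids[which.max(h$counts)]
  un <- un - 2 * pi * round(mode_val / (2 * pi))
  if (!is.null(pm)) { pm$phase <- un; pm }
  else phase_map(un, pixel_pitch_um = pixel_pitch_um)
}

#' Average unwrapped phase maps
#'
#' Pixelwise arithmetic mean of phase maps sharing one grid geometry;
#' used to suppress coherence-induced disturbances across the frames of
#' one timepoint.
#'
#' @param phases list of [phase_map()] objects (length >= 1).
#' @return a [phase_map()].
#' @export
average_phases <- function(phases) {
  stopifnot(is.list(phases), length(phases) >= 1)
  ref <- phases[[1]]
  stopifnot(inherits(ref, "phase_map"))
  dims <- dim(ref$phase)
  acc <- matrix(0, dims[1], dims[2])
  for (p in phases) {
    if (!inherits(p, "phase_map") || !all(dim(p$phase) == dims) ||
        p$pixel_pitch_um != ref$pixel_pitch_um)
      stop_data("phase maps must share grid geometry")
    acc <- acc + p$phase
  }
  out <- ref
  out$phase <- acc / length(phases)
  out
}

#' Reconstruct an averaged phase map from a hologram stack
#'
#' Full per-timepoint chain: per frame, sideband extraction, aberration
#' compensation (curvature estimated once on the first frame and reused;
#' the aberration is static within a timepoint), optional refocusing,
#' atan2 phase and unwrapping; the unwrapped maps are then averaged.
#'
#' @param holos list of `hologram` objects (one timepoint, >= 1 frame).
#' @param params a [recon_params()].
#' @param verbose emit per-frame diagnostic messages.
#' @return an averaged [phase_map()].
#' @export
reconstruct_stack <- function(holos, params = recon_params(),
                              verbose = FALSE) {
  stopifnot(is.list(holos), length(holos) >= 1)
  curvature <- NULL
  maps <- lapply(seq_along(holos), function(k) {
    sb <- locate_sideband(holos[[k]], params)
    fld <- extract_object_wave(holos[[k]], sb, params)
    if (params$compensate) {
      if (is.null(curvature)) {
        fld <- compensate_spherical(fld, sb, params)
        curvature <<- attr(fld, "curvature")
      } else if (curvature != 0) {
        r2 <- radius2_px(nrow(fld$field), ncol(fld$field))
        fld$field <- fld$field * exp(-1i * curvature * r2)
      }
    }
    if (params$refocus_um != 0) fld <- refocus(fld, params$refocus_um)
    if (verbose)
      message(sprintf(
        "frame %d: sideband (%.3f, %.3f) cyc/px, support %.3f, curv %.2e",
        k, sb$peak_cpp[1], sb$peak_cpp[2], sb$support_radius_cpp,
        curvature %||% 0))
    pm <- unwrap_phase(Arg(fld$field), pixel_pitch_um = fld$pixel_pitch_um)
    pm$wavelength_nm <- params$wavelength_nm
    pm$time_h <- if (inherits(holos[[k]], "hologram")) holos[[k]]$time_h
                 else NULL
    pm
  })
  average_phases(maps)
}
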