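# Off-axis hologram forward model: carrier fringes, quadratic (spherical)
# aberration, defocus, per-frame decorrelated coherent noise, detector
# noise.  The reference tilt is exp(-2*pi*i*(fx*x + fy*y)), so the
# sideband that carries the object wave O (phase positive for
# n_cell > n_medium) appears at +carrier in the spectrum.

#' Optical configuration of the virtual microscope
#'
#' @param wavelength_nm laser wavelength (nm); 532 nm by default.
#' @param pixel_pitch_um camera pixel pitch referred to the sample plane.
#' @param carrier_cpp off-axis carrier frequency, cycles/pixel, as
#'   (fx, fy); both components must satisfy 0 < |f| < 0.5 (Nyquist).
#' @param reference_amplitude,object_amplitude wave amplitudes (> 0).
#' @param aberration_rad_px2 quadratic (spherical) phase coefficient in
#'   rad/pixel^2 applied as `a * r^2` about the grid centre.
#' @param defocus_um defocus distance (um); the object wave is propagated
#'   by this distance before interference.
#' @param coherent_sigma_rad std of the smooth per-frame random phase
#'   screen emulating frame-to-frame decorrelation of the illumination.
#' @param coherent_corr_px correlation length of the phase screen (px).
#' @param detector_sigma additive detector noise std (intensity counts).
#' @param frames_per_timepoint holograms recorded per position and
#'   timepoint (default 15).
#' @param quantize_8bit optional 8-bit intensity quantization.
#' @return an `optical_config`.
#' @export
optical_config <- function(wavelength_nm = 532, pixel_pitch_um = 0.879,
                           carrier_cpp = c(0.25, 0.25),
                           reference_amplitude = 1, object_amplitude = 1,
                           aberration_rad_px2 = 0, defocus_um = 0,
                           coherent_sigma_rad = 0, coherent_corr_px = 8,
                           detector_sigma = 0,
                           frames_per_timepoint = 15L,
                           quantize_8bit = FALSE) {
  if (any(abs(carrier_cpp) <= 0) || any(abs(carrier_cpp) >= 0.5))
    stop_config("carrier components must satisfy 0 < |f| < 0.5 cycles/pixel")
  if (reference_amplitude <= 0 || object_amplitude < 0)
    stop_config("reference amplitude must be > 0, object amplitude >= 0")
  if (frames_per_timepoint < 1)
    stop_config("frames_per_timepoint must be >= 1")
  structure(list(wavelength_nm = wavelength_nm,
                 pixel_pitch_um = pixel_pitch_um,
                 carrier_cpp = as.numeric(carrier_cpp),
                 reference_amplitude = reference_amplitude,
                 object_amplitude = object_amplitude,
                 aberration_rad_px2 = aberration_rad_px2,
                 defocus_um = defocus_um,
                 coherent_sigma_rad = coherent_sigma_rad,
                 coherent_corr_px = coherent_corr_px,
                 detector_sigma = detector_sigma,
                 frames_per_timepoint = as.integer(frames_per_timepoint),
                 quantize_8bit = isTRUE(quantize_8bit)),
            class = "optical_config")
}

# squared radius (px^2) about the grid centre, rows = y
radius2_px <- function(ny, nx) {
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  outer(((0:(ny - 1)) - cy)^2, ((0:(nx - 1)) - cx)^2, `+`)
}

#' Forward object wave of a phase map
#'
#' Builds `object_amplitude * exp(i * phase)`, applies the quadratic
#' aberration phase `exp(i * a * r^2)` and, if `defocus_um` is non-zero,
#' propagates the field by that distance (angular-spectrum kernel).
#'
#' @param phase a [phase_map()] whose grid matches the configuration.
#' @param config an [optical_config()].
#' @return a [complex_field()].
#' @export
object_wave <- function(phase, config) {
  stopifnot(inherits(phase, "phase_map"), inherits(config, "optical_config"))
  ny <- nrow(phase$phase); nx <- ncol(phase$phase)
  ph <- phase$phase
  if (config$aberration_rad_px2 != 0)
    ph <- ph + config$aberration_rad_px2 * radius2_px(ny, nx)
  fld <- complex_field(config$object_amplitude * exp(1i * ph),
                       pixel_pitch_um = phase$pixel_pitch_um,
                       wavelength_nm = config$wavelength_nm)
  if (config$defocus_um != 0)
    fld <- propagate(fld, config$defocus_um)
  fld
}

# smooth random phase screen: low-pass-filtered white noise rescaled to
# the requested std (returns a zero matrix when sigma == 0)
phase_screen <- function(ny, nx, sigma, corr_px, seed) {
  if (sigma <= 0) return(matrix(0, ny, nx))
  with_seed(seed, {
    w <- matrix(rnorm(ny * nx), ny, nx)
    fy <- freq_axis(ny); fx <- freq_axis(nx)
    f2 <- outer(fy^2, fx^2, `+`)
    filt <- exp(-2 * (pi * corr_px)^2 * f2)
    s <- Re(fft(fft(w) * filt, inverse = TRUE)) / (ny * nx)
    sigma * (s - mean(s)) / sd(s)
  })
}

#' Record one off-axis hologram
#'
#' Intensity \eqn{|O e^{i\eta} + R|^2} with a tilted plane reference
#' \eqn{R = A_r \exp(-2\pi i (f_x x + f_y y))}, a smooth per-frame
#' coherent phase perturbation \eqn{\eta} and additive detector noise;
#' intensity is clipped at zero.
#'
#' @param object a [complex_field()] from [object_wave()].
#' @param config an [optical_config()].
#' @param seed integer seed for the noise realizations.
#' @param time_h,frame metadata recorded on the hologram.
#' @return a `hologram`.
#' @export
interfere <- function(object, config, seed = 1L, time_h = 0, frame = 1L) {
  stopifnot(inherits(object, "complex_field"),
            inherits(config, "optical_config"))
  if (any(abs(config$carrier_cpp) >= 0.5))
    stop_config("carrier at or above Nyquist would alias")
  O <- object$field
  ny <- nrow(O); nx <- ncol(O)
  eta <- phase_screen(ny, nx, config$coherent_sigma_rad,
                      config$coherent_corr_px, derive_seed(seed, 1))
  x <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  y <- matrix(0:(ny - 1), ny, nx)
  Rw <- config$reference_amplitude *
    exp(-2i * pi * (config$carrier_cpp[1] * x + config$carrier_cpp[2] * y))
  I <- Mod(O * exp(1i * eta) + Rw)^2
  if (config$detector_sigma > 0)
    I <- I + with_seed(derive_seed(seed, 2),
                       matrix(rnorm(ny * nx, sd = config$detector_sigma),
                              ny, nx))
  I <- pmax(I, 0)
  if (config$quantize_8bit)
    I <- round(I / max(I) * 255) / 255 * max(I)
  new_hologram(I, config, time_h = time_h, frame = frame, seed = seed)
}

#' Verify off-axis carrier separation
#'
#' Checks that the sideband (object bandwidth around the carrier) stays
#' clear of the zero-order term (width twice the object bandwidth):
#' requires carrier distance > 3x the object's spectral support radius.
#' Warns when the orders would overlap; never stops the simulation.
#'
#' @param object a [complex_field()] (the object wave).
#' @param config an [optical_config()].
#' @return the estimated object bandwidth (cycles/pixel), invisibly.
#' @export
verify_carrier_separation <- function(object, config) {
  S <- Mod(fft(object$field))
  ny <- nrow(S); nx <- ncol(S)
  f2 <- outer(freq_axis(ny)^2, freq_axis(nx)^2, `+`)
  thr <- 0.01 * max(S)
  bw <- sqrt(max(f2[S >= thr]))
  sep <- sqrt(sum(config$carrier_cpp^2))
  if (sep <= 3 * bw)
    warning(sprintf(paste0(
      "carrier distance %.3f cyc/px does not separate the image orders ",
      "(object bandwidth ~%.3f cyc/px); expect zero-order contamination"),
      sep, bw))
  invisible(bw)
}

#' Acquire a multi-frame hologram stack for one timepoint
#'
#' Renders the scene phase once, then records
#' `config$frames_per_timepoint` holograms with independent coherent and
#' detector noise realizations (seed stream derived from `seed`, `t` and
#' the frame index).  Pure function of (scene, config, t, seed).
#'
#' @param scene a `dhm_scene`.
#' @param config an [optical_config()].
#' @param t acquisition time (h), recorded as metadata.
#' @param seed master seed for the stack.
#' @param check_separation warn if the carrier does not separate the
#'   image orders (see [verify_carrier_separation()]).
#' @return list of `hologram` objects, length `frames_per_timepoint`.
#' @export
acquire_timepoint <- function(scene, config, t = 0, seed = 1L,
                              check_separation = FALSE) {
  stopifnot(inherits(scene, "dhm_scene"))
  ph <- render_phase(scene, wavelength_nm = config$wavelength_nm)
  obj <- object_wave(ph, config)
  if (check_separation) verify_carrier_separation(obj, config)
  lapply(seq_len(config$frames_per_timepoint), function(k)
    interfere(obj, config, seed = derive_seed(seed, t * 2, k),
              time_h = t, frame = k))
}
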