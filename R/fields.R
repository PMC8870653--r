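# Core raster containers: phase maps, complex object waves, holograms.

#' Quantitative phase map
#'
#' @param phase real matrix of unwrapped phase values in radians
#'   (rows = y, columns = x).
#' @param pixel_pitch_um pixel pitch in the sample plane (um/pixel).
#' @param wavelength_nm illumination wavelength (nm), if known.
#' @param time_h acquisition time in hours, if known.
#' @param background_corrected logical flag set by the background stage.
#' @return an object of class `phase_map`.
#' @export
phase_map <- function(phase, pixel_pitch_um, wavelength_nm = NULL,
                      time_h = NULL, background_corrected = FALSE) {
  stopifnot(is.matrix(phase), is.numeric(phase))
  if (!is_scalar_num(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop_config("pixel pitch must be > 0")
  structure(list(phase = phase, pixel_pitch_um = pixel_pitch_um,
                 wavelength_nm = wavelength_nm, time_h = time_h,
                 background_corrected = isTRUE(background_corrected)),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map %d x %d px, pitch %.4g um/px%s>\n",
              nrow(x$phase), ncol(x$phase), x$pixel_pitch_um,
              if (x$background_corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Complex object wave sampled on the camera grid
#'
#' @param field complex matrix.
#' @param pixel_pitch_um pixel pitch (um/pixel).
#' @param wavelength_nm wavelength (nm).
#' @return an object of class `complex_field`.
#' @export
complex_field <- function(field, pixel_pitch_um, wavelength_nm = 532) {
  stopifnot(is.matrix(field))
  structure(list(field = field, pixel_pitch_um = pixel_pitch_um,
                 wavelength_nm = wavelength_nm),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field %d x %d px, pitch %.4g um/px>\n",
              nrow(x$field), ncol(x$field), x$pixel_pitch_um))
  invisible(x)
}

new_hologram <- function(intensity, config, time_h = 0, frame = 1L,
                         seed = NA_integer_) {
  structure(list(intensity = intensity, config = config, time_h = time_h,
                 frame = as.integer(frame), seed = seed),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram %d x %d px, t = %.2f h, frame %d>\n",
              nrow(x$intensity), ncol(x$intensity), x$time_h, x$frame))
  invisible(x)
}
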