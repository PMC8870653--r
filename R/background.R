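# Rolling-ball background subtraction: the background is the grayscale
# morphological opening of the phase image by a spherical-cap structuring
# element, i.e. the upper envelope traced by a ball rolled under the
# surface.  Fixed parameters are meant to be shared across experiments.

#' Rolling-ball parameters
#'
#' @param radius_px ball radius in pixels.  Must exceed the largest cell
#'   footprint radius so cellular signal is bridged, not subtracted; the
#'   default 50 px (about 44 um at 0.879 um/pixel) is several cell radii.
#' @param height_scale ball aspect: phase drop (radians) per pixel of cap
#'   height.  Sets the ball curvature `height_scale / radius_px`
#'   (rad/pixel^2); backgrounds with smaller curvature are followed
#'   exactly while narrow cellular peaks are bridged.
#' @param smooth_px width (pixels, odd) of the mean pre-filter applied to
#'   the copy on which the background is estimated; the estimate is then
#'   subtracted from the unsmoothed image.  This mirrors the smoothing
#'   step of the standard rolling-ball implementation and prevents the
#'   opening from tracking noise minima (which would bias masses
#'   upward).  Set to 1 for the pure opening.
#' @param zero_mode re-zero the corrected map on its phase mode (the
#'   specimen-free level defines zero; the mode is background as long as
#'   cells cover less than half the FOV).  This removes the small
#'   constant offset left when the opening tracks minima of residual
#'   reconstruction ripple.
#' @param light_background set when features are phase minima (not the
#'   case for cells, which are phase maxima; default FALSE).
#' @return a `background_params` object.
#' @export
background_params <- function(radius_px = 50, height_scale = 0.005,
                              smooth_px = 5, zero_mode = TRUE,
                              light_background = FALSE) {
  if (!is_scalar_num(radius_px) || radius_px < 1)
    stop_config("ball radius must be >= 1 pixel")
  if (!is_scalar_num(height_scale) || height_scale <= 0)
    stop_config("height scale must be > 0")
  if (!is_scalar_num(smooth_px) || smooth_px < 1 || smooth_px %% 2 != 1)
    stop_config("smooth_px must be an odd integer >= 1")
  structure(list(radius_px = radius_px, height_scale = height_scale,
                 smooth_px = as.integer(smooth_px),
                 zero_mode = isTRUE(zero_mode),
                 light_background = isTRUE(light_background)),
            class = "background_params")
}

# separable box blur with edge replication
box_blur <- function(m, k) {
  if (k <= 1) return(m)
  h <- (k - 1) / 2
  pad_idx <- function(n) c(rep(1, h), seq_len(n), rep(n, h))
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
  kern <- rep(1 / k, k)
  sm <- apply(mp, 2, function(cl) stats::filter(cl, kern))
  sm <- t(apply(sm, 1, function(r) stats::filter(r, kern)))
  sm[(h + 1):(h + nrow(m)), (h + 1):(h + ncol(m))]
}

#' Subtract the rolling-ball background from a phase map
#'
#' Computes background = opening(phase) = dilate(erode(phase)) with a
#' spherical-cap structuring element and returns phase - background.
#' The output is >= 0 where the surface is ball-touchable, background
#' regions end up near zero, and cellular features narrower than the
#' ball are preserved.
#'
#' @param phase a [phase_map()] (or bare matrix).
#' @param params a [background_params()].
#' @return a background-corrected [phase_map()] (flag set), or a matrix
#'   when a matrix was supplied.
#' @export
rolling_ball_subtract <- function(phase, params = background_params()) {
  stopifnot(inherits(params, "background_params"))
  m <- if (inherits(phase, "phase_map")) phase$phase else phase
  stopifnot(is.matrix(m))
  if (params$radius_px >= min(dim(m)))
    stop_config("ball radius (%g px) must be smaller than the image (%d x %d)",
                params$radius_px, nrow(m), ncol(m))
  sgn <- if (params$light_background) -1 else 1
  est <- box_blur(sgn * m, params$smooth_px)
  bg <- sgn * .ball_dilate_cpp(
    .ball_erode_cpp(est, params$radius_px, params$height_scale),
    params$radius_px, params$height_scale)
  out <- m - bg
  if (params$zero_mode && diff(range(out)) > 1e-12) {
    d <- stats::density(out, n = 512)
    out <- out - d$x[which.max(d$y)]
  }
  if (inherits(phase, "phase_map")) {
    phase$phase <- out
    phase$background_corrected <- TRUE
    phase
  } else out
}
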