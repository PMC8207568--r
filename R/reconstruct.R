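#' Background-normalize a hologram to a contrast field
#'
#' Divides the recorded intensity by a reference and subtracts one, yielding
#' a zero-mean contrast field for object-free holograms. With an explicit
#' `reference` hologram (e.g. an object-free frame) the normalization is
#' `intensity / reference - 1`; without one, a Gaussian low-pass of the
#' hologram itself estimates the illumination envelope, which also removes
#' the radial vignette of the point source.
#'
#' @param h A `dihm_hologram`.
#' @param reference Optional `dihm_hologram` of matching size with strictly
#'   positive intensity.
#' @param sigma Low-pass standard deviation in pixels for the self-reference
#'   mode. Default `sensor_pixels / 8`: wide enough to pass the illumination
#'   envelope through while leaving plankton-scale structure in the contrast.
#' @return Numeric contrast matrix.
#' @export
background_normalize <- function(h, reference = NULL, sigma = NULL) {
  stopifnot(inherits(h, "dihm_hologram"))
  intensity <- h$intensity * 1.0
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "dihm_hologram")) reference$intensity
           else reference
    if (!all(dim(ref) == dim(intensity))) {
      stop("reference dimensions must match the hologram", call. = FALSE)
    }
    if (any(ref <= 0)) {
      stop("reference must be strictly positive everywhere", call. = FALSE)
    }
    return(intensity / ref - 1)
  }
  sigma <- sigma %||% (h$geometry$sensor_pixels / 8)
  lp <- gaussian_lowpass(intensity, sigma)
  lp[lp <= 0] <- mean(intensity)
  intensity / lp - 1
}

# FFT-based Gaussian low-pass filter. The input is mirror-extended to
# 2n x 2n before the periodic FFT so the blur sees symmetric, not
# wrapped-around, boundaries; the original quadrant is returned.
gaussian_lowpass <- function(x, sigma) {
  n <- nrow(x)
  m <- ncol(x)
  big <- rbind(cbind(x, x[, m:1]), cbind(x[n:1, ], x[n:1, m:1]))
  nb <- nrow(big)
  f <- fft_freq(nb, 1)
  g <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, `+`))
  sm <- Re(stats::fft(stats::fft(big) * g, inverse = TRUE)) / length(big)
  sm[seq_len(n), seq_len(m)]
}

#' Reconstruct the wavefield at one z-plane
#'
#' Re-adds the unit reference wave to the normalized contrast, apodizes the
#' contrast with a cosine border to suppress FFT wraparound, and
#' back-propagates by the plane's effective distance expressed in sensor
#' coordinates (`z_eff * M^2`, Fresnel scaling), the exact inverse of the
#' forward model's recording frame. The
#' recorded amplitude shows absorbing objects dark on a bright (~1)
#' background; `mode = "intensity"` records the squared magnitude instead.
#' The plane carries its object-plane pixel size `pixel_pitch / M(z)`.
#'
#' @param h A `dihm_hologram`.
#' @param z Plane distance from the point source (um), in
#'   `(0, source_to_camera)`.
#' @param contrast Optional precomputed [background_normalize()] output.
#' @param mode `"amplitude"` (default) or `"intensity"`.
#' @param apodize_px Cosine-taper border width in pixels (default 16; 0
#'   disables).
#' @return A `dihm_plane` with fields `z`, `amplitude`, `object_pixel_size`.
#' @export
reconstruct_plane <- function(h, z, contrast = NULL, mode = "amplitude",
                              apodize_px = 16) {
  stopifnot(inherits(h, "dihm_hologram"))
  check_z_domain(h$geometry, z)
  contrast <- contrast %||% background_normalize(h)
  w <- apodize_window(nrow(contrast), apodize_px)
  field <- 1 + contrast * w
  u <- propagate(field, -sensor_distance(h$geometry, z),
                 h$geometry$wavelength, h$geometry$pixel_pitch)
  amp <- if (mode == "intensity") Mod(u)^2 else Mod(u)
  new_plane(z, amp, object_pixel_size(h$geometry, z))
}

object_pixel_size <- function(geometry, z) {
  geometry$pixel_pitch / magnification(geometry, z)
}

new_plane <- function(z, amplitude, object_pixel_size) {
  structure(list(z = z, amplitude = amplitude,
                 object_pixel_size = object_pixel_size),
            class = "dihm_plane")
}

#' Reconstruct a z-stack through the sample space
#'
#' One [reconstruct_plane()] per scheduled z-distance (default: the
#' geometry's [plane_schedule()], e.g. 300 planes for a 15 mm sample space
#' at a 50 um step). The contrast field and its forward FFT are computed
#' once and reused across planes.
#'
#' @inheritParams reconstruct_plane
#' @param schedule Ascending z-distances (um). Default [plane_schedule()].
#' @return A `dihm_stack`: ordered list of planes by ascending z.
#' @export
reconstruct_stack <- function(h, schedule = NULL, contrast = NULL,
                              mode = "amplitude", apodize_px = 16) {
  stopifnot(inherits(h, "dihm_hologram"))
  schedule <- schedule %||% plane_schedule(h$geometry)
  if (length(schedule) == 0) stop("schedule must be non-empty", call. = FALSE)
  if (is.unsorted(schedule, strictly = TRUE)) {
    stop("schedule must be strictly ascending", call. = FALSE)
  }
  contrast <- contrast %||% background_normalize(h)
  n <- nrow(contrast)
  field <- 1 + contrast * apodize_window(n, apodize_px)
  spec <- stats::fft(field)
  g <- h$geometry
  planes <- lapply(schedule, function(z) {
    pitch <- object_pixel_size(g, z)
    k <- as_kernel(n, -sensor_distance(g, z), g$wavelength, g$pixel_pitch,
                   band_limit = TRUE)
    u <- stats::fft(spec * k, inverse = TRUE) / length(field)
    amp <- if (mode == "intensity") Mod(u)^2 else Mod(u)
    new_plane(z, amp, pitch)
  })
  structure(list(planes = planes, geometry = g, source = h$provenance),
            class = "dihm_stack")
}

#' @export
print.dihm_stack <- function(x, ...) {
  zs <- vapply(x$planes, `[[`, numeric(1), "z")
  cat(sprintf("<dihm_stack> %d planes, z in [%g, %g] um\n",
              length(zs), min(zs), max(zs)))
  invisible(x)
}

#' @export
print.dihm_plane <- function(x, ...) {
  cat(sprintf("<dihm_plane> z = %g um, %d x %d, %.3f um/px\n",
              x$z, nrow(x$amplitude), ncol(x$amplitude),
              x$object_pixel_size))
  invisible(x)
}
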