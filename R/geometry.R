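#' Optical geometry of a point-source in-line holographic microscope
#'
#' Describes a Gabor-style lensless geometry: a point source emitting
#' spherical waves, a sample space bounded by `z_min`/`z_max` (distances from
#' the source), and a square sensor at `source_to_camera`. All lengths are in
#' micrometres. Defaults follow a submersible DIHM with a 405 nm solid-state
#' laser, the camera 54 mm from the point source, a 2048 x 2048 sensor, and a
#' 15 mm sample space reconstructed at a 50 um step.
#'
#' The sensor pixel pitch is an instrument property not fixed by the optical
#' layout; it is a required configuration value with a documented default of
#' 5.5 um (a typical machine-vision CMOS pitch). Every physical-size
#' computation reads the pitch from the geometry object.
#'
#' @param wavelength Laser wavelength (um). Default 0.405.
#' @param source_to_camera Point source to sensor distance (um). Default 54000.
#' @param sensor_pixels Sensor side length in pixels. Default 2048; tests and
#'   examples use smaller grids.
#' @param pixel_pitch Sensor pixel pitch (um). Default 5.5.
#' @param z_min,z_max Bounds of the sample space, as distances from the point
#'   source (um). Defaults 2000 and 17000, spanning 15 mm.
#' @param z_step Reconstruction step (um). Default 50.
#' @param bit_depth Sensor quantization depth. Default 8.
#'
#' @return An object of class `dihm_geometry` (a named list).
#' @examples
#' g <- optical_geometry(sensor_pixels = 512)
#' magnification(g, 27000)
#' @export
optical_geometry <- function(wavelength = 0.405,
                             source_to_camera = 54000,
                             sensor_pixels = 2048,
                             pixel_pitch = 5.5,
                             z_min = 2000,
                             z_max = 17000,
                             z_step = 50,
                             bit_depth = 8) {
  stopifnot(wavelength > 0, pixel_pitch > 0, z_step > 0)
  if (!(0 < z_min && z_min < z_max && z_max < source_to_camera)) {
    stop("require 0 < z_min < z_max < source_to_camera", call. = FALSE)
  }
  if (sensor_pixels < 8) stop("sensor_pixels must be >= 8", call. = FALSE)
  structure(
    list(
      wavelength = wavelength,
      source_to_camera = source_to_camera,
      sensor_pixels = as.integer(sensor_pixels),
      pixel_pitch = pixel_pitch,
      z_min = z_min,
      z_max = z_max,
      z_step = z_step,
      bit_depth = as.integer(bit_depth)
    ),
    class = "dihm_geometry"
  )
}

#' @export
print.dihm_geometry <- function(x, ...) {
  cat("<dihm_geometry>\n")
  cat(sprintf("  wavelength      %g um\n", x$wavelength))
  cat(sprintf("  source->camera  %g um\n", x$source_to_camera))
  cat(sprintf("  sensor          %d x %d px @ %g um\n",
              x$sensor_pixels, x$sensor_pixels, x$pixel_pitch))
  cat(sprintf("  sample space    [%g, %g] um, step %g um (%d planes)\n",
              x$z_min, x$z_max, x$z_step, length(plane_schedule(x))))
  invisible(x)
}

#' Transverse magnification of the point-source geometry
#'
#' With the source-to-camera distance `L` and an object at distance `z_obj`
#' from the point source, the spherical reference wave magnifies the object
#' by `M = L / z_obj` at the sensor.
#'
#' @param geometry A [optical_geometry()] object.
#' @param z_obj Object distance from the point source (um), in
#'   `(0, source_to_camera)`.
#' @return Magnification `M > 1`.
#' @examples
#' magnification(optical_geometry(), 27000) # 2
#' @export
magnification <- function(geometry, z_obj) {
  check_z_domain(geometry, z_obj)
  geometry$source_to_camera / z_obj
}

#' Effective propagation distance under the Fresnel scaling theorem
#'
#' A hologram recorded with a point source at `z1 = z_obj` in front of the
#' object and the sensor `z2 = L - z_obj` behind it is equivalent to a
#' plane-wave hologram of the same object recorded at the effective distance
#' `z_eff = z1 * z2 / (z1 + z2)`, with the transverse scale magnified by
#' [magnification()]. This maps spherical-wave recording onto an ordinary
#' plane-wave diffraction problem on a regular grid.
#'
#' @inheritParams magnification
#' @return Effective distance (um); `0 < z_eff < min(z1, z2)`.
#' @examples
#' effective_distance(optical_geometry(), 27000) # 13500
#' @export
effective_distance <- function(geometry, z_obj) {
  check_z_domain(geometry, z_obj)
  z1 <- z_obj
  z2 <- geometry$source_to_camera - z_obj
  z1 * z2 / (z1 + z2)
}

# The same effective distance expressed in (magnified) sensor coordinates:
# z_eff * M(z)^2 = L (L - z) / z. Propagating the magnified object by this
# distance at the sensor pitch is the plane-wave problem the sensor grid
# actually samples, and gives one shared frame for multi-plane scenes.
sensor_distance <- function(geometry, z_obj) {
  effective_distance(geometry, z_obj) * magnification(geometry, z_obj)^2
}

check_z_domain <- function(geometry, z_obj) {
  if (any(z_obj <= 0 | z_obj >= geometry$source_to_camera)) {
    stop("z_obj must lie strictly between 0 and source_to_camera",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reconstruction plane schedule
#'
#' z-distances at which a hologram is reconstructed: starting at `z_min` and
#' stepping by `z_step` over the half-open interval `[z_min, z_max)`, so a
#' 15 mm sample space at a 50 um step yields exactly 300 planes. Distances
#' are quantized to integer micrometres so schedules are exact.
#'
#' @param geometry A [optical_geometry()] object.
#' @return Numeric vector of z-distances (um), strictly increasing.
#' @examples
#' length(plane_schedule(optical_geometry())) # 300
#' @export
plane_schedule <- function(geometry) {
  span_um <- round(geometry$z_max) - round(geometry$z_min)
  step_um <- round(geometry$z_step)
  n <- span_um %/% step_um
  round(geometry$z_min) + step_um * (seq_len(n) - 1)
}

#' Imaged sample volume
#'
#' Volume of water imaged by a set of holograms. The flow cell holds a
#' nominal 0.1 mL per frame; because illumination falls off radially, only
#' part of that volume is effectively imaged, and the empirically derived
#' working volume is 0.063 mL per hologram. `corrected = TRUE` applies the
#' working-volume constant.
#'
#' @param n_holograms Number of holograms (>= 0).
#' @param corrected Apply the working-volume correction? Default TRUE.
#' @return Volume in mL.
#' @examples
#' imaged_volume(1000, corrected = TRUE) # 63 mL
#' @export
imaged_volume <- function(n_holograms, corrected = TRUE) {
  if (any(n_holograms < 0)) stop("n_holograms must be >= 0", call. = FALSE)
  n_holograms * if (corrected) 0.063 else 0.1
}

#' Desk-scale geometry preserving the instrument's numerical aperture
#'
#' Shrinks the full 2048-pixel, 54 mm instrument by an integer factor
#' (default 4: a 512 x 512 sensor 13.5 mm from the source with a 3.75 mm
#' sample space). Sensor side, source-to-camera distance and sample-space
#' bounds all scale together while the pixel pitch, wavelength and 50 um
#' z-step stay fixed, so the effective numerical aperture
#' `N * pitch / (2 L)` — and with it lateral resolution and depth of field —
#' matches the full-size instrument. This makes 512-pixel simulations
#' behave optically like the real device, at a fraction of the cost.
#'
#' @param scale Integer shrink factor. Default 4.
#' @param ... Overrides passed to [optical_geometry()].
#' @return A `dihm_geometry`.
#' @export
scaled_geometry <- function(scale = 4, ...) {
  args <- list(...)
  defaults <- list(
    sensor_pixels = 2048 / scale,
    source_to_camera = 54000 / scale,
    z_min = 1000,
    z_max = 1000 + 15000 / scale
  )
  defaults[names(args)] <- args
  do.call(optical_geometry, defaults)
}
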