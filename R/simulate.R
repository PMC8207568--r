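#' Scene phantom: ground-truth objects for the hologram simulator
#'
#' A phantom lists absorbing (optionally phase-shifting) objects in the
#' sample space, each a thin disc-shaped transmittance mask at a known
#' distance from the point source. Phantoms provide exact ground truth for
#' closed-loop tests of the reconstruction, detection and autofocus stages.
#'
#' @param objects Data frame with one row per object and columns
#'   `x`, `y` (lateral position, um, relative to the optical axis),
#'   `z` (distance from the point source, um),
#'   `equivalent_diameter` (um), `transmission` (amplitude factor in
#'   `[0, 1]`; 0 = opaque) and optionally `phase_shift` (radians, default 0).
#' @param noise_seed Integer seed used when shot noise is simulated.
#' @return A `dihm_phantom` object.
#' @examples
#' ph <- scene_phantom(data.frame(
#'   x = 0, y = 0, z = 5000, equivalent_diameter = 100, transmission = 0
#' ))
#' @export
scene_phantom <- function(objects = NULL, noise_seed = 1L) {
  if (is.null(objects)) {
    objects <- tibble::tibble(
      x = numeric(), y = numeric(), z = numeric(),
      equivalent_diameter = numeric(), transmission = numeric(),
      phase_shift = numeric()
    )
  }
  objects <- tibble::as_tibble(objects)
  if (!"phase_shift" %in% names(objects)) objects$phase_shift <- 0
  req <- c("x", "y", "z", "equivalent_diameter", "transmission")
  missing <- setdiff(req, names(objects))
  if (length(missing) > 0) {
    stop("phantom objects lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(objects$transmission < 0 | objects$transmission > 1)) {
    stop("transmission must lie in [0, 1]", call. = FALSE)
  }
  if (any(objects$equivalent_diameter <= 0)) {
    stop("object diameters must be > 0", call. = FALSE)
  }
  structure(list(objects = objects, noise_seed = as.integer(noise_seed)),
            class = "dihm_phantom")
}

#' Radial illumination falloff of the point source
#'
#' Central-axis illumination is brightest on the optical axis and attenuates
#' towards the hologram edges. The falloff is modeled as a radial Gaussian
#' `exp(-strength * (r / r_corner)^2)`, normalized to 1 at the center;
#' `strength = 0` gives a flat field.
#'
#' @param geometry A [optical_geometry()] object.
#' @param strength Falloff strength, >= 0.
#' @return `sensor_pixels` x `sensor_pixels` matrix with values in `(0, 1]`,
#'   maximal at the center and non-increasing with radius.
#' @export
vignette_field <- function(geometry, strength = 1) {
  if (strength < 0) stop("strength must be >= 0", call. = FALSE)
  n <- geometry$sensor_pixels
  ctr <- (n + 1) / 2
  u <- (seq_len(n) - ctr)
  r2 <- outer(u^2, u^2, `+`)
  exp(-strength * r2 / (2 * (ctr - 0.5)^2))
}

#' Simulate a point-source in-line hologram
#'
#' Scalar-diffraction forward model under the Fresnel scaling theorem:
#' objects are applied as thin transmittance masks at their planes in
#' ascending z, and the field is carried between planes and to the sensor
#' by angular-spectrum propagation. All propagation happens in sensor
#' coordinates, where each plane's effective distance is
#' `z_eff(z) * M(z)^2 = L (L - z) / z` — the plane-wave problem the sensor
#' grid samples directly, giving one shared frame in which the sequential
#' multi-plane pass is self-consistent and occlusion-preserving. The
#' recorded intensity is the squared field magnitude, optionally multiplied
#' by a radial vignette, optionally perturbed by Poisson shot noise, and
#' quantized to the sensor bit depth.
#'
#' Each object's mask is rasterized at that plane's object-plane pixel size
#' `pixel_pitch / M(z)` (equivalently: magnified by `M` on the sensor
#' grid), with edge antialiasing; a diameter below two object-plane pixels
#' is unresolvable and raises a sampling error.
#'
#' @param phantom A [scene_phantom()].
#' @param geometry A [optical_geometry()].
#' @param with_noise Add Poisson shot noise? Default FALSE.
#' @param with_vignette Multiply by [vignette_field()]? Default FALSE.
#' @param vignette_strength Passed to [vignette_field()]. Default 1.
#' @param photons Mean photon count per pixel for the shot-noise model.
#'   Default 2000 (about 2% relative noise at mid-intensity).
#' @param quantize Quantize to `2^bit_depth` levels? Default TRUE; set to
#'   FALSE to keep the floating-point intensity (useful for tests).
#' @return A `dihm_hologram` object with fields `intensity` (matrix),
#'   `geometry`, and `provenance`.
#' @export
simulate_hologram <- function(phantom, geometry,
                              with_noise = FALSE, with_vignette = FALSE,
                              vignette_strength = 1, photons = 2000,
                              quantize = TRUE) {
  stopifnot(inherits(phantom, "dihm_phantom"),
            inherits(geometry, "dihm_geometry"))
  obj <- phantom$objects
  if (nrow(obj) > 0 &&
      any(obj$z < geometry$z_min | obj$z > geometry$z_max)) {
    stop("all phantom objects must lie within [z_min, z_max]", call. = FALSE)
  }
  n <- geometry$sensor_pixels
  u <- matrix(1 + 0i, n, n)
  if (nrow(obj) > 0) {
    obj <- obj[order(obj$z), , drop = FALSE]
    d_sens <- vapply(obj$z, function(z) sensor_distance(geometry, z),
                     numeric(1)) # decreasing in z: light meets low z first
    for (i in seq_len(nrow(obj))) {
      pitch_i <- geometry$pixel_pitch / magnification(geometry, obj$z[i])
      if (i > 1 && d_sens[i] != d_sens[i - 1]) {
        u <- propagate(u, d_sens[i - 1] - d_sens[i],
                       geometry$wavelength, geometry$pixel_pitch)
      }
      u <- u * object_mask(n, pitch_i, obj$x[i], obj$y[i],
                           obj$equivalent_diameter[i],
                           obj$transmission[i], obj$phase_shift[i])
    }
    u <- propagate(u, d_sens[nrow(obj)], geometry$wavelength,
                   geometry$pixel_pitch)
  }
  intensity <- Mod(u)^2
  if (with_vignette) {
    intensity <- intensity * vignette_field(geometry, vignette_strength)
  }
  if (with_noise) {
    mu <- mean(intensity)
    if (mu > 0) {
      intensity <- with_seed(phantom$noise_seed, {
        matrix(stats::rpois(length(intensity), intensity / mu * photons),
               n, n) * mu / photons
      })
    }
  }
  if (quantize) intensity <- quantize_intensity(intensity, geometry$bit_depth)
  new_hologram(intensity, geometry,
               provenance = sprintf("simulated: %d object(s)", nrow(obj)))
}

# Antialiased thin disc transmittance mask on an n x n grid with pixel size
# `pitch` (um/px); (x, y) are offsets from the grid center in um.
object_mask <- function(n, pitch, x, y, diameter, transmission, phase_shift) {
  r_px <- (diameter / 2) / pitch
  if (2 * r_px < 2) {
    stop("object diameter below 2 object-plane pixels; increase size or ",
         "use a finer grid", call. = FALSE)
  }
  ctr <- (n + 1) / 2
  rows <- seq_len(n) - (ctr + y / pitch)
  cols <- seq_len(n) - (ctr + x / pitch)
  dist <- sqrt(outer(rows^2, cols^2, `+`))
  coverage <- clamp(r_px - dist + 0.5, 0, 1) # 1 inside, 0 outside, ramped edge
  tval <- transmission * exp(1i * phase_shift)
  1 - coverage * (1 - tval)
}

# Map intensity to integer gray levels with the mean anchored at mid-scale.
quantize_intensity <- function(intensity, bit_depth) {
  top <- 2^bit_depth - 1
  mu <- mean(intensity)
  if (mu <= 0) return(matrix(0L, nrow(intensity), ncol(intensity)))
  q <- round(intensity / mu * (2^(bit_depth - 1) - 1))
  matrix(as.integer(clamp(q, 0, top)), nrow(intensity), ncol(intensity))
}

new_hologram <- function(intensity, geometry, provenance = "") {
  if (any(intensity < 0)) stop("hologram intensity must be >= 0", call. = FALSE)
  structure(list(intensity = intensity, geometry = geometry,
                 provenance = provenance),
            class = "dihm_hologram")
}

#' @export
print.dihm_hologram <- function(x, ...) {
  cat(sprintf("<dihm_hologram> %d x %d  [%s]\n",
              nrow(x$intensity), ncol(x$intensity), x$provenance))
  invisible(x)
}
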