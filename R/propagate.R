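#' Angular-spectrum propagation of a scalar wavefield
#'
#' Advances a sampled complex field by `distance` along the optical axis by
#' multiplying its spatial-frequency spectrum with the exact scalar transfer
#' function `exp(i * 2 * pi * distance * sqrt(1/lambda^2 - fx^2 - fy^2))`.
#' Evanescent components (spatial frequencies beyond `1/lambda`) are zeroed.
#' `distance = 0` is the identity.
#'
#' With `band_limit = TRUE` (the default) the transfer function is
#' additionally capped at the band-limiting frequency
#' `f_lim = 1 / (lambda * sqrt((2 * distance * df)^2 + 1))` per axis, the
#' standard remedy for kernel undersampling when the propagation distance is
#' large relative to the grid extent; without it the sampled kernel aliases
#' and wraparound copies contaminate the field. The cap is an identity for
#' content the grid can physically carry to that distance.
#'
#' @param field Square complex (or numeric) matrix of field samples.
#' @param distance Signed propagation distance (um); negative back-propagates.
#' @param wavelength Wavelength (um).
#' @param sample_pitch Grid sample spacing (um), > 0.
#' @param band_limit Apply the band-limiting cap? Default TRUE.
#' @return Complex matrix of the propagated field, same dimensions.
#' @examples
#' u <- matrix(1 + 0i, 16, 16)
#' v <- propagate(u, 100, 0.405, 5.5)
#' max(abs(Mod(v) - 1)) < 1e-12
#' @export
propagate <- function(field, distance, wavelength, sample_pitch,
                      band_limit = TRUE) {
  if (!is_square_matrix(field)) stop("field must be a square matrix", call. = FALSE)
  if (!is.finite(distance)) stop("distance must be finite", call. = FALSE)
  if (sample_pitch <= 0) stop("sample_pitch must be > 0", call. = FALSE)
  if (distance == 0) return(field + 0i)
  spec <- stats::fft(field)
  h <- as_kernel(nrow(field), distance, wavelength, sample_pitch, band_limit)
  stats::fft(spec * h, inverse = TRUE) / length(field)
}

# Sampled angular-spectrum transfer function on an n x n grid.
as_kernel <- function(n, distance, wavelength, sample_pitch, band_limit) {
  f <- fft_freq(n, sample_pitch)
  fx <- matrix(f, n, n)
  fy <- matrix(f, n, n, byrow = TRUE)
  arg <- 1 / wavelength^2 - fx^2 - fy^2
  prop <- arg > 0
  kz <- sqrt(pmax(arg, 0))
  h <- exp(2i * pi * distance * kz) * prop
  if (band_limit) {
    df <- 1 / (n * sample_pitch)
    flim <- 1 / (wavelength * sqrt((2 * distance * df)^2 + 1))
    h <- h * (abs(fx) <= flim & abs(fy) <= flim)
  }
  h
}

# DFT sample frequencies (cycles per um), FFT ordering.
fft_freq <- function(n, pitch) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * pitch)
}

# Cosine-taper window pulling a contrast field to zero over `border` pixels
# at each edge; suppresses wraparound artifacts of the periodic FFT.
apodize_window <- function(n, border = 16) {
  if (border <= 0) return(matrix(1, n, n))
  border <- min(border, floor(n / 2))
  w <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * (seq_len(border) - 0.5) / border)
  w[seq_len(border)] <- ramp
  w[n + 1 - seq_len(border)] <- ramp
  outer(w, w)
}
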