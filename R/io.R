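#' Write and read holograms
#'
#' Quantized holograms round-trip bit-exactly through 8-bit grayscale PNG.
#' Unquantized (floating-point) intensities can be written to a `.tsv` path,
#' which stores full-precision text and also round-trips exactly.
#'
#' @param h A `dihm_hologram`.
#' @param path Output path; `.png` for 8-bit grayscale, `.tsv` for
#'   full-precision text.
#' @return `write_hologram` returns `path` invisibly; `read_hologram`
#'   returns a `dihm_hologram`.
#' @export
write_hologram <- function(h, path) {
  stopifnot(inherits(h, "dihm_hologram"))
  if (grepl("\\.tsv$", path)) {
    utils::write.table(format(h$intensity, digits = 17, scientific = TRUE),
                       path, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    top <- 2^h$geometry$bit_depth - 1
    v <- h$intensity
    if (any(v != round(v)) || any(v > top)) {
      stop("hologram is not quantized to bit_depth; write to .tsv instead",
           call. = FALSE)
    }
    png::writePNG(v / top, path)
  }
  invisible(path)
}

#' @param path Path written by [write_hologram()].
#' @param geometry The [optical_geometry()] the file must conform to.
#' @rdname write_hologram
#' @export
read_hologram <- function(path, geometry) {
  if (grepl("\\.tsv$", path)) {
    v <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(v) <- NULL
  } else {
    img <- png::readPNG(path)
    if (length(dim(img)) != 2) {
      stop("hologram PNG must be single-channel grayscale", call. = FALSE)
    }
    v <- matrix(as.integer(round(img * (2^geometry$bit_depth - 1))),
                nrow(img), ncol(img))
  }
  if (nrow(v) != geometry$sensor_pixels || ncol(v) != geometry$sensor_pixels) {
    stop(sprintf("hologram is %d x %d but geometry expects %d x %d",
                 nrow(v), ncol(v), geometry$sensor_pixels,
                 geometry$sensor_pixels), call. = FALSE)
  }
  new_hologram(v, geometry, provenance = path)
}

#' Write and read an optical geometry as a YAML sidecar
#'
#' @param geometry A [optical_geometry()].
#' @param path YAML file path.
#' @return `read_geometry` returns a [optical_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "dihm_geometry"))
  yaml::write_yaml(unclass(geometry), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  do.call(optical_geometry, yaml::read_yaml(path))
}
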