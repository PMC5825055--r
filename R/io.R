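#' Read a scene image
#'
#' Reads a PNG or JPEG file into a `height x width x 3` numeric array with
#' values in `[0, 1]`. Grayscale files are expanded by channel replication
#' (with a warning), alpha channels are dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An RGB array, `height x width x 3`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (is.matrix(img)) {
    warning("grayscale image; replicating channel to RGB")
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a saliency map as an 8-bit grayscale PNG
#'
#' The map is min-max rescaled to `[0, 1]` for visualization; use
#' [write_pfm()] for a lossless float round-trip.
#'
#' @param map A [saliency_map] or a numeric matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path) {
  g <- if (inherits(map, "saliency_map")) map$grid else map
  png::writePNG(minmax01(g), path)
  invisible(path)
}

#' Lossless float raster I/O (PFM)
#'
#' Writes/reads a single-channel portable float map (`Pf`), little-endian,
#' for exact round-trips of saliency rasters. PFM stores rows bottom-up;
#' the in-memory convention (row 1 = top) is restored on read.
#'
#' @param map A [saliency_map] or numeric matrix (for writing).
#' @param path File path.
#' @return `read_pfm()` returns a numeric matrix; `write_pfm()` returns
#'   `path` invisibly.
#' @export
write_pfm <- function(map, path) {
  g <- if (inherits(map, "saliency_map")) map$grid else map
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("Pf", paste(ncol(g), nrow(g)), "-1.0"), con, sep = "\n")
  # bottom-up scanlines, row-major
  writeBin(as.numeric(t(g[nrow(g):1, , drop = FALSE])), con,
           size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_pfm
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "Pf")) stop("not a grayscale PFM file", call. = FALSE)
  dims <- scan(text = readLines(con, n = 1), quiet = TRUE)
  scale <- as.numeric(readLines(con, n = 1))
  endian <- if (scale < 0) "little" else "big"
  v <- readBin(con, "numeric", n = dims[1] * dims[2], size = 4, endian = endian)
  m <- matrix(v, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  m[nrow(m):1, , drop = FALSE]
}
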