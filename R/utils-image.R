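# Low-level raster utilities shared by all modules.
#
# Conventions used throughout the package:
#   * a grayscale raster is a plain numeric matrix, height x width,
#     grid[row, col], row 1 = top of the image;
#   * an RGB image is a height x width x 3 array with values in [0, 1];
#   * pixel coordinates exposed to users are 0-based, x = column, y = row,
#     origin at the top-left corner, half-open bounds [0, w) x [0, h).

# round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# min-max rescale to [0, 1]; a constant map collapses to all zeros
minmax01 <- function(m) {
  rng <- range(m)
  if (!all(is.finite(rng))) stop("non-finite values in map", call. = FALSE)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

is_constant_map <- function(m) diff(range(m)) <= 0

#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# derive a child seed from a user seed, keeping inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset)) %% 2147483629)
}

# separable convolution with a symmetric 1-D kernel (applied along rows
# and columns); stats::filter does the inner loops in C. pad = "zero"
# (fixation-map smoothing: border fixations lose mass) or "replicate"
# (feature pyramids: avoids spurious contrast at the image boundary).
conv_sep <- function(m, k, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  r <- (length(k) - 1L) / 2L
  one_axis <- function(m) {
    h <- nrow(m); w <- ncol(m)
    p <- if (pad == "zero") {
      q <- matrix(0, h + 2L * r, w)
      q[(r + 1L):(r + h), ] <- m
      q
    } else {
      m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
    }
    f <- stats::filter(p, k, method = "convolution", sides = 2L)
    matrix(f[(r + 1L):(r + h), ], h, w)
  }
  t(one_axis(t(one_axis(m))))
}

gaussian_kernel1d <- function(sigma, radius = ceiling(6 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# isotropic Gaussian blur, zero padding, mass-preserving kernel (sums to 1)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  conv_sep(m, gaussian_kernel1d(sigma))
}

# center-aligned bilinear resize; symmetric under 180-degree flips
resize_bilinear <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  if (new_h == h && new_w == w) return(m)
  sy <- h / new_h; sx <- w / new_w
  yy <- pmin(pmax((seq_len(new_h) - 0.5) * sy - 0.5, 0), h - 1)
  xx <- pmin(pmax((seq_len(new_w) - 0.5) * sx - 0.5, 0), w - 1)
  y0 <- floor(yy); fy <- yy - y0
  x0 <- floor(xx); fx <- xx - x0
  y1 <- pmin(y0 + 1, h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  a <- m[y0 + 1, , drop = FALSE] * (1 - fy) + m[y1 + 1, , drop = FALSE] * fy
  t(t(a[, x0 + 1, drop = FALSE]) * (1 - fx) + t(a[, x1 + 1, drop = FALSE]) * fx)
}

# full 2-D convolution via shift-and-add, replicate-edge padding, output
# same size; kernels here are small (Gabor 9x9) and pyramid levels are small
conv2_same <- function(m, kern) {
  h <- nrow(m); w <- ncol(m)
  kr <- (nrow(kern) - 1L) / 2L; kc <- (ncol(kern) - 1L) / 2L
  p <- m[c(rep(1L, kr), seq_len(h), rep(h, kr)),
         c(rep(1L, kc), seq_len(w), rep(w, kc)), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      kv <- kern[i, j]
      if (kv != 0)
        out <- out + kv * p[i:(i + h - 1L), j:(j + w - 1L)]
    }
  }
  out
}

# Gabor quadrature pair; theta is the preferred BAR orientation in degrees
# (90 = vertical bars, i.e. luminance varying along x), so the sinusoidal
# carrier runs perpendicular to the bars
gabor_kernels <- function(theta_deg, wavelength = 7, sigma = wavelength / 3,
                          gamma = 0.5, radius = 4) {
  a <- (theta_deg + 90) * pi / 180
  # y varies fastest so matrix rows are the image's row (y) axis
  g <- expand.grid(y = (-radius):radius, x = (-radius):radius)
  xr <- g$x * cos(a) + g$y * sin(a)
  yr <- -g$x * sin(a) + g$y * cos(a)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / wavelength)
  odd <- env * sin(2 * pi * xr / wavelength)
  even <- even - mean(even)      # zero DC response
  n <- sqrt(sum(even^2) + sum(odd^2))
  dimk <- c(2L * radius + 1L, 2L * radius + 1L)
  list(even = matrix(even / n, dimk[1], dimk[2]),
       odd = matrix(odd / n, dimk[1], dimk[2]))
}

gabor_energy <- function(m, kernels) {
  sqrt(conv2_same(m, kernels$even)^2 + conv2_same(m, kernels$odd)^2)
}

# linear border attenuation window: 0 at the map edge ramping to 1 over
# frac of the smaller dimension; suppresses the spurious center-surround
# responses that upsampled coarse surrounds create along image borders
border_attenuation <- function(h, w, frac = 0.1) {
  r <- max(1, round(frac * min(h, w)))
  ramp <- function(n) pmin(1, (pmin(seq_len(n) - 1, n - seq_len(n)) + 0.5) / r)
  outer(ramp(h), ramp(w), pmin)
}

# centered Gaussian density raster (integrates to ~1 over the grid)
center_gaussian <- function(height, width, sigma) {
  cy <- (height - 1) / 2; cx <- (width - 1) / 2
  gy <- exp(-((seq_len(height) - 1) - cy)^2 / (2 * sigma^2))
  gx <- exp(-((seq_len(width) - 1) - cx)^2 / (2 * sigma^2))
  g <- outer(gy, gx)
  g / sum(g)
}

as_gray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3)
  (image[, , 1] + image[, , 2] + image[, , 3]) / 3
}

image_dims <- function(image) {
  d <- dim(image)
  c(height = d[1], width = d[2])
}
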