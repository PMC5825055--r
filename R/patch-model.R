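# PCA patch-dissimilarity saliency ("Proposed P"): non-overlapping t x t
# patches described by CIELAB color and intensity-gradient features,
# projected onto the leading principal components, scored by
# spatially-weighted L1 dissimilarity to (neighbouring) patches, with an
# age-specific patch-size subset and center-bias weighting.

PATCH_SIZES <- c(64, 32, 16, 8)   # scale index 1..4, coarser -> finer

#' Patch sizes of a scale subset
#'
#' Scale indices 1..4 correspond to patch sizes 64, 32, 16, 8 px
#' (coarser to finer); subset `a:4` means sizes `a` through 4.
#'
#' @param scales Integer scale indices in 1..4.
#' @return Patch sizes in pixels.
#' @export
patch_scale_subset <- function(scales) {
  stopifnot(all(scales %in% 1:4))
  PATCH_SIZES[scales]
}

#' Per-patch feature extraction
#'
#' Tiles the image with non-overlapping `t x t` patches (the trailing
#' remainder is cropped) and describes each patch by the flattened pixels
#' of five channels: CIELAB `L*`, `a*`, `b*` and the horizontal/vertical
#' intensity gradients `I_x`, `I_y` — a feature vector of length `5 t^2`.
#'
#' @param image RGB array (`height x width x 3`, values in `[0, 1]`).
#' @param t Patch side in pixels, one of 64, 32, 16, 8.
#' @return List with `grid` (class `patch_grid`: `t`, `np`, patch layout
#'   and 0-based patch-center coordinates) and `X` (`5 t^2 x np` feature
#'   matrix, patches in raster order).
#' @export
extract_patch_features <- function(image, t) {
  if (!(t %in% PATCH_SIZES))
    stop("t must be one of ", paste(PATCH_SIZES, collapse = ", "),
         call. = FALSE)
  d <- dim(image)[1:2]
  if (t > min(d)) stop("patch size exceeds image", call. = FALSE)
  nr <- floor(d[1] / t); nc <- floor(d[2] / t)
  h <- nr * t; w <- nc * t
  img <- image[seq_len(h), seq_len(w), , drop = FALSE]
  lab <- grDevices::convertColor(cbind(as.vector(img[, , 1]),
                                       as.vector(img[, , 2]),
                                       as.vector(img[, , 3])),
                                 from = "sRGB", to = "Lab")
  Lc <- matrix(lab[, 1], h, w)
  ac <- matrix(lab[, 2], h, w)
  bc <- matrix(lab[, 3], h, w)
  I <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  Ix <- cbind(I[, 2, drop = FALSE] - I[, 1, drop = FALSE],
              (I[, 3:w, drop = FALSE] - I[, 1:(w - 2), drop = FALSE]) / 2,
              I[, w, drop = FALSE] - I[, w - 1, drop = FALSE])
  Iy <- rbind(I[2, , drop = FALSE] - I[1, , drop = FALSE],
              (I[3:h, , drop = FALSE] - I[1:(h - 2), , drop = FALSE]) / 2,
              I[h, , drop = FALSE] - I[h - 1, , drop = FALSE])
  np <- nr * nc
  X <- matrix(0, 5 * t * t, np)
  centers <- matrix(0, np, 2)
  i <- 0L
  for (pr in seq_len(nr)) {
    rows <- ((pr - 1) * t + 1):(pr * t)
    for (pc in seq_len(nc)) {
      cols <- ((pc - 1) * t + 1):(pc * t)
      i <- i + 1L
      X[, i] <- c(Lc[rows, cols], ac[rows, cols], bc[rows, cols],
                  Ix[rows, cols], Iy[rows, cols])
      centers[i, ] <- c((pc - 1) * t + (t - 1) / 2,    # x
                        (pr - 1) * t + (t - 1) / 2)    # y
    }
  }
  grid <- structure(list(t = t, np = np, nrow_p = nr, ncol_p = nc,
                         centers = data.frame(x = centers[, 1],
                                              y = centers[, 2]),
                         cropped_dims = c(h, w), image_dims = d),
                    class = "patch_grid")
  list(grid = grid, X = X)
}

#' @export
print.patch_grid <- function(x, ...) {
  cat("<patch_grid> t = ", x$t, ", ", x$nrow_p, "x", x$ncol_p, " = ",
      x$np, " patches on ", x$cropped_dims[1], "x", x$cropped_dims[2],
      "\n", sep = "")
  invisible(x)
}

#' PCA reduction of the patch feature matrix
#'
#' Centers each feature dimension, forms the covariance over patches and
#' solves its eigenproblem (via the SVD of the centered matrix — identical
#' spectrum, numerically stabler for the tall thin matrices that large
#' patches produce). The retained dimension `d` is the smallest count whose
#' cumulative eigenvalue share reaches `variance_keep`.
#'
#' @param X Feature matrix (`features x np`) from [extract_patch_features()].
#' @param variance_keep Fraction of total variance to retain (default 0.95);
#'   `1.0` keeps the full spectrum (an isometry of the patch cloud).
#' @return Object of class `patch_features`: `lambda` (descending
#'   eigenvalues), `E` (basis, columns orthonormal), `d`, `X_reduced`
#'   (`d x np`), `degenerate`.
#' @export
pca_reduce <- function(X, variance_keep = 0.95) {
  np <- ncol(X)
  if (np < 2) stop("need at least 2 patches", call. = FALSE)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  sv <- svd(Xc)
  lambda <- sv$d^2 / (np - 1)
  total <- sum(lambda)
  if (total <= 1e-12) {
    return(structure(list(lambda = lambda, E = NULL, d = 0L,
                          X_reduced = matrix(0, 0, np), center = ctr,
                          degenerate = TRUE, variance_keep = variance_keep),
                     class = "patch_features"))
  }
  cum <- cumsum(lambda) / total
  d <- which(cum >= variance_keep - 1e-12)[1]
  E <- sv$u[, seq_len(d), drop = FALSE]
  structure(list(lambda = lambda, E = E, d = d,
                 X_reduced = crossprod(E, Xc), center = ctr,
                 degenerate = FALSE, variance_keep = variance_keep),
            class = "patch_features")
}

#' @export
print.patch_features <- function(x, ...) {
  cat("<patch_features> d = ", x$d, " of ", length(x$lambda),
      " (variance_keep = ", x$variance_keep, ")",
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

# raw spatially-weighted dissimilarity scores:
#   S(R_i) = omega_i * sum_{j in Nbr(i)} L1(x_i, x_j) / (1 + dist_ij)
# with dist in pixels normalized by the image diagonal
patch_dissimilarity_scores <- function(X_reduced, centers, diag_len,
                                       L_nb = "all", omega = NULL) {
  np <- ncol(X_reduced)
  D1 <- as.matrix(stats::dist(t(X_reduced), method = "manhattan"))
  Dp <- as.matrix(stats::dist(centers)) / diag_len
  W <- D1 / (1 + Dp)
  diag(W) <- 0
  if (!identical(L_nb, "all")) {
    k <- as.integer(L_nb)
    for (i in seq_len(np)) {
      ord <- order(Dp[i, -i])  # nearest first among the others
      keep <- setdiff(seq_len(np), i)[ord[seq_len(min(k, np - 1))]]
      drop <- setdiff(seq_len(np), c(i, keep))
      W[i, drop] <- 0
    }
  }
  s <- unname(rowSums(W))
  if (!is.null(omega)) s <- s * omega
  s
}

#' Patch-dissimilarity saliency for one patch size
#'
#' Scores each patch by its spatially-weighted L1 dissimilarity to the
#' other patches in the reduced feature space
#' (`S(R_i) = omega(i) * sum_j sum_s |x_s^i - x_s^j| / (1 + dist(p_i, p_j))`,
#' patch-center distances normalized by the image diagonal), min-max
#' normalizes the scores, paints them back at full resolution by
#' nearest-patch assignment and Gaussian-smooths the result. The outer
#' weight `omega(i) = 1 - w_k * d(c, p_i) / D` is the age-adapted center
#' bias at the patch centers.
#'
#' @param grid A `patch_grid`.
#' @param reduced A `patch_features` from [pca_reduce()].
#' @param L_nb `"all"` (every other patch contributes) or an integer count
#'   of nearest neighbours.
#' @param w_k Center-bias strength in `[0, 1]`.
#' @param smooth_sigma Post-hoc smoothing sigma (default `t / 2`); `0`
#'   disables smoothing.
#' @return Object of class `patch_saliency`: `scores_raw`, `scores`
#'   (normalized), `map` (full-resolution [saliency_map],
#'   `source = "model_P"`), `omega`.
#' @export
patch_saliency <- function(grid, reduced, L_nb = "all", w_k = 0,
                           smooth_sigma = NULL) {
  stopifnot(inherits(grid, "patch_grid"))
  d_img <- grid$image_dims
  if (is.null(smooth_sigma)) smooth_sigma <- grid$t / 2
  omega <- {
    cy <- (d_img[1] - 1) / 2; cx <- (d_img[2] - 1) / 2
    D <- sqrt(cx^2 + cy^2)
    dd <- sqrt((grid$centers$x - cx)^2 + (grid$centers$y - cy)^2)
    1 - w_k * dd / D
  }
  if (reduced$d == 0) {
    map <- saliency_map(matrix(0, d_img[1], d_img[2]), source = "model_P",
                        normalization = "minmax01")
    attr(map, "degenerate") <- TRUE
    return(structure(list(scores_raw = rep(0, grid$np),
                          scores = rep(0, grid$np), map = map,
                          omega = omega, L_nb = L_nb, w_k = w_k),
                     class = "patch_saliency"))
  }
  diag_len <- sqrt(sum(d_img^2))
  raw <- patch_dissimilarity_scores(reduced$X_reduced,
                                    as.matrix(grid$centers), diag_len,
                                    L_nb = L_nb, omega = omega)
  scores <- if (diff(range(raw)) > 0) minmax01(matrix(raw, 1))[1, ]
            else rep(0, grid$np)
  # nearest-patch paint-back: pixel row/col -> clamped patch index
  pr <- pmin((seq_len(d_img[1]) - 1) %/% grid$t, grid$nrow_p - 1)
  pc <- pmin((seq_len(d_img[2]) - 1) %/% grid$t, grid$ncol_p - 1)
  full <- matrix(scores[outer(pr * grid$ncol_p, pc, `+`) + 1],
                 d_img[1], d_img[2])
  if (smooth_sigma > 0) full <- gaussian_blur(full, smooth_sigma)
  map <- saliency_map(minmax01(full), source = "model_P",
                      normalization = "minmax01")
  structure(list(scores_raw = raw, scores = scores, map = map,
                 omega = omega, L_nb = L_nb, w_k = w_k),
            class = "patch_saliency")
}

#' @export
print.patch_saliency <- function(x, ...) {
  cat("<patch_saliency> ", length(x$scores), " patches, w_k = ", x$w_k,
      ", L_nb = ", paste(x$L_nb, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Multi-scale patch saliency over an age-specific size subset
#'
#' Computes the patch-dissimilarity map for each patch size in the subset,
#' min-max normalizes each at full resolution, averages them and
#' re-normalizes. All per-size maps share the smoothing scale of the
#' smallest (finest) size in the subset.
#'
#' @param image RGB array.
#' @param t_subset Patch sizes, a subset of `c(64, 32, 16, 8)` (see
#'   [patch_scale_subset()] for the scale-index form).
#' @param w_k Center-bias strength.
#' @param variance_keep PCA variance fraction per size.
#' @param L_nb Neighbour count (see [patch_saliency()]).
#' @return A [saliency_map] with `source = "model_P"`.
#' @export
multiscale_patch_saliency <- function(image, t_subset = PATCH_SIZES,
                                      w_k = 0, variance_keep = 0.95,
                                      L_nb = "all") {
  if (length(t_subset) == 0) stop("t_subset is empty", call. = FALSE)
  stopifnot(all(t_subset %in% PATCH_SIZES))
  sig <- min(t_subset) / 2
  maps <- lapply(t_subset, function(t) {
    pf <- extract_patch_features(image, t)
    red <- pca_reduce(pf$X, variance_keep = variance_keep)
    patch_saliency(pf$grid, red, L_nb = L_nb, w_k = w_k,
                   smooth_sigma = sig)$map$grid
  })
  avg <- Reduce(`+`, maps) / length(maps)
  saliency_map(minmax01(avg), source = "model_P", normalization = "minmax01")
}
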