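# Multi-scale center-surround saliency ("Proposed S" model family).
#
# The classic bottom-up architecture: 9-level dyadic Gaussian pyramids of
# intensity and broadly-tuned color channels, Gabor orientation energy on
# the intensity pyramid, center-surround differences between pyramid levels
# (center c in {2,3,4}, surround c+delta, delta in {3,4}), an iterative-free
# peak-promoting normalization N, and across-scale combination at a common
# pyramid level. The age adaptation enters through the scale-subset start
# index s: only center-surround maps i = s..6 (finer -> coarser) are summed.

CS_PAIRS <- cbind(center = c(2, 2, 3, 3, 4, 4),
                  delta  = c(3, 4, 3, 4, 3, 4))

level_dims <- function(dims, k) ceiling(dims / 2^k)

pyramid_of <- function(m, n_levels = 9) {
  out <- vector("list", n_levels)
  out[[1]] <- m
  k5 <- c(1, 4, 6, 4, 1) / 16
  for (k in 2:n_levels) {
    prev <- out[[k - 1]]
    sm <- conv_sep(prev, k5, pad = "replicate")
    out[[k]] <- resize_bilinear(sm, ceiling(nrow(prev) / 2),
                                ceiling(ncol(prev) / 2))
  }
  out
}

#' Feature pyramids of an image
#'
#' Builds 9-level (0..8) dyadic Gaussian pyramids of the intensity channel
#' `I = (r + g + b) / 3`, of the broadly tuned color channels R, G, B, Y
#' (chromatic channels are divided by intensity where it exceeds 10% of its
#' maximum and set to zero elsewhere, then rectified), and Gabor orientation
#' energy of the intensity pyramid at 0/45/90/135 degrees (levels 2..8, the
#' only levels the center-surround stage consumes).
#'
#' @param image RGB array (`height x width x 3`, values in `[0, 1]`) or a
#'   grayscale matrix (replicated to RGB with a warning). Images whose
#'   shorter side is below 256 px are upscaled (with a warning) so the
#'   coarsest level stays non-degenerate.
#' @param orientations Gabor bar orientations in degrees.
#' @return Object of class `feature_pyramids`.
#' @export
build_pyramids <- function(image, orientations = c(0, 45, 90, 135)) {
  if (is.matrix(image)) {
    warning("grayscale input; replicating channel to RGB")
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  }
  d <- dim(image)[1:2]
  if (min(d) < 256) {
    warning("image shorter side < 256 px; upscaling for pyramid depth")
    f <- 256 / min(d)
    up <- lapply(1:3, function(ch)
      resize_bilinear(image[, , ch], round(d[1] * f), round(d[2] * f)))
    image <- array(unlist(up), dim = c(dim(up[[1]]), 3))
    d <- dim(image)[1:2]
  }
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  I <- (r + g + b) / 3
  thr <- 0.1 * max(I)
  sel <- I > thr
  rn <- gn <- bn <- array(0, dim = d)
  rn[sel] <- r[sel] / I[sel]
  gn[sel] <- g[sel] / I[sel]
  bn[sel] <- b[sel] / I[sel]
  R <- pmax(rn - (gn + bn) / 2, 0)
  G <- pmax(gn - (rn + bn) / 2, 0)
  B <- pmax(bn - (rn + gn) / 2, 0)
  Y <- pmax((rn + gn) / 2 - abs(rn - gn) / 2 - bn, 0)
  pyr <- list(intensity = pyramid_of(I),
              R = pyramid_of(R), G = pyramid_of(G),
              B = pyramid_of(B), Y = pyramid_of(Y))
  gab <- lapply(orientations, function(th) {
    kern <- gabor_kernels(th)
    lv <- vector("list", 9)
    for (k in 3:9) lv[[k]] <- gabor_energy(pyr$intensity[[k]], kern)
    lv
  })
  names(gab) <- paste0("deg", orientations)
  structure(c(pyr, list(gabor = gab, orientations = orientations, dims = d)),
            class = "feature_pyramids")
}

#' @export
print.feature_pyramids <- function(x, ...) {
  cat("<feature_pyramids> ", x$dims[1], "x", x$dims[2],
      ", 9 levels, orientations ", paste(x$orientations, collapse = "/"),
      " deg\n", sep = "")
  invisible(x)
}

# |center - upsampled surround| at the center level
cs_diff <- function(pyr_levels, center, delta) {
  ce <- pyr_levels[[center + 1]]
  su <- pyr_levels[[center + delta + 1]]
  abs(ce - resize_bilinear(su, nrow(ce), ncol(ce)))
}

#' Center-surround feature maps
#'
#' Computes the six per-channel center-surround maps for centers
#' `c in {2, 3, 4}` and surround offsets `delta in {3, 4}`; index `i = 1`
#' (c=2, delta=3) is the finest, `i = 6` (c=4, delta=4) the coarsest.
#' Chromatic maps are double-opponent:
#' `RG = |(R_c - G_c) - upsampled(G_s - R_s)|`, analogously `BY`.
#'
#' @param pyr A `feature_pyramids` object.
#' @return Object of class `feature_maps`: lists `intensity`, `RG`, `BY`
#'   (6 maps each) and `orientation` (per orientation, 6 maps), each map at
#'   its center-level resolution.
#' @export
center_surround_maps <- function(pyr) {
  stopifnot(inherits(pyr, "feature_pyramids"))
  n <- nrow(CS_PAIRS)
  intensity <- RG <- BY <- vector("list", n)
  orientation <- lapply(pyr$gabor, function(x) vector("list", n))
  rg_levels <- mapply(function(R, G) R - G, pyr$R, pyr$G, SIMPLIFY = FALSE)
  by_levels <- mapply(function(B, Y) B - Y, pyr$B, pyr$Y, SIMPLIFY = FALSE)
  for (i in seq_len(n)) {
    ce <- CS_PAIRS[i, "center"]; de <- CS_PAIRS[i, "delta"]
    intensity[[i]] <- cs_diff(pyr$intensity, ce, de)
    # double opponency: surround enters with opposite sign
    RG[[i]] <- {
      cmap <- rg_levels[[ce + 1]]
      smap <- -rg_levels[[ce + de + 1]]   # (G_s - R_s)
      abs(cmap - resize_bilinear(smap, nrow(cmap), ncol(cmap)))
    }
    BY[[i]] <- {
      cmap <- by_levels[[ce + 1]]
      smap <- -by_levels[[ce + de + 1]]   # (Y_s - B_s)
      abs(cmap - resize_bilinear(smap, nrow(cmap), ncol(cmap)))
    }
    for (th in names(pyr$gabor))
      orientation[[th]][[i]] <- cs_diff(pyr$gabor[[th]], ce, de)
  }
  structure(list(intensity = intensity, RG = RG, BY = BY,
                 orientation = orientation, dims = pyr$dims),
            class = "feature_maps")
}

#' Peak-promoting map normalization N
#'
#' Rescales a map to `[0, 1]` and multiplies it by `(M - mbar)^2`, where
#' `M` is the global maximum (1 after rescaling) and `mbar` the mean of all
#' *other* local maxima (3x3-neighborhood maxima exceeding 0.05). Maps with
#' a single strong peak are preserved; maps with many comparable peaks are
#' suppressed. A constant map returns all zeros.
#'
#' @param m Numeric matrix.
#' @param local_max_threshold Minimum height for a local maximum to count.
#' @return Normalized matrix.
#' @export
normalize_N <- function(m, local_max_threshold = 0.05) {
  if (is_constant_map(m)) return(array(0, dim = dim(m)))
  m <- minmax01(m)
  h <- nrow(m); w <- ncol(m)
  p <- matrix(-Inf, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  nbr_max <- matrix(-Inf, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nbr_max <- pmax(nbr_max, p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)])
  }
  is_peak <- m >= nbr_max & m > local_max_threshold
  peaks <- m[is_peak]
  M <- max(m)
  others <- peaks[-which.max(peaks)]   # drop one instance of the global max
  factor <- if (length(others) == 0) M^2 else (M - mean(others))^2
  m * factor
}

#' Conspicuity stack of an image
#'
#' Runs the full feature pipeline once and stores every per-scale map,
#' `N`-normalized and resized to the common combination scale, so that the
#' age-adapted scale-subset combination for any start index `s` is a cheap
#' sum. Compute this once per image when scanning subsets or training.
#'
#' @param image RGB array (or `feature_pyramids`/`feature_maps`).
#' @param common_level Pyramid level of the combination grid (default 4).
#' @inheritParams build_pyramids
#' @return Object of class `conspicuity_stack`.
#' @export
conspicuity_stack <- function(image, common_level = 4,
                              orientations = c(0, 45, 90, 135)) {
  fm <- if (inherits(image, "feature_maps")) image
        else if (inherits(image, "feature_pyramids")) center_surround_maps(image)
        else center_surround_maps(build_pyramids(image, orientations))
  cd <- level_dims(fm$dims, common_level)
  res <- function(m) {
    att <- m * border_attenuation(nrow(m), ncol(m))
    resize_bilinear(normalize_N(att), cd[1], cd[2])
  }
  structure(list(
    intensity = lapply(fm$intensity, res),
    RG = lapply(fm$RG, res),
    BY = lapply(fm$BY, res),
    orientation = lapply(fm$orientation, function(or) lapply(or, res)),
    dims = fm$dims, common_dims = cd, common_level = common_level
  ), class = "conspicuity_stack")
}

#' @export
print.conspicuity_stack <- function(x, ...) {
  cat("<conspicuity_stack> image ", x$dims[1], "x", x$dims[2],
      ", combination grid ", x$common_dims[1], "x", x$common_dims[2],
      " (level ", x$common_level, ")\n", sep = "")
  invisible(x)
}

#' Across-scale conspicuity maps for a scale subset
#'
#' Combines the normalized center-surround maps `i = s..6` into the three
#' conspicuity maps: `Ibar = sum_i N(I_i)`,
#' `Cbar = sum_i [N(RG_i) + N(BY_i)]`, and
#' `Obar = sum_theta N(sum_i N(O_i(theta)))` — the across-scale sum on the
#' common grid, with the orientation channel renormalized per orientation
#' before pooling (the classic "same settings" convention; without it the
#' many-peaked distractor orientation dominates and orientation pop-out is
#' lost). `s = 1` reproduces the classic all-scales combination; `s = 6`
#' keeps only the coarsest map.
#'
#' @param stack A [conspicuity_stack()].
#' @param s Scale-subset start index in `1..6`.
#' @return List with matrices `Ibar`, `Cbar`, `Obar`.
#' @export
conspicuity <- function(stack, s = 1) {
  stopifnot(inherits(stack, "conspicuity_stack"))
  if (!(s %in% 1:6)) stop("s must be in 1..6", call. = FALSE)
  idx <- s:6
  add <- function(maps) Reduce(`+`, maps[idx])
  Ibar <- add(stack$intensity)
  Cbar <- add(stack$RG) + add(stack$BY)
  Obar <- Reduce(`+`, lapply(stack$orientation,
                             function(or) normalize_N(add(or))))
  list(Ibar = Ibar, Cbar = Cbar, Obar = Obar)
}

#' Multi-scale subset saliency map ("S" model)
#'
#' The final map is `S = (N(Ibar) + N(Cbar) + N(Obar)) / 3`, computed on
#' the common grid, upsampled to the image resolution and min-max
#' normalized; an optional age-specific center bias `w_k` modulates it via
#' [apply_center_bias()].
#'
#' @param image RGB array or a precomputed [conspicuity_stack()].
#' @param s Scale-subset start index (1 = all scales ... 6 = coarsest only).
#' @param w_k Center-bias strength in `[0, 1]` (0 = none).
#' @param dims Output dimensions `c(height, width)`; defaults to the
#'   (possibly upscaled) image dimensions.
#' @return A [saliency_map] with `source = "model_S"`. A featureless
#'   (blank) image yields a constant zero map carrying a `degenerate`
#'   attribute.
#' @export
saliency_S <- function(image, s = 1, w_k = 0, dims = NULL) {
  stack <- if (inherits(image, "conspicuity_stack")) image
           else conspicuity_stack(image)
  cm <- conspicuity(stack, s)
  S <- (normalize_N(cm$Ibar) + normalize_N(cm$Cbar) + normalize_N(cm$Obar)) / 3
  if (is.null(dims)) dims <- stack$dims
  up <- resize_bilinear(S, dims[1], dims[2])
  degenerate <- is_constant_map(up)
  out <- saliency_map(minmax01(up), source = "model_S",
                      normalization = "minmax01")
  if (w_k > 0) {
    out <- apply_center_bias(out, w_k)
    out$source <- "model_S"
  }
  attr(out, "degenerate") <- degenerate
  out
}
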