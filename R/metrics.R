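#' Explorativeness entropy of a human saliency map
#'
#' First-order entropy of the map's intensity histogram,
#' `H = sum_l h(l) * log(L / h(l))` over occupied bins, where `h(l)` is the
#' count of pixels in intensity bin `l` and `L` the total pixel count.
#' Equivalently `H = L *` Shannon entropy (nats) of the normalized
#' histogram. Spread-out (exploratory) gaze gives high `H`; concentrated
#' gaze gives low `H`. A constant map returns `H = 0` with a degenerate
#' flag rather than an error.
#'
#' @param map A [saliency_map] (min-max normalized) or numeric matrix with
#'   values in `[0, 1]`.
#' @param bins Number `B >= 2` of equal-width histogram bins on `[0, 1]`.
#' @param base Logarithm base; natural log by default, so `H` is in
#'   pixels x nats.
#' @return An object of class `entropy_result`: list with `H`, `L`,
#'   `histogram` (length `bins`) and `degenerate`.
#' @export
explorativeness_entropy <- function(map, bins = 256, base = exp(1)) {
  g <- if (inherits(map, "saliency_map")) map$grid else map
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  if (min(g) < 0 || max(g) > 1)
    stop("map must be normalized to [0, 1]; see build_human_saliency_map()",
         call. = FALSE)
  L <- length(g)
  degenerate <- is_constant_map(g)
  bin <- pmin(floor(as.vector(g) * bins), bins - 1L) + 1L
  h <- tabulate(bin, nbins = bins)
  occ <- h > 0
  H <- sum(h[occ] * (log(L / h[occ]) / log(base)))
  structure(list(H = H, L = L, histogram = h, degenerate = degenerate),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("<entropy_result> H = ", format(x$H, digits = 6), " (L = ", x$L,
      if (x$degenerate) ", degenerate map" else "", ")\n", sep = "")
  invisible(x)
}

#' Threshold configuration for the agreement score
#'
#' The agreement analysis thresholds a saliency map at `T` coverage levels
#' of the most salient area. Levels must be strictly increasing fractions
#' in `(0, 1]` ending at 1.
#'
#' @param T Number of levels (default 20: 5%, 10%, ..., 100%).
#' @param coverage_levels Explicit levels, overriding `T`.
#' @export
agreement_config <- function(T = 20, coverage_levels = NULL) {
  if (is.null(coverage_levels)) coverage_levels <- seq_len(T) / T
  if (length(coverage_levels) < 2 ||
      any(diff(coverage_levels) <= 0) ||
      utils::tail(coverage_levels, 1) != 1 ||
      coverage_levels[1] <= 0)
    stop("coverage levels must be strictly increasing in (0, 1], last = 1",
         call. = FALSE)
  structure(list(T = length(coverage_levels),
                 coverage_levels = coverage_levels),
            class = "agreement_config")
}

# row-major rank order of a grid (most salient first); ties broken by
# raster order, row-major, lowest index first
rowmajor_saliency_order <- function(grid) {
  v <- as.vector(t(grid))
  order(-v)   # radix sort: stable, so ties keep raster order
}

#' Threshold a saliency map at a coverage fraction
#'
#' Returns the binary mask of the `ceiling(coverage * L)` most salient
#' pixels. Ties at the cut value are resolved deterministically in raster
#' order (row-major, lowest index first).
#'
#' @param map A [saliency_map] or numeric matrix.
#' @param coverage Fraction in `(0, 1]` of the most salient area to keep.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
threshold_saliency_map <- function(map, coverage) {
  g <- if (inherits(map, "saliency_map")) map$grid else map
  if (coverage <= 0 || coverage > 1)
    stop("coverage must be in (0, 1]", call. = FALSE)
  L <- length(g)
  k <- ceiling(coverage * L)
  ord <- rowmajor_saliency_order(g)
  keep_rowmajor <- logical(L)
  keep_rowmajor[ord[seq_len(k)]] <- TRUE
  matrix(as.integer(keep_rowmajor), nrow(g), ncol(g), byrow = TRUE)
}

#' Thresholded-ROC agreement between a saliency map and fixations
#'
#' For each coverage level the source map is thresholded to a binary mask
#' of its most salient pixels; the true positive rate is the fraction of
#' target fixation pixels inside the mask and the false positive rate the
#' fraction of non-fixation pixels inside it. The points, anchored at
#' (0,0) and (1,1), form an ROC curve whose trapezoidal area is the
#' agreement score.
#'
#' @param source_map A [saliency_map] (the predictor).
#' @param target_fixations A `fixation_map` (or 0/1 matrix) of the target
#'   group's pooled fixations.
#' @param cfg An [agreement_config()].
#' @return Object of class `roc_curve`: list with `points` (data frame
#'   `fpr`, `tpr`) and `auc`.
#' @export
agreement_auc <- function(source_map, target_fixations,
                          cfg = agreement_config()) {
  g <- if (inherits(source_map, "saliency_map")) source_map$grid
       else source_map
  f <- if (inherits(target_fixations, "fixation_map")) target_fixations$grid
       else target_fixations
  if (!all(dim(g) == dim(f)))
    stop("source map and fixation map dimensions differ", call. = FALSE)
  L <- length(g)
  fr <- which(as.vector(t(f)) > 0)   # row-major indices of fixation pixels
  nF <- length(fr)
  if (nF == 0) stop("target fixation map is empty", call. = FALSE)
  nN <- L - nF
  ord <- rowmajor_saliency_order(g)
  sortpos <- integer(L)
  sortpos[ord] <- seq_len(L)
  fixpos <- sort(sortpos[fr])
  ks <- ceiling(cfg$coverage_levels * L)
  tp <- findInterval(ks, fixpos)
  tpr <- tp / nF
  fpr <- if (nN > 0) (ks - tp) / nN else rep(1, length(ks))
  pts <- rbind(c(0, 0), cbind(fpr, tpr), c(1, 1))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  auc <- sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) +
                               utils::tail(pts[, 2], -1)) / 2)
  structure(list(points = data.frame(fpr = pts[, 1], tpr = pts[, 2]),
                 auc = auc, coverage_levels = cfg$coverage_levels),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", format(x$auc, digits = 4), " (",
      nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' Intra-/inter-group agreement matrix
#'
#' Entry (source `g_s`, target `g_t`) is the mean over images of the
#' agreement AUC between the human saliency map of `g_s` and the pooled
#' fixation pixels of `g_t`. Diagonal entries are the intra-group
#' agreement, off-diagonal the inter-group agreement. Missing
#' (group, image) cells are skipped with a warning.
#'
#' @param table A [fixation_table].
#' @param groups Group labels (default: all in the table).
#' @param images Image ids (default: all registered).
#' @param sigma Smoothing sigma for the human maps (see
#'   [build_human_saliency_map()]).
#' @param cfg An [agreement_config()].
#' @return A `groups x groups` numeric matrix with an `n_images` attribute.
#' @export
agreement_matrix <- function(table, groups = table$groups,
                             images = table$dims$image, sigma = NULL,
                             cfg = agreement_config()) {
  stopifnot(inherits(table, "fixation_table"))
  missing_cells <- character(0)
  fmaps <- list(); smaps <- list()
  for (g in groups) for (im in images) {
    key <- paste(g, im, sep = "\r")
    if (nrow(select_fixations(table, g, im)) == 0) {
      missing_cells <- c(missing_cells, paste0(g, "/", im))
      next
    }
    fm <- build_fixation_map(table, g, im)
    fmaps[[key]] <- fm
    smaps[[key]] <- build_human_saliency_map(fm, sigma = sigma)
  }
  if (length(missing_cells))
    warning("skipped (group, image) cell(s) without fixations: ",
            paste(missing_cells, collapse = ", "))
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(source = groups, target = groups))
  for (gs in groups) for (gt in groups) {
    aucs <- c()
    for (im in images) {
      ks <- paste(gs, im, sep = "\r"); kt <- paste(gt, im, sep = "\r")
      if (is.null(smaps[[ks]]) || is.null(fmaps[[kt]])) next
      aucs <- c(aucs, agreement_auc(smaps[[ks]], fmaps[[kt]], cfg)$auc)
    }
    m[gs, gt] <- if (length(aucs)) mean(aucs) else NA_real_
  }
  attr(m, "n_images") <- length(images)
  m
}

#' Center map and centroid distance of a group
#'
#' Averages a group's per-image human saliency maps into a center map,
#' min-max normalizes it, and measures the Euclidean distance between its
#' intensity-weighted centroid and the geometric image center
#' `((w-1)/2, (h-1)/2)`. A small distance means the group's attention mass
#' sits near the screen center (strong center bias).
#'
#' @param maps List of [saliency_map]s (same dimensions).
#' @return Object of class `center_bias_result`: `center_map`
#'   ([saliency_map], `source = "center_map"`), `centroid` `(x, y)` and
#'   `distance_px`.
#' @export
compute_center_map <- function(maps) {
  if (length(maps) == 0) stop("no maps supplied", call. = FALSE)
  grids <- lapply(maps, function(m)
    if (inherits(m, "saliency_map")) m$grid else m)
  d <- dim(grids[[1]])
  if (!all(vapply(grids, function(g) all(dim(g) == d), logical(1))))
    stop("maps have differing dimensions", call. = FALSE)
  avg <- Reduce(`+`, grids) / length(grids)
  h <- d[1]; w <- d[2]
  tot <- sum(avg)
  if (tot > 0) {
    cx <- sum(colSums(avg) * (seq_len(w) - 1)) / tot
    cy <- sum(rowSums(avg) * (seq_len(h) - 1)) / tot
  } else {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
  }
  dist_px <- sqrt((cx - (w - 1) / 2)^2 + (cy - (h - 1) / 2)^2)
  structure(list(
    center_map = saliency_map(minmax01(avg), source = "center_map",
                              normalization = "minmax01"),
    centroid = c(x = cx, y = cy),
    distance_px = dist_px,
    degenerate = tot <= 0
  ), class = "center_bias_result")
}

#' @export
print.center_bias_result <- function(x, ...) {
  cat("<center_bias_result> centroid (",
      format(x$centroid[1], digits = 5), ", ",
      format(x$centroid[2], digits = 5), "), distance to center ",
      format(x$distance_px, digits = 5), " px\n", sep = "")
  invisible(x)
}

#' Fixation prediction by the center map alone
#'
#' Uses a group's center map as a saliency map to predict fixation
#' locations; a high AUC indicates a strong center bias in the target
#' fixations.
#'
#' @param cbr A `center_bias_result` (or a [saliency_map]).
#' @param target_fixations A `fixation_map` or 0/1 matrix.
#' @param cfg An [agreement_config()].
#' @return The AUC (numeric scalar).
#' @export
center_map_prediction_auc <- function(cbr, target_fixations,
                                      cfg = agreement_config()) {
  src <- if (inherits(cbr, "center_bias_result")) cbr$center_map else cbr
  agreement_auc(src, target_fixations, cfg)$auc
}
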