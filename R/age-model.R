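# Age-specific learned feature combination ("S+I+C"), age-weighted center
# bias, training-sample selection and the scale-subset scan.

#' Center weight map
#'
#' Per-pixel weight `C(i) = 1 - d(c, p_i) / D`, where `d` is the Euclidean
#' distance from pixel `p_i` to the geometric image center
#' `c = ((w-1)/2, (h-1)/2)` and `D` the distance from the center to the
#' farthest corner. `C` is 1 at the center and 0 at the farthest corner.
#'
#' @param height,width Map dimensions in pixels.
#' @return Object of class `center_weight_map`: list with `grid` and `D`.
#' @export
center_weight_map <- function(height, width) {
  stopifnot(height >= 1, width >= 1)
  cy <- (height - 1) / 2; cx <- (width - 1) / 2
  D <- sqrt(cx^2 + cy^2)
  if (D == 0) return(structure(list(grid = matrix(1, height, width), D = 0),
                               class = "center_weight_map"))
  dy <- ((seq_len(height) - 1) - cy)^2
  dx <- ((seq_len(width) - 1) - cx)^2
  grid <- 1 - sqrt(outer(dy, dx, `+`)) / D
  structure(list(grid = grid, D = D), class = "center_weight_map")
}

#' Apply an age-weighted center bias to a saliency map
#'
#' Multiplies the map by `(1 - w_k) + w_k * C(i)` and re-normalizes, where
#' `C` is the [center_weight_map()] and `w_k in [0, 1]` the group-specific
#' strength of the center-bias tendency. `w_k = 0` returns the map
#' unchanged; `w_k = 1` zeroes the farthest corners regardless of features.
#'
#' @param map A [saliency_map] or numeric matrix.
#' @param w_k Center-bias strength in `[0, 1]`.
#' @return A [saliency_map] (same `source` as the input).
#' @export
apply_center_bias <- function(map, w_k) {
  if (w_k < 0 || w_k > 1) stop("w_k must be in [0, 1]", call. = FALSE)
  is_sm <- inherits(map, "saliency_map")
  g <- if (is_sm) map$grid else map
  if (w_k == 0) {
    return(if (is_sm) map else
             saliency_map(g, source = "model_S", normalization = "raw"))
  }
  C <- center_weight_map(nrow(g), ncol(g))$grid
  out <- minmax01(g * (1 - w_k + w_k * C))
  saliency_map(out,
               image_id = if (is_sm) map$image_id else NA_character_,
               source = if (is_sm) map$source else "model_S",
               normalization = "minmax01")
}

#' Select strongly positive / negative training samples
#'
#' Greedily picks the `P` highest-valued pixels of a group's human saliency
#' map (positives) and the `P` lowest-valued pixels (negatives), subject to
#' a pairwise separation of at least `min_sep` pixels within each class so
#' samples do not collapse onto adjacent pixels of one peak. Ties are
#' resolved in raster order. If the separation cannot be satisfied it is
#' halved with a warning until it can.
#'
#' @param human_map A [saliency_map] (min-max normalized) or matrix.
#' @param P Samples per class (default 10, after which additional samples
#'   only add redundancy).
#' @param min_sep Minimum pairwise distance in pixels within a class;
#'   defaults to the map's smoothing scale `25/1024 * width`.
#' @return Object of class `training_samples`: data frame `samples` with
#'   columns `x`, `y` (0-based), `value`, `label`, plus `P` and `min_sep`.
#' @export
select_training_samples <- function(human_map, P = 10, min_sep = NULL) {
  g <- if (inherits(human_map, "saliency_map")) human_map$grid else human_map
  if (P < 1) stop("P must be >= 1", call. = FALSE)
  if (is_constant_map(g))
    stop("constant (degenerate) map: cannot rank salient locations",
         call. = FALSE)
  if (is.null(min_sep)) min_sep <- default_sigma(ncol(g))
  h <- nrow(g); w <- ncol(g)
  v <- as.vector(t(g))                       # row-major
  xy <- cbind(x = (seq_along(v) - 1) %% w,
              y = (seq_along(v) - 1) %/% w)
  greedy <- function(ord, sep, banned = NULL) {
    picked <- integer(0)
    for (i in ord) {
      if (i %in% banned) next
      if (length(picked)) {
        dd <- sqrt((xy[picked, 1] - xy[i, 1])^2 +
                   (xy[picked, 2] - xy[i, 2])^2)
        if (any(dd < sep)) next
      }
      picked <- c(picked, i)
      if (length(picked) == P) break
    }
    picked
  }
  ord_hi <- order(-v)
  ord_lo <- order(v)
  sep <- min_sep
  pos <- greedy(ord_hi, sep)
  while (length(pos) < P && sep > 0.5) {
    sep <- sep / 2
    warning("could not place ", P, " positives at min_sep; relaxed to ", sep)
    pos <- greedy(ord_hi, sep)
  }
  sep <- min_sep
  neg <- greedy(ord_lo, sep, banned = pos)
  while (length(neg) < P && sep > 0.5) {
    sep <- sep / 2
    warning("could not place ", P, " negatives at min_sep; relaxed to ", sep)
    neg <- greedy(ord_lo, sep, banned = pos)
  }
  samples <- data.frame(
    x = xy[c(pos, neg), 1], y = xy[c(pos, neg), 2],
    value = v[c(pos, neg)],
    label = rep(c("positive", "negative"), c(length(pos), length(neg)))
  )
  structure(list(samples = samples, P = P, min_sep = min_sep),
            class = "training_samples")
}

# deterministic full-batch subgradient descent on L2-regularized hinge loss
# (max-margin linear classifier); X: n x p, y in {-1, +1}. The bias is
# carried as an augmented weight (lightly regularized), the standard trick
# that keeps the recursion w_{t+1} = (1 - 1/t) w_t + eta * ghat stable.
fit_linear_svm <- function(X, y, C = 1, iters = 2000) {
  if (length(unique(y)) < 2)
    stop("training labels are all one class", call. = FALSE)
  Xa <- cbind(X, bias = 1)
  n <- nrow(Xa); p <- ncol(Xa)
  lambda <- 1 / (n * C)
  w <- numeric(p)
  for (t in seq_len(iters)) {
    eta <- 1 / (lambda * t)
    viol <- as.vector(Xa %*% w) * y < 1
    ghat <- if (any(viol))
      colSums(Xa[viol, , drop = FALSE] * y[viol]) / n else numeric(p)
    w <- w - eta * (lambda * w - ghat)
  }
  list(w = as.vector(w[-p]), b = w[p])
}

# full-resolution (Ibar, Cbar, Obar) feature channels for a scale subset,
# each min-max normalized; the per-pixel feature vector of the linear model
features_SIC <- function(stack, s, dims = stack$dims) {
  cm <- conspicuity(stack, s)
  lapply(cm, function(m) minmax01(resize_bilinear(m, dims[1], dims[2])))
}

#' Train the age-specific feature-combination model ("S+I+C")
#'
#' For each training image the three conspicuity channels (intensity,
#' color, orientation) at scale subset `s` are sampled at `P` strongly
#' positive and `P` strongly negative locations of the group's human
#' saliency map, and a linear max-margin classifier is fitted to the pooled
#' samples, yielding per-group weights `w_g` and bias `b_g`. The group's
#' center-bias strength `w_k` is either supplied or fitted by a 1-D grid
#' search maximizing the training-set AUC.
#'
#' @param images Named list of RGB arrays, or a named list of precomputed
#'   [conspicuity_stack()]s (names are image ids).
#' @param gaze A [fixation_table] with fixations of `group` on those images.
#' @param group Group label to train for.
#' @param s Scale-subset start index.
#' @param P Samples per class per image.
#' @param sigma Human-map smoothing sigma.
#' @param w_k Center-bias strength; `NULL` fits it by grid search.
#' @param wk_grid Grid for the `w_k` search.
#' @param cfg [agreement_config()] used when fitting `w_k`.
#' @return Object of class `group_model`: `group`, `w` (named length-3
#'   vector: intensity, color, orientation), `b`, `s`, `w_k`, `sigma`.
#' @export
train_group_model <- function(images, gaze, group, s = 1, P = 10,
                              sigma = NULL, w_k = NULL,
                              wk_grid = seq(0, 1, by = 0.1),
                              cfg = agreement_config()) {
  ids <- names(images)
  if (length(ids) < 2) stop("need at least 2 training images", call. = FALSE)
  stacks <- lapply(images, function(im)
    if (inherits(im, "conspicuity_stack")) im else conspicuity_stack(im))
  X <- NULL; y <- NULL
  feats <- list(); fmaps <- list()
  for (id in ids) {
    fmap <- build_fixation_map(gaze, group, id)
    hmap <- build_human_saliency_map(fmap, sigma = sigma)
    samp <- select_training_samples(hmap, P = P)
    fs <- features_SIC(stacks[[id]], s, dims = dim(hmap$grid))
    idx <- cbind(samp$samples$y + 1, samp$samples$x + 1)
    Xi <- cbind(intensity = fs$Ibar[idx],
                color = fs$Cbar[idx],
                orientation = fs$Obar[idx])
    X <- rbind(X, Xi)
    y <- c(y, ifelse(samp$samples$label == "positive", 1, -1))
    feats[[id]] <- fs
    fmaps[[id]] <- fmap
  }
  fit <- fit_linear_svm(X, y)
  model <- structure(list(group = group,
                          w = stats::setNames(fit$w, colnames(X)),
                          b = fit$b, s = s, w_k = w_k %||% 0,
                          sigma = sigma),
                     class = "group_model")
  if (is.null(w_k)) {
    score_maps <- lapply(ids, function(id) sic_score_map(feats[[id]], model))
    aucs <- vapply(wk_grid, function(wk) {
      mean(mapply(function(sm, fm) {
        agreement_auc(apply_center_bias(sm, wk), fm, cfg)$auc
      }, score_maps, fmaps[ids]))
    }, numeric(1))
    model$w_k <- wk_grid[which.max(aucs)]   # ties: smallest w_k
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear score map from precomputed full-res features (before center bias)
sic_score_map <- function(fs, model) {
  sc <- model$w[1] * fs$Ibar + model$w[2] * fs$Cbar +
        model$w[3] * fs$Obar + model$b
  saliency_map(minmax01(sc), source = "model_SIC",
               normalization = "minmax01")
}

#' @export
print.group_model <- function(x, ...) {
  cat("<group_model> group ", x$group, ": w = (",
      paste(format(x$w, digits = 4), collapse = ", "), "), b = ",
      format(x$b, digits = 4), ", s = ", x$s, ", w_k = ", x$w_k, "\n",
      sep = "")
  invisible(x)
}

#' Predict a saliency map with a trained group model
#'
#' Per-pixel linear score `w_g . X + b_g` over the (intensity, color,
#' orientation) conspicuity features at the model's scale subset, min-max
#' normalized and modulated by the group's center bias `w_k`.
#'
#' @param image RGB array or [conspicuity_stack()].
#' @param model A `group_model` from [train_group_model()].
#' @return A [saliency_map] with `source = "model_SIC"`.
#' @export
predict_saliency_SIC <- function(image, model) {
  stopifnot(inherits(model, "group_model"))
  stack <- if (inherits(image, "conspicuity_stack")) image
           else conspicuity_stack(image)
  fs <- features_SIC(stack, model$s)
  out <- sic_score_map(fs, model)
  if (model$w_k > 0) {
    out <- apply_center_bias(out, model$w_k)
    out$source <- "model_SIC"
  }
  out
}

#' Serialize / deserialize a group model as JSON
#'
#' @param model A `group_model`.
#' @param path JSON file path.
#' @return `read_group_model()` returns a `group_model`.
#' @export
write_group_model <- function(model, path) {
  obj <- unclass(model)
  obj$w <- as.list(obj$w)   # keep channel names in the JSON object
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_group_model
#' @export
read_group_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$w <- unlist(m$w)
  structure(m, class = "group_model")
}

#' Scan scale subsets for a group
#'
#' Evaluates the "S" model at every start index `s` against a group's
#' pooled fixations, reporting the mean agreement AUC per subset and the
#' best subset `s*`. Less explorative (child-like) cohorts are expected to
#' peak at coarser subsets, adult-like cohorts at the full range.
#'
#' @param images Named list of RGB arrays or [conspicuity_stack()]s.
#' @param gaze A [fixation_table].
#' @param group Group label.
#' @param s_values Start indices to scan.
#' @param w_k Center-bias strength applied to each candidate map.
#' @param cfg [agreement_config()].
#' @return Data frame with columns `s` and `mean_auc`, plus attribute
#'   `s_star` (the argmax, smallest on ties); class `scale_scan`.
#' @export
scan_scale_subsets <- function(images, gaze, group, s_values = 1:6,
                               w_k = 0, cfg = agreement_config()) {
  ids <- names(images)
  stacks <- lapply(images, function(im)
    if (inherits(im, "conspicuity_stack")) im else conspicuity_stack(im))
  fmaps <- lapply(ids, function(id) build_fixation_map(gaze, group, id))
  mean_auc <- vapply(s_values, function(s) {
    mean(mapply(function(st, fm) {
      agreement_auc(saliency_S(st, s = s, w_k = w_k,
                               dims = dim(fm$grid)), fm, cfg)$auc
    }, stacks, fmaps))
  }, numeric(1))
  out <- data.frame(s = s_values, mean_auc = mean_auc)
  attr(out, "s_star") <- s_values[which.max(mean_auc)]
  class(out) <- c("scale_scan", "data.frame")
  out
}

#' Fit the center-bias strength of a group
#'
#' Grid search over `w_k`, maximizing the mean agreement AUC of
#' center-bias-modulated base maps against the group's fixation maps.
#' Ties resolve to the smallest `w_k`.
#'
#' @param base_maps List of [saliency_map]s (one per image).
#' @param fixation_maps Parallel list of `fixation_map`s.
#' @param wk_grid Candidate strengths.
#' @param cfg [agreement_config()].
#' @return The fitted `w_k` with attribute `auc` (the AUC profile).
#' @export
fit_center_bias <- function(base_maps, fixation_maps,
                            wk_grid = seq(0, 1, by = 0.05),
                            cfg = agreement_config()) {
  aucs <- vapply(wk_grid, function(wk) {
    mean(mapply(function(sm, fm) {
      agreement_auc(apply_center_bias(sm, wk), fm, cfg)$auc
    }, base_maps, fixation_maps))
  }, numeric(1))
  out <- wk_grid[which.max(aucs)]
  attr(out, "auc") <- stats::setNames(aucs, wk_grid)
  out
}
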