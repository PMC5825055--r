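# Seeded synthetic observer cohorts: the stand-in for non-deposited
# eye-tracking data. Three independent generative knobs map onto the three
# analysis axes: the exploration temperature tau spreads or concentrates
# fixations (entropy), per-group attention maps control preferred regions
# (agreement), and a central-Gaussian mixture weight lambda_cb controls the
# center bias.

#' Group profile for the cohort simulator
#'
#' @param label Group label (e.g. `"4y"`, `"adult"`).
#' @param n_observers Observers in the group (default 20, the scale of a
#'   typical developmental eye-tracking group).
#' @param fixations_per_observer Fixations per observer per image
#'   (default 30, roughly 10 s of free viewing at 3 fixations/s).
#' @param lambda_cb Central-mixture weight in `[0, 1]`: the fraction of
#'   fixation density drawn toward a central Gaussian.
#' @param tau Exploration temperature (> 0). The sampling density is the
#'   attention map raised to `1 / tau`: low `tau` concentrates fixations on
#'   the strongest peaks (child-like, low entropy), high `tau` spreads them
#'   (adult-like, high entropy).
#' @param source_mode Where the group's attention map comes from:
#'   `"explicit_map"` (supply `attention_maps`), `"uniform"`,
#'   `"coarse_conspicuity"` (the "S" model at `s = s_true`), or
#'   `"full_conspicuity"` (the "S" model at `s = 1`).
#' @param s_true Scale-subset start used by `"coarse_conspicuity"`.
#' @param attention_maps Named list (by image id) of matrices for
#'   `"explicit_map"`.
#' @param center_sigma Central-Gaussian sigma; default `width / 6`.
#' @return Object of class `group_profile`.
#' @export
group_profile <- function(label, n_observers = 20,
                          fixations_per_observer = 30,
                          lambda_cb = 0.2, tau = 1,
                          source_mode = c("explicit_map", "uniform",
                                          "coarse_conspicuity",
                                          "full_conspicuity"),
                          s_true = 5, attention_maps = NULL,
                          center_sigma = NULL) {
  source_mode <- match.arg(source_mode)
  if (lambda_cb < 0 || lambda_cb > 1)
    stop("lambda_cb must be in [0, 1]", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  structure(list(label = label, n_observers = n_observers,
                 fixations_per_observer = fixations_per_observer,
                 lambda_cb = lambda_cb, tau = tau,
                 source_mode = source_mode, s_true = s_true,
                 attention_maps = attention_maps,
                 center_sigma = center_sigma),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat("<group_profile> ", x$label, ": ", x$n_observers, " obs x ",
      x$fixations_per_observer, " fix, lambda_cb = ", x$lambda_cb,
      ", tau = ", x$tau, ", source = ", x$source_mode, "\n", sep = "")
  invisible(x)
}

#' Pop-out test stimulus
#'
#' A regular `n x n` array of bars on a dark background with exactly one
#' odd item: a red bar among green bars (`odd_feature = "color"`) or a
#' horizontal bar among vertical bars (`"orientation"`). The classic
#' validation stimulus for a bottom-up saliency model: the odd item should
#' attract the global maximum.
#'
#' @param width,height Image dimensions in pixels. The default 512 px keeps
#'   the bars visible across the pyramid levels the center-surround stage
#'   uses; at 256 px the bars vanish above level 2 and the orientation
#'   channel degrades.
#' @param n Grid size (`n >= 3`).
#' @param odd_feature `"color"` or `"orientation"`.
#' @param seed Seed controlling the odd item's position and the small
#'   positional jitter of all items.
#' @return List with `image` (RGB array), `mask` (logical matrix marking
#'   the odd item's bounding box) and `odd_cell` (`c(row, col)`).
#' @export
make_popout_image <- function(width = 512, height = 512, n = 5,
                              odd_feature = c("color", "orientation"),
                              seed = NULL) {
  odd_feature <- match.arg(odd_feature)
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  with_seed(seed, {
    img <- array(0.25, dim = c(height, width, 3))
    cell_w <- width / n; cell_h <- height / n
    bar_len <- round(0.5 * min(cell_w, cell_h))
    bar_wid <- max(2, round(0.14 * min(cell_w, cell_h)))
    odd <- c(sample.int(n, 1), sample.int(n, 1))
    mask <- matrix(FALSE, height, width)
    for (r in seq_len(n)) for (cc in seq_len(n)) {
      jx <- stats::runif(1, -0.03, 0.03) * cell_w
      jy <- stats::runif(1, -0.03, 0.03) * cell_h
      cx <- (cc - 0.5) * cell_w + jx
      cy <- (r - 0.5) * cell_h + jy
      is_odd <- all(c(r, cc) == odd)
      horizontal <- is_odd && odd_feature == "orientation"
      # moderately saturated distractors; the odd color is the unique
      # strong opponent response, as in classic pop-out displays
      col3 <- if (is_odd && odd_feature == "color") c(0.9, 0.08, 0.08)
              else c(0.1, 0.45, 0.1)
      half_l <- bar_len / 2; half_w <- bar_wid / 2
      if (horizontal) { hx <- half_l; hy <- half_w } else { hx <- half_w; hy <- half_l }
      rows <- max(1, round(cy - hy)):min(height, round(cy + hy))
      cols <- max(1, round(cx - hx)):min(width, round(cx + hx))
      for (ch in 1:3) img[rows, cols, ch] <- col3[ch]
      if (is_odd) {
        pad <- ceiling(bar_len / 2) + 2
        mrows <- max(1, round(cy - pad)):min(height, round(cy + pad))
        mcols <- max(1, round(cx - pad)):min(width, round(cx + pad))
        mask[mrows, mcols] <- TRUE
      }
    }
    list(image = img, mask = mask, odd_cell = odd)
  })
}

#' Layered test scene: coarse blobs plus fine details
#'
#' Generates a scene containing a few large low-frequency color blobs and
#' many small high-contrast details at disjoint recorded locations — a
#' controllable analog of the coarse-versus-fine level-of-detail structure
#' of natural scenes. If disjoint placement fails after 100 attempts the
#' corresponding count is reduced with a warning.
#'
#' @param width,height Image dimensions.
#' @param n_coarse_blobs,n_fine_details Element counts (each >= 1).
#' @param seed Seed for positions and colors.
#' @return List with `image` (RGB array), `coarse` and `fine` (data frames
#'   of 0-based `x`, `y` centers).
#' @export
make_layered_scene <- function(width = 256, height = 256,
                               n_coarse_blobs = 3, n_fine_details = 20,
                               seed = NULL) {
  stopifnot(n_coarse_blobs >= 1, n_fine_details >= 1)
  with_seed(seed, {
    img <- array(0.45, dim = c(height, width, 3))
    blob_sigma <- min(width, height) / 10
    blob_r <- 1.6 * blob_sigma
    fine_r <- 4
    placed <- matrix(numeric(0), 0, 3)  # x, y, radius
    place <- function(n, radius, margin) {
      pts <- matrix(numeric(0), 0, 2)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (att in 1:100) {
          x <- stats::runif(1, margin, width - 1 - margin)
          y <- stats::runif(1, margin, height - 1 - margin)
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2) >
                  radius + placed[, 3])) {
            ok <- TRUE; break
          }
        }
        if (!ok) {
          warning("could not place all elements disjointly; reduced count")
          break
        }
        placed <<- rbind(placed, c(x, y, radius))
        pts <- rbind(pts, c(x, y))
      }
      pts
    }
    coarse <- place(n_coarse_blobs, blob_r, blob_r)
    fine <- place(n_fine_details, fine_r, fine_r + 2)
    yy <- matrix(seq_len(height) - 1, height, width)
    xx <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
    for (i in seq_len(nrow(coarse))) {
      g <- exp(-((xx - coarse[i, 1])^2 + (yy - coarse[i, 2])^2) /
                 (2 * blob_sigma^2))
      col3 <- stats::runif(3, 0.1, 1)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.8 * g) +
                                     0.8 * g * col3[ch]
    }
    for (i in seq_len(nrow(fine))) {
      cx <- round(fine[i, 1]); cy <- round(fine[i, 2])
      col3 <- if (stats::runif(1) < 0.5) c(0.02, 0.02, 0.02)
              else stats::runif(3, 0, 1)
      rows <- max(1, cy - 2):min(height, cy + 4)
      cols <- max(1, cx - 2):min(width, cx + 4)
      # small checkered square: high-frequency content
      chk <- outer(rows, cols, function(a, b) (a + b) %% 2 == 0)
      for (ch in 1:3) {
        block <- img[rows, cols, ch]
        block[chk] <- col3[ch]
        block[!chk] <- 1 - col3[ch]
        img[rows, cols, ch] <- block
      }
    }
    list(image = img,
         coarse = data.frame(x = coarse[, 1], y = coarse[, 2]),
         fine = data.frame(x = fine[, 1], y = fine[, 2]))
  })
}

#' Synthetic attention map with central and peripheral interest
#'
#' Builds an explicit attention map for the simulator's `"explicit_map"`
#' mode: a pedestal plus Gaussian interest lobes, some placed deep in the
#' image corners (peripheral interest) and some near the center, all offset
#' by a consistent eccentricity so that a cohort's average saliency map has
#' a measurable off-center centroid. This is the configuration used to
#' probe center-bias recovery: a central-mixture cohort concentrates on the
#' central lobes while a scene-driven cohort also visits the corner lobes.
#'
#' @param width,height Map dimensions.
#' @param n_peripheral,n_central Lobe counts.
#' @param pedestal Baseline attention level (relative to lobe peaks ~1).
#' @param offset_frac Consistent eccentric offset of all lobes, as a
#'   fraction of the image size.
#' @param seed Seed for lobe placement.
#' @return A `height x width` attention matrix (not normalized).
#' @export
make_attention_map <- function(width = 256, height = 256,
                               n_peripheral = 3, n_central = 3,
                               pedestal = 0.45, offset_frac = 0.08,
                               seed = NULL) {
  with_seed(seed, {
    yy <- matrix(seq_len(height) - 1, height, width)
    xx <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
    A <- matrix(pedestal, height, width)
    ox <- offset_frac * width; oy <- offset_frac * height
    sig <- width / 13
    corners <- list(c(0, 0), c(0, width - 1),
                    c(height - 1, 0), c(height - 1, width - 1))
    ci <- sample(seq_along(corners), min(n_peripheral, 4))
    for (k in seq_len(n_peripheral)) {
      co <- corners[[ci[((k - 1) %% length(ci)) + 1]]]
      f <- stats::runif(1, 0.75, 0.9)
      cy <- (height - 1) / 2 + f * (co[1] - (height - 1) / 2) + oy
      cx <- (width - 1) / 2 + f * (co[2] - (width - 1) / 2) + ox
      A <- A + stats::runif(1, 0.7, 1) *
        exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sig^2))
    }
    for (k in seq_len(n_central)) {
      cx <- (width - 1) / 2 + stats::runif(1, -0.15, 0.15) * width + ox
      cy <- (height - 1) / 2 + stats::runif(1, -0.15, 0.15) * height + oy
      A <- A + stats::runif(1, 0.7, 1) *
        exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sig^2))
    }
    A
  })
}

# resolve a profile's attention map for one stimulus (matrix, >= 0)
resolve_attention <- function(profile, image, image_id, stack_cache = NULL) {
  switch(profile$source_mode,
    uniform = matrix(1, dim(image)[1], dim(image)[2]),
    explicit_map = {
      A <- profile$attention_maps[[image_id]]
      if (is.null(A)) stop("no explicit attention map for image '",
                           image_id, "'", call. = FALSE)
      A
    },
    coarse_conspicuity = ,
    full_conspicuity = {
      s <- if (profile$source_mode == "full_conspicuity") 1 else profile$s_true
      st <- if (!is.null(stack_cache)) stack_cache[[image_id]] else NULL
      if (is.null(st)) st <- conspicuity_stack(image)
      saliency_S(st, s = s, dims = dim(image)[1:2])$grid
    })
}

#' Simulate the fixations of one observer group
#'
#' For each stimulus an attention map `A` is resolved from the profile's
#' `source_mode`; fixations are drawn i.i.d. per observer from the density
#' `[(1 - lambda_cb) * A + lambda_cb * G_center]^(1/tau)` (renormalized),
#' where `G_center` is a central Gaussian. Regeneration from the same seed
#' is bit-identical.
#'
#' @param stimuli Named list of RGB arrays (or matrices when the profile
#'   does not need pixel data); names are the image ids.
#' @param profile A [group_profile()].
#' @param seed Integer seed.
#' @param stack_cache Optional named list of precomputed
#'   [conspicuity_stack()]s (saves recomputation across groups/seeds).
#' @return Object of class `simulated_cohort`: `table` (a
#'   [fixation_table]), `truth` (the per-image attention maps used),
#'   `profile`, `seed`.
#' @export
simulate_group_fixations <- function(stimuli, profile, seed,
                                     stack_cache = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  ids <- names(stimuli)
  if (is.null(ids)) stop("stimuli must be a named list", call. = FALSE)
  recs <- list(); truth <- list()
  dims <- data.frame(image = ids,
                     width = vapply(stimuli, function(s) dim(s)[2], 0),
                     height = vapply(stimuli, function(s) dim(s)[1], 0))
  for (ii in seq_along(ids)) {
    id <- ids[[ii]]
    img <- stimuli[[ii]]
    h <- dim(img)[1]; w <- dim(img)[2]
    A <- resolve_attention(profile, img, id, stack_cache)
    truth[[id]] <- A
    if (sum(A) <= 0 && profile$lambda_cb == 0)
      stop("all-zero sampling density for image '", id, "'", call. = FALSE)
    An <- if (sum(A) > 0) A / sum(A) else matrix(0, h, w)
    cs <- profile$center_sigma %||% (w / 6)
    G <- center_gaussian(h, w, cs)
    mix <- (1 - profile$lambda_cb) * An + profile$lambda_cb * G
    dens <- mix^(1 / profile$tau)
    tot <- sum(dens)
    if (tot <= 0 || !is.finite(tot))
      stop("all-zero sampling density for image '", id, "'", call. = FALSE)
    prob <- as.vector(dens) / tot         # column-major over pixels
    nfix <- profile$fixations_per_observer
    recs[[id]] <- with_seed(derive_seed(seed, ii), {
      draws <- sample.int(h * w, profile$n_observers * nfix,
                          replace = TRUE, prob = prob)
      data.frame(
        observer = rep(paste0(profile$label, "_obs",
                              seq_len(profile$n_observers)), each = nfix),
        group = profile$label,
        image = id,
        x = (draws - 1) %/% h,     # column index, 0-based
        y = (draws - 1) %% h,      # row index, 0-based
        index = rep(seq_len(nfix) - 1L, profile$n_observers)
      )
    })
  }
  table <- fixation_table(do.call(rbind, recs), dims,
                          groups = profile$label)
  structure(list(table = table, truth = truth, profile = profile,
                 seed = seed),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> group ", x$profile$label, ", seed ", x$seed,
      ": ", nrow(x$table$records), " fixations on ",
      nrow(x$table$dims), " image(s)\n", sep = "")
  invisible(x)
}

#' Simulate a multi-group cohort
#'
#' Runs [simulate_group_fixations()] for each profile (with per-group
#' derived seeds) and merges the tables.
#'
#' @param stimuli Named list of RGB arrays.
#' @param profiles List of [group_profile()]s.
#' @param seed Integer master seed.
#' @param stack_cache Optional precomputed stacks (see
#'   [simulate_group_fixations()]).
#' @return A [fixation_table] covering all groups, with the per-group
#'   attention maps in attribute `truth`.
#' @export
simulate_cohort <- function(stimuli, profiles, seed, stack_cache = NULL) {
  tabs <- list(); truth <- list()
  for (k in seq_along(profiles)) {
    sc <- simulate_group_fixations(stimuli, profiles[[k]],
                                   derive_seed(seed, 7919 * k),
                                   stack_cache = stack_cache)
    tabs[[k]] <- sc$table$records
    truth[[profiles[[k]]$label]] <- sc$truth
  }
  out <- fixation_table(do.call(rbind, tabs),
                        dims = data.frame(
                          image = names(stimuli),
                          width = vapply(stimuli, function(s) dim(s)[2], 0),
                          height = vapply(stimuli, function(s) dim(s)[1], 0)),
                        groups = vapply(profiles, `[[`, "", "label"))
  attr(out, "truth") <- truth
  out
}
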