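# Shared fixtures, built in code. Heavier objects (conspicuity stacks) are
# computed once here and reused across test files.

# small fixation table: 2 groups, 1 image, hand-placed coordinates
tiny_fixation_table <- function() {
  fixation_table(
    records = data.frame(
      observer = c("a1", "a1", "a2", "b1", "b1"),
      group = c("kid", "kid", "kid", "adult", "adult"),
      image = "img1",
      x = c(10.4, 10.4, 30, 40, 50),
      y = c(20.6, 20.6, 35, 45, 55)
    ),
    dims = data.frame(image = "img1", width = 64, height = 64)
  )
}

# deterministic Gaussian-blob saliency map (already in [0, 1])
blob_map <- function(h, w, cx, cy, sigma) {
  yy <- matrix(seq_len(h) - 1, h, w)
  xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sigma^2))
}

# fixation map with n fixations at given 0-based pixel coords
fmap_at <- function(h, w, xy) {
  g <- matrix(0L, h, w)
  g[cbind(xy[, 2] + 1, xy[, 1] + 1)] <- 1L
  structure(list(grid = g, image_id = "f", group = "g",
                 n_fixations = nrow(xy)), class = "fixation_map")
}

# independent rank-based AUC (Mann-Whitney): probability that a fixated
# pixel outranks a non-fixated one under the saliency values
rank_auc <- function(saliency, fixmap) {
  v <- as.vector(saliency)
  f <- as.vector(fixmap) > 0
  r <- rank(v)
  nF <- sum(f); nN <- sum(!f)
  (sum(r[f]) - nF * (nF + 1) / 2) / (nF * nN)
}

# layered scenes + stacks shared across itti/model tests (computed once)
.shared <- new.env()
shared_scenes <- function(n = 2, seed0 = 900) {
  key <- paste0("scenes", n, "_", seed0)
  if (is.null(.shared[[key]])) {
    sc <- lapply(seq_len(n), function(i)
      make_layered_scene(seed = seed0 + i)$image)
    names(sc) <- paste0("sc", seq_len(n))
    .shared[[key]] <- sc
  }
  .shared[[key]]
}
shared_stacks <- function(n = 2, seed0 = 900) {
  key <- paste0("stacks", n, "_", seed0)
  if (is.null(.shared[[key]]))
    .shared[[key]] <- lapply(shared_scenes(n, seed0), conspicuity_stack)
  .shared[[key]]
}
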