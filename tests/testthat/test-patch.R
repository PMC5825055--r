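test_that("patch features have the documented shape and content", {
  img <- array(0.5, dim = c(64, 64, 3))
  pf <- extract_patch_features(img, 16)
  expect_equal(pf$grid$np, 16)
  expect_equal(nrow(pf$X), 5 * 16 * 16)   # 1280
  # constant image: identical feature vectors, zero gradients
  expect_equal(max(apply(pf$X, 1, function(r) diff(range(r)))), 0)
  expect_true(all(pf$X[(3 * 256 + 1):(5 * 256), ] == 0))

  # checkerboard aligned to patches: two alternating feature vectors
  chk <- array(0, dim = c(32, 32, 3))
  tile <- matrix(rep(c(0.2, 0.8), each = 8, times = 2), 16, 16)
  for (ch in 1:3) chk[, , ch] <- rbind(cbind(tile * 0 + 0.2, tile * 0 + 0.8),
                                       cbind(tile * 0 + 0.8, tile * 0 + 0.2))
  pc <- extract_patch_features(chk, 16)
  lab <- 1:(3 * 256)   # color rows; the gradient rows see the block edges
  expect_equal(pc$X[lab, 1], pc$X[lab, 4])
  expect_equal(pc$X[lab, 2], pc$X[lab, 3])
  expect_gt(max(abs(pc$X[lab, 1] - pc$X[lab, 2])), 1)

  # patch centers are 0-based pixel centers
  expect_equal(pf$grid$centers$x[1], 7.5)
  expect_equal(pf$grid$centers$y[16], 55.5)
  expect_error(extract_patch_features(img, 12), "t must be")
  expect_error(extract_patch_features(array(0.5, dim = c(32, 32, 3)), 64),
               "exceeds")
})

test_that("PCA reduction keeps the spectrum contract", {
  # full variance: reduced distances equal full distances (isometry)
  set.seed(7)
  X <- matrix(rnorm(40 * 20), 40, 20)
  red <- pca_reduce(X, variance_keep = 1)
  expect_equal(as.vector(dist(t(red$X_reduced))), as.vector(dist(t(X))),
               tolerance = 1e-9)
  expect_true(all(diff(red$lambda) <= 1e-9))
  expect_equal(crossprod(red$E), diag(red$d), tolerance = 1e-9)

  # identical patches: degenerate, d = 0
  red0 <- pca_reduce(matrix(1, 10, 5))
  expect_true(red0$degenerate)
  expect_equal(red0$d, 0)

  # constructed rank-2 spectrum lambda = (9, 1, 0, ...): d = 1 at 0.9
  np <- 20
  s1 <- rep(c(1, -1), np / 2); s1 <- s1 / sqrt(sum(s1^2)) * sqrt(9 * (np - 1))
  s2 <- rep(c(1, 1, -1, -1), np / 4); s2 <- s2 / sqrt(sum(s2^2)) * sqrt(1 * (np - 1))
  U <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  X2 <- U %*% rbind(s1, s2)
  red2 <- pca_reduce(X2, variance_keep = 0.9)
  expect_equal(red2$lambda[1:2], c(9, 1), tolerance = 1e-9)
  expect_equal(red2$d, 1)
})

test_that("patch dissimilarity matches the hand-worked and brute-force oracles", {
  # 2-patch toy: reduced coords 0 and 3, normalized distance 1 -> 3/2 each
  s <- agesal:::patch_dissimilarity_scores(
    matrix(c(0, 3), 1, 2),
    matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE),  # centers 5 px apart
    diag_len = 5
  )
  expect_equal(s, c(1.5, 1.5))

  # brute-force double-loop oracle on random <= 36-patch instances
  set.seed(9)
  for (rep in 1:5) {
    np <- sample(6:36, 1)
    d <- sample(1:4, 1)
    Xr <- matrix(rnorm(d * np), d, np)
    ctr <- cbind(runif(np, 0, 100), runif(np, 0, 80))
    omega <- runif(np, 0.5, 1)
    fast <- agesal:::patch_dissimilarity_scores(Xr, ctr, diag_len = 128,
                                                omega = omega)
    slow <- numeric(np)
    for (i in 1:np) {
      acc <- 0
      for (j in 1:np) {
        if (i == j) next
        l1 <- sum(abs(Xr[, i] - Xr[, j]))
        dd <- sqrt(sum((ctr[i, ] - ctr[j, ])^2)) / 128
        acc <- acc + l1 / (1 + dd)
      }
      slow[i] <- omega[i] * acc
    }
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("an anomalous patch is the top-scoring patch", {
  set.seed(13)
  for (rep in 1:5) {
    img <- array(0.4, dim = c(64, 64, 3))
    cell <- sample(0:15, 1)
    r0 <- (cell %/% 4) * 16; c0 <- (cell %% 4) * 16
    img[(r0 + 1):(r0 + 16), (c0 + 1):(c0 + 16), 1] <- 0.9  # odd red patch
    pf <- extract_patch_features(img, 16)
    red <- pca_reduce(pf$X)
    ps <- patch_saliency(pf$grid, red)
    expect_equal(which.max(ps$scores_raw), cell %/% 4 * 4 + cell %% 4 + 1)
    # the full-resolution map peaks inside the odd patch
    am <- which(ps$map$grid == max(ps$map$grid), arr.ind = TRUE)[1, ]
    expect_true(am[1] >= r0 + 1 && am[1] <= r0 + 16 &&
                am[2] >= c0 + 1 && am[2] <= c0 + 16)
  }

  # homogeneous image: all scores equal (degenerate reduction)
  hom <- array(0.3, dim = c(64, 64, 3))
  pf0 <- extract_patch_features(hom, 16)
  ps0 <- patch_saliency(pf0$grid, pca_reduce(pf0$X))
  expect_true(all(ps0$scores_raw == 0))
  expect_true(attr(ps0$map, "degenerate"))
})

test_that("patch saliency is invariant to patch enumeration order", {
  set.seed(15)
  np <- 12; d <- 3
  Xr <- matrix(rnorm(d * np), d, np)
  ctr <- cbind(runif(np, 0, 60), runif(np, 0, 60))
  s0 <- agesal:::patch_dissimilarity_scores(Xr, ctr, diag_len = 85)
  perm <- sample(np)
  s1 <- agesal:::patch_dissimilarity_scores(Xr[, perm], ctr[perm, ],
                                            diag_len = 85)
  expect_equal(s1, s0[perm], tolerance = 1e-12)
})

test_that("multi-scale subsets combine per-size maps as documented", {
  img <- shared_scenes()[[1]]
  # singleton subset equals that size's map
  single <- multiscale_patch_saliency(img, t_subset = 32)
  pf <- extract_patch_features(img, 32)
  direct <- patch_saliency(pf$grid, pca_reduce(pf$X),
                           smooth_sigma = 16)$map
  expect_equal(single$grid, direct$grid, tolerance = 1e-12)

  # subsets {1..4} and {2..4} differ only by the 64-px map's contribution
  m_all <- multiscale_patch_saliency(img, patch_scale_subset(1:4))
  m_234 <- multiscale_patch_saliency(img, patch_scale_subset(2:4))
  # reconstruct from the four per-size maps
  sizes <- patch_scale_subset(1:4)
  per <- lapply(sizes, function(t) {
    p <- extract_patch_features(img, t)
    patch_saliency(p$grid, pca_reduce(p$X), smooth_sigma = 4)$map$grid
  })
  mm <- agesal:::minmax01
  expect_equal(m_all$grid, mm(Reduce(`+`, per) / 4), tolerance = 1e-12)
  expect_equal(m_234$grid, mm(Reduce(`+`, per[-1]) / 3), tolerance = 1e-12)

  expect_error(multiscale_patch_saliency(img, integer(0)), "empty")
  expect_equal(patch_scale_subset(3:4), c(16, 8))
})
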