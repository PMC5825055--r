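test_that("explorativeness entropy matches hand values and the Shannon identity", {
  # constant map: single occupied bin, H = 0, degenerate flag
  e0 <- explorativeness_entropy(matrix(0.5, 8, 8))
  expect_equal(e0$H, 0)
  expect_true(e0$degenerate)

  # 4-pixel map {0, 1/3, 2/3, 1}, B = 4: one count per bin, H = 4 log 4
  e4 <- explorativeness_entropy(matrix(c(0, 1/3, 2/3, 1), 2, 2), bins = 4)
  expect_equal(e4$H, 4 * log(4))
  expect_equal(e4$histogram, rep(1L, 4))

  # identity H = L * Shannon(p) against an independent entropy routine,
  # on random maps
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(runif(32 * 32), 32, 32)
    m <- (m - min(m)) / (max(m) - min(m))
    e <- explorativeness_entropy(m)
    p <- e$histogram / e$L
    p <- p[p > 0]
    shannon <- sum(-p * log(p))
    expect_equal(e$H, e$L * shannon, tolerance = 1e-12)
    expect_lte(e$H, e$L * log(256))
  }
  expect_error(explorativeness_entropy(matrix(2, 2, 2)), "normalized")
  expect_error(explorativeness_entropy(matrix(0.1, 2, 2), bins = 1), "bins")
})

test_that("thresholding keeps the top coverage with raster tie-breaks", {
  # coverage 1: everything
  expect_true(all(threshold_saliency_map(matrix(runif(20), 4, 5), 1) == 1))

  # strictly increasing 10-pixel map: exactly the top 3
  m <- matrix(1:10 / 10, 2, 5)           # column-major fill
  mask <- threshold_saliency_map(m, 0.3)
  expect_equal(sum(mask), 3)
  expect_true(all(mask[m >= 0.8] == 1))

  # constant map: ceiling(L/2) pixels, raster-first (row-major) oracle
  cm <- matrix(1, 3, 4)
  mask2 <- threshold_saliency_map(cm, 0.5)
  oracle <- matrix(0L, 3, 4)
  rowmajor <- arrayInd(1:6, c(4, 3))     # first 6 cells in row-major order
  oracle[cbind(rowmajor[, 2], rowmajor[, 1])] <- 1L
  expect_identical(mask2, oracle)
  expect_error(threshold_saliency_map(cm, 0), "coverage")
})

test_that("agreement AUC behaves like a saliency ROC", {
  set.seed(21)
  h <- 64; w <- 64
  xy <- cbind(sample(0:(w - 1), 30), sample(0:(h - 1), 30))
  fm <- fmap_at(h, w, xy)

  # self-prediction: the blurred map of the fixations predicts them
  # (fine threshold levels; the coarse T = 20 discretization alone caps
  # the trapezoid area well below 1)
  cfg_px <- agreement_config(coverage_levels = (1:(h * w)) / (h * w))
  sm <- build_human_saliency_map(fm)   # default width-scaled sigma
  roc <- agreement_auc(sm, fm, cfg_px)
  expect_gte(roc$auc, 0.95)
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_equal(range(roc$points$fpr), c(0, 1))

  # per-pixel threshold levels agree with the rank-statistic oracle
  for (i in 1:5) {
    m <- matrix(runif(h * w), h, w)
    a1 <- agreement_auc(m, fm, cfg_px)$auc
    expect_equal(a1, rank_auc(m, fm$grid), tolerance = 0.02)
  }

  # monotone-transform invariance of the source map
  m <- matrix(runif(h * w), h, w)
  a <- agreement_auc(m, fm)$auc
  expect_equal(agreement_auc(sqrt(m), fm)$auc, a)
  expect_equal(agreement_auc(exp(3 * m), fm)$auc, a)
  expect_gte(a, 0); expect_lte(a, 1)

  expect_error(agreement_auc(m, matrix(0L, h, w)), "empty")
  expect_error(agreement_auc(matrix(0, 2, 2), fm), "dimensions")
})

test_that("agreement matrix is coherent across groups and relabeling", {
  tab <- tiny_fixation_table()
  # single group, single image: 1x1 matrix equals agreement_auc directly
  m1 <- agreement_matrix(tab, groups = "kid")
  sm <- build_human_saliency_map(build_fixation_map(tab, "kid", "img1"))
  expect_equal(m1[1, 1],
               agreement_auc(sm, build_fixation_map(tab, "kid", "img1"))$auc)

  # two identical groups: symmetric, diagonal == off-diagonal
  rec <- tab$records[tab$records$group == "kid", ]
  rec2 <- rec; rec2$group <- "kid2"; rec2$observer <- paste0("x", rec2$observer)
  dup <- fixation_table(rbind(rec, rec2), tab$dims)
  m2 <- agreement_matrix(dup)
  expect_equal(m2[1, 1], m2[2, 2])
  expect_equal(m2[1, 2], m2[2, 1])

  # invariance under observer relabeling within a group
  rel <- tab
  rel$records$observer <- paste0("obs", as.integer(factor(rel$records$observer)))
  expect_equal(agreement_matrix(rel), agreement_matrix(tab))

  # missing cells are skipped with a warning
  part <- tab$records[-(4:5), ]
  part <- rbind(part, data.frame(observer = "b9", group = "adult",
                                 image = "img2", x = 1, y = 1))
  ptab <- fixation_table(part, rbind(tab$dims,
                                     data.frame(image = "img2", width = 64,
                                                height = 64)))
  expect_warning(agreement_matrix(ptab), "skipped")
})

test_that("center map centroid and prediction behave geometrically", {
  # radially symmetric central map: centroid at center
  g <- blob_map(101, 101, 50, 50, 10)
  cb <- compute_center_map(list(g))
  expect_lt(cb$distance_px, 1e-9)

  # mirrored point masses: centroid back at the center
  p1 <- matrix(0, 51, 51); p1[11, 11] <- 1
  p2 <- matrix(0, 51, 51); p2[41, 41] <- 1
  expect_lt(compute_center_map(list(p1, p2))$distance_px, 1e-9)

  # single point mass at (0,0) on 101x101: distance 50 * sqrt(2)
  pm <- matrix(0, 101, 101); pm[1, 1] <- 1
  expect_equal(compute_center_map(list(pm))$distance_px, 50 * sqrt(2))
  expect_error(compute_center_map(list()), "no maps")

  # all fixations at the most central pixel: near-perfect prediction
  # (fine threshold levels: the coarse default discretization alone caps
  # the trapezoid area at 1 - 0.05/2)
  cb2 <- compute_center_map(list(blob_map(64, 64, 31.5, 31.5, 12)))
  fm <- fmap_at(64, 64, cbind(32, 32))
  expect_gte(center_map_prediction_auc(cb2, fm, agreement_config(T = 200)),
             0.99)

  # uniform fixations: chance-level prediction on average
  set.seed(31)
  aucs <- replicate(50, {
    xy <- cbind(sample(0:63, 20, replace = TRUE),
                sample(0:63, 20, replace = TRUE))
    center_map_prediction_auc(cb2, fmap_at(64, 64, xy))
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("entropy separates scattered from clustered gaze", {
  set.seed(41)
  wins <- 0
  for (i in 1:10) {
    n <- 40
    scat <- cbind(sample(0:127, n, TRUE), sample(0:127, n, TRUE))
    clus <- cbind(pmin(pmax(round(rnorm(n, 64, 6)), 0), 127),
                  pmin(pmax(round(rnorm(n, 64, 6)), 0), 127))
    Hs <- explorativeness_entropy(
      build_human_saliency_map(fmap_at(128, 128, scat), sigma = 4))$H
    Hc <- explorativeness_entropy(
      build_human_saliency_map(fmap_at(128, 128, clus), sigma = 4))$H
    wins <- wins + (Hs > Hc)
  }
  expect_equal(wins, 10)
})
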