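test_that("pop-out stimuli are constructed as specified", {
  po <- make_popout_image(seed = 1, odd_feature = "color")
  img <- po$image
  # exactly one red bar: red-dominant pixels form one connected block,
  # all inside the mask
  reddish <- img[, , 1] > 0.5 & img[, , 2] < 0.3
  expect_gt(sum(reddish), 20)
  expect_true(all(po$mask[reddish]))
  # mask is one item's bounding box, a small fraction of the image
  expect_lt(mean(po$mask), 0.03)
  expect_gt(sum(po$mask), 0)
  # different seeds move the odd item
  po2 <- make_popout_image(seed = 2, odd_feature = "color")
  expect_false(identical(po$odd_cell, po2$odd_cell))
  expect_error(make_popout_image(n = 2), "n must be")
})

test_that("layered scenes record disjoint coarse/fine locations", {
  sc <- make_layered_scene(n_coarse_blobs = 3, n_fine_details = 20,
                           seed = 5)
  expect_equal(nrow(sc$coarse), 3)
  expect_equal(nrow(sc$fine), 20)
  pts <- rbind(sc$coarse, sc$fine)
  d <- as.matrix(dist(pts))
  expect_true(all(d[upper.tri(d)] > 4))
  expect_true(all(pts$x >= 0 & pts$x < 256 & pts$y >= 0 & pts$y < 256))

  # seeded regeneration is bit-identical
  sc2 <- make_layered_scene(n_coarse_blobs = 3, n_fine_details = 20,
                            seed = 5)
  expect_identical(sc$image, sc2$image)

  # blob-only image is low-frequency dominated relative to detail-only
  blob <- make_layered_scene(n_coarse_blobs = 4, n_fine_details = 1,
                             seed = 6)$image
  fine <- make_layered_scene(n_coarse_blobs = 1, n_fine_details = 40,
                             seed = 6)$image
  lowfreq_share <- function(im) {
    g <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
    sp <- Mod(stats::fft(g - mean(g)))^2
    h <- nrow(g); w <- ncol(g)
    fy <- pmin(0:(h - 1), h - (0:(h - 1))) / h
    fx <- pmin(0:(w - 1), w - (0:(w - 1))) / w
    rad <- sqrt(outer(fy^2, fx^2, `+`))
    sum(sp[rad < 0.05]) / sum(sp)
  }
  expect_gt(lowfreq_share(blob), lowfreq_share(fine))
})

test_that("simulated fixations respect bounds, seeds and density modes", {
  stims <- list(a = array(0.5, dim = c(64, 96, 3)))
  A <- blob_map(64, 96, 30, 30, 6)
  pr <- group_profile("g", n_observers = 5, fixations_per_observer = 20,
                      lambda_cb = 0.3, tau = 1,
                      source_mode = "explicit_map",
                      attention_maps = list(a = A))
  sc <- simulate_group_fixations(stims, pr, seed = 10)
  r <- sc$table$records
  expect_equal(nrow(r), 100)
  expect_true(all(r$x >= 0 & r$x < 96 & r$y >= 0 & r$y < 64))
  expect_equal(length(unique(r$observer)), 5)

  # bit-identical regeneration
  sc2 <- simulate_group_fixations(stims, pr, seed = 10)
  expect_identical(sc$table$records, sc2$table$records)
  sc3 <- simulate_group_fixations(stims, pr, seed = 11)
  expect_false(identical(sc$table$records, sc3$table$records))

  # lambda = 1: centroid lands near the image center
  prc <- group_profile("g", n_observers = 25, fixations_per_observer = 20,
                       lambda_cb = 1, tau = 1, source_mode = "uniform")
  scc <- simulate_group_fixations(stims, prc, seed = 12)
  rc <- scc$table$records
  diag_len <- sqrt(96^2 + 64^2)
  expect_lt(sqrt((mean(rc$x) - 95 / 2)^2 + (mean(rc$y) - 63 / 2)^2),
            0.03 * diag_len)

  # all-zero density errors out
  przero <- group_profile("g", lambda_cb = 0, source_mode = "explicit_map",
                          attention_maps = list(a = matrix(0, 64, 96)))
  expect_error(simulate_group_fixations(stims, przero, seed = 1),
               "all-zero")
})

test_that("tau controls entropy and lambda controls centering independently", {
  stims <- list(a = array(0.5, dim = c(128, 128, 3)))
  A <- make_attention_map(128, 128, seed = 77)
  H_of <- function(tau, lam, seed) {
    pr <- group_profile("g", n_observers = 15, fixations_per_observer = 30,
                        lambda_cb = lam, tau = tau,
                        source_mode = "explicit_map",
                        attention_maps = list(a = A))
    sc <- simulate_group_fixations(stims, pr, seed = seed)
    fm <- build_fixation_map(sc$table, "g", "a")
    list(H = explorativeness_entropy(build_human_saliency_map(fm))$H,
         cen = compute_center_map(
           list(build_human_saliency_map(fm)))$distance_px)
  }
  # higher tau -> higher entropy at fixed lambda (paired seeds)
  wins <- 0
  for (i in 1:8) {
    a <- H_of(2, 0.3, 100 + i); b <- H_of(0.4, 0.3, 100 + i)
    wins <- wins + (a$H > b$H)
  }
  expect_equal(wins, 8)
  # higher lambda -> smaller centroid distance at fixed tau
  wins2 <- 0
  for (i in 1:8) {
    lo <- H_of(1, 0.1, 200 + i); hi <- H_of(1, 0.9, 200 + i)
    wins2 <- wins2 + (hi$cen < lo$cen)
  }
  expect_gte(wins2, 7)
})
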