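test_that("center weight map follows the closed form", {
  cw <- center_weight_map(101, 101)
  expect_equal(cw$grid[51, 51], 1)        # center
  expect_equal(cw$grid[1, 1], 0)          # farthest corner
  expect_equal(cw$grid[51, 1], 1 - 1 / sqrt(2))  # pixel (x=0, y=50)
  expect_true(all(cw$grid >= 0 & cw$grid <= 1))
})

test_that("center-bias modulation is identity at 0 and pure C at 1", {
  m <- matrix(runif(64 * 48), 48, 64)
  expect_identical(apply_center_bias(m, 0)$grid, m)
  sm <- saliency_map(minmax01(m), normalization = "minmax01",
                     source = "model_S")
  expect_identical(apply_center_bias(sm, 0), sm)

  # odd dims so the geometric center is a pixel and max(C) = 1 exactly
  flat <- matrix(0.7, 49, 65)
  out <- apply_center_bias(flat, 1)
  expect_equal(out$grid, center_weight_map(49, 65)$grid, tolerance = 1e-12)

  # stronger w_k strictly depresses the border ring relative to the
  # center (before re-normalization the ratio ring/center falls)
  C <- center_weight_map(48, 64)$grid
  ring <- C < 0.25
  ratios <- vapply(c(0.2, 0.5, 0.8), function(wk) {
    b <- m * (1 - wk + wk * C)
    mean(b[ring]) / mean(b[!ring])
  }, 0)
  expect_true(all(diff(ratios) < 0))
  expect_error(apply_center_bias(m, 1.2), "w_k")
})

test_that("training samples are extreme, separated and disjoint", {
  hm <- blob_map(96, 96, 30, 30, 8) + blob_map(96, 96, 70, 60, 8)
  hm <- hm / max(hm)
  ts <- select_training_samples(hm, P = 10, min_sep = 6)
  s <- ts$samples
  pos <- s[s$label == "positive", ]
  neg <- s[s$label == "negative", ]
  expect_equal(nrow(pos), 10)
  expect_equal(nrow(neg), 10)
  # pairwise separation within each class
  for (cl in list(pos, neg)) {
    d <- as.matrix(dist(cl[, c("x", "y")]))
    expect_true(all(d[upper.tri(d)] >= 6))
  }
  # positives are genuinely top-rated, negatives bottom-rated
  expect_true(all(pos$value >= quantile(hm, 0.9)))
  expect_true(all(neg$value <= quantile(hm, 0.5)))
  expect_equal(nrow(merge(pos[, c("x", "y")], neg[, c("x", "y")])), 0)

  # single-Gaussian map, P = 1: positive at the peak, negative at a
  # far minimum
  g <- blob_map(64, 64, 20, 24, 6)
  t1 <- select_training_samples(g / max(g), P = 1)
  expect_equal(unlist(t1$samples[1, c("x", "y")]), c(x = 20, y = 24))
  expect_lt(t1$samples$value[2], 1e-6)

  expect_error(select_training_samples(matrix(1, 8, 8), P = 1),
               "degenerate")
})

test_that("the linear max-margin fit separates and is chance on noise", {
  set.seed(5)
  # separable: perfect training accuracy
  X <- rbind(matrix(rnorm(60, 2), 30, 2), matrix(rnorm(60, -2), 30, 2))
  y <- rep(c(1, -1), each = 30)
  fit <- agesal:::fit_linear_svm(X, y)
  pred <- sign(X %*% fit$w + fit$b)
  expect_equal(as.vector(pred), y)
  expect_error(agesal:::fit_linear_svm(X, rep(1, 60)), "one class")

  # permuted labels: training AUC near chance over 20 seeds (n large
  # enough that the 3-parameter model cannot overfit noticeably)
  aucs <- vapply(1:20, function(i) {
    set.seed(i)
    n <- 200
    Xr <- matrix(runif(n * 3), n, 3)
    yr <- sample(rep(c(1, -1), n / 2))
    f <- agesal:::fit_linear_svm(Xr, yr)
    sc <- as.vector(Xr %*% f$w + f$b)
    r <- rank(sc)
    np <- sum(yr > 0)
    (sum(r[yr > 0]) - np * (np + 1) / 2) / (np * (n - np))
  }, 0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("SIC prediction reduces to single channels and full center bias", {
  st <- shared_stacks()[[1]]
  gm <- structure(list(group = "g", w = c(intensity = 1, color = 0,
                                          orientation = 0),
                       b = 0, s = 1, w_k = 0, sigma = NULL),
                  class = "group_model")
  out <- predict_saliency_SIC(st, gm)
  ibar <- agesal:::features_SIC(st, 1)$Ibar
  expect_equal(out$grid, minmax01(ibar), tolerance = 1e-12)

  gm$w_k <- 1
  out2 <- predict_saliency_SIC(st, gm)
  expect_equal(out2$grid[1, 1], 0)      # farthest corners zeroed
  expect_equal(out2$source, "model_SIC")
})

test_that("group models serialize to JSON and back", {
  gm <- structure(list(group = "4y", w = c(intensity = 0.2, color = 1.4,
                                           orientation = -0.1),
                       b = 0.05, s = 5, w_k = 0.6, sigma = NULL),
                  class = "group_model")
  f <- tempfile(fileext = ".json")
  write_group_model(gm, f)
  gm2 <- read_group_model(f)
  expect_equal(gm2$w, gm$w)
  expect_equal(gm2$b, gm$b)
  expect_equal(gm2$s, gm$s)
  expect_equal(gm2$w_k, gm$w_k)
})

test_that("training on a color-driven cohort favors the color channel", {
  stacks <- shared_stacks(4)
  scenes <- shared_scenes(4)
  atts <- lapply(stacks, function(st)
    agesal:::features_SIC(st, 1, dims = c(256, 256))$Cbar)
  pr <- group_profile("g", n_observers = 10, lambda_cb = 0, tau = 0.7,
                      source_mode = "explicit_map", attention_maps = atts)
  sc <- simulate_group_fixations(scenes, pr, seed = 3)
  gm <- train_group_model(stacks[1:3], sc$table, "g", s = 1, w_k = 0)
  expect_equal(names(which.max(abs(gm$w))), "color")
  # held-out prediction beats chance comfortably
  fm <- build_fixation_map(sc$table, "g", "sc4")
  expect_gt(agreement_auc(predict_saliency_SIC(stacks[[4]], gm), fm)$auc,
            0.7)
})

test_that("scale-subset scan has the right shape and reports s*", {
  stacks <- shared_stacks()
  pr <- group_profile("g", n_observers = 8, lambda_cb = 0, tau = 1,
                      source_mode = "coarse_conspicuity", s_true = 5)
  sc <- simulate_group_fixations(shared_scenes(), pr, seed = 2,
                                 stack_cache = stacks)
  scan <- scan_scale_subsets(stacks, sc$table, "g", s_values = c(1, 5))
  expect_equal(nrow(scan), 2)
  expect_named(scan, c("s", "mean_auc"))
  expect_true(attr(scan, "s_star") %in% c(1, 5))
  expect_true(all(scan$mean_auc >= 0 & scan$mean_auc <= 1))
})
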