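test_that("reconstruction with a stub model matches direct error computation", {
  scan <- tiny_phantom(n_slices = 14, canvas = c(16L, 16L), seed = 11)
  # stub "model": predicts the input triplet itself as the next triplet
  res <- reconstruct_scan(scan, function(x) x)
  expect_length(res, 9L)
  for (j in seq_along(res)) {
    direct <- sum((scan$slices[, , (j + 3):(j + 5)] -
                     scan$slices[, , j:(j + 2)])^2)
    expect_equal(res[[j]]$l2, direct, tolerance = 1e-10)
    expect_equal(sum(res[[j]]$error_map$values), res[[j]]$l2,
                 tolerance = 1e-10)
    expect_identical(res[[j]]$start_index, j)
  }
})

test_that("a perfect reconstructor scores zero everywhere", {
  scan <- tiny_phantom(n_slices = 16, canvas = c(16L, 16L), seed = 12)
  pairs <- enumerate_triplet_pairs(scan)
  k <- 0
  perfect <- function(x) {
    k <<- k + 1
    pairs[[k]]$target
  }
  res <- reconstruct_scan(scan, perfect)
  sc <- score_scan(res, "whole")
  expect_identical(sc$mean_l2_whole, 0)
  expect_identical(sc$mean_l2_top10, 0)
})

test_that("scan scores implement whole and top-window modes", {
  fake_results <- function(l2s) lapply(seq_along(l2s), function(j) {
    structure(list(start_index = j, error_map = list(values = l2s[j], P = 1L),
                   l2 = l2s[j]),
              class = "reconstruction_result")
  })
  expect_identical(score_scan(fake_results(c(1, 2, 3)), "whole",
                              window = 2L)$mean_l2_whole, 2)
  # exactly window sets: top equals whole
  ten <- score_scan(fake_results(rnorm(10)^2), "top10")
  expect_identical(ten$mean_l2_top10, ten$mean_l2_whole)
  # worked example: 12 sets, spikes at the end
  v <- c(rep(0, 10), 5, 5)
  sc <- score_scan(fake_results(v), "top10")
  expect_identical(sc$top10_start, 3L)
  expect_identical(sc$mean_l2_top10, 1)
  # fewer sets than the window falls back with a note
  expect_message(short <- score_scan(fake_results(c(1, 3)), "top10"),
                 "falls back")
  expect_identical(short$mean_l2_top10, 2)
  expect_error(score_scan(list(), "whole"),
               class = "madgan_validation_error")
})

test_that("top-window score equals exhaustive search on random vectors", {
  set.seed(41)
  fake_results <- function(l2s) lapply(seq_along(l2s), function(j) {
    structure(list(start_index = j, error_map = list(values = l2s[j], P = 1L),
                   l2 = l2s[j]),
              class = "reconstruction_result")
  })
  for (i in 1:200) {
    n <- sample(10:40, 1)
    v <- runif(n)^2
    sc <- score_scan(fake_results(v), "top10")
    or <- top_window_oracle(v, 10L)
    expect_identical(sc$mean_l2_top10, or$mean)
    expect_identical(sc$top10_start, or$start)
  }
})

test_that("AUC equals brute-force concordance and handles ties", {
  df <- function(neg, pos) data.frame(
    score = c(neg, pos),
    group = rep(c("healthy", "abnormal"), c(length(neg), length(pos))),
    subtype = rep(c("phantom_healthy", "phantom_lesion"),
                  c(length(neg), length(pos))))
  expect_identical(evaluate_cohort(df(c(0.1, 0.2), c(0.5, 0.6)))$auc, 1)
  expect_identical(evaluate_cohort(df(c(1, 1), c(1, 1, 1)))$auc, 0.5)
  expect_equal(evaluate_cohort(df(c(0.1, 0.2, 0.3), c(0.25, 0.4)))$auc,
               5 / 6, tolerance = 1e-12)
  expect_error(evaluate_cohort(df(c(0.1), numeric(0))),
               class = "madgan_validation_error")
  set.seed(55)
  for (i in 1:200) {
    neg <- round(runif(sample(2:8, 1)), 1) # coarse grid forces ties
    pos <- round(runif(sample(2:8, 1)), 1)
    expect_equal(evaluate_cohort(df(neg, pos))$auc, auc_oracle(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(66)
  for (i in 1:20) {
    neg <- runif(6); pos <- runif(5) + 0.2
    d0 <- data.frame(score = c(neg, pos),
                     group = rep(c("healthy", "abnormal"), c(6, 5)),
                     subtype = "x")
    a0 <- evaluate_cohort(d0)$auc
    for (f in list(function(x) 3 * x + 2, exp, function(x) x^3)) {
      d1 <- d0; d1$score <- f(d1$score)
      expect_equal(evaluate_cohort(d1)$auc, a0, tolerance = 1e-12)
    }
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  neg <- rnorm(15); pos <- rnorm(12, mean = 0.8)
  d <- data.frame(score = c(neg, pos),
                  group = rep(c("healthy", "abnormal"), c(15, 12)),
                  subtype = "x")
  ours <- evaluate_cohort(d)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(0, 1), c(15, 12)), predictor = c(neg, pos),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("subtype filtering restricts the positive class", {
  d <- data.frame(score = c(0.1, 0.2, 0.9, 0.15),
                  group = c("healthy", "healthy", "abnormal", "abnormal"),
                  subtype = c("phantom_healthy", "phantom_healthy",
                              "phantom_lesion", "phantom_atrophy"))
  r <- evaluate_cohort(d, positive_subtypes = "phantom_lesion")
  expect_identical(r$n_pos, 1L)
  expect_identical(r$auc, 1)
  r2 <- evaluate_cohort(d, positive_subtypes = "phantom_atrophy")
  expect_identical(r2$auc, 0.5)   # 0.15 beats 0.1, loses to 0.2
})

test_that("heatmaps clip, colour and blend as specified", {
  tgt <- array(runif(8 * 8 * 3), c(8, 8, 3))
  rec <- tgt
  rec[1, 1, ] <- tgt[1, 1, ] + 1   # large error -> clips at clip_max
  em <- l2_error(tgt, rec)
  res <- structure(list(start_index = 1L, target_triplet = tgt,
                        reconstructed_triplet = rec, error_map = em,
                        l2 = em$l2),
                   class = "reconstruction_result")
  ov <- render_heatmap(res, clip_max = 0.2, alpha = 0.5)
  expect_identical(dim(ov), c(8L, 8L, 3L, 3L))
  expect_true(all(ov >= 0 & ov <= 1))
  maxcol <- jet_colors(1)
  for (s in 1:3) {
    expect_equal(ov[1, 1, , s],
                 as.numeric(0.5 * tgt[1, 1, s] + 0.5 * maxcol),
                 tolerance = 1e-12)
  }
  # zero error renders the colormap minimum everywhere
  res0 <- structure(list(start_index = 1L, target_triplet = tgt,
                         reconstructed_triplet = tgt,
                         error_map = l2_error(tgt, tgt), l2 = 0),
                    class = "reconstruction_result")
  ov0 <- render_heatmap(res0, clip_max = 0.2, alpha = 0.4)
  mincol <- jet_colors(0)
  expect_equal(ov0[3, 5, , 2],
               as.numeric(0.6 * tgt[3, 5, 2] + 0.4 * mincol),
               tolerance = 1e-12)
  expect_error(render_heatmap(res, clip_max = 0),
               class = "madgan_config_error")
  expect_error(render_heatmap(res, alpha = 0), class = "madgan_config_error")
})

test_that("jet colormap spans blue to red within [0,1]", {
  v <- seq(0, 1, by = 0.05)
  cols <- jet_colors(v)
  expect_true(all(cols >= 0 & cols <= 1))
  expect_gt(cols[1, 3], cols[1, 1])            # low end blue-dominant
  expect_gt(cols[nrow(cols), 1], cols[nrow(cols), 3]) # high end red
})
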