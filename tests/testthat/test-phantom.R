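test_that("phantom generation is deterministic and respects invariants", {
  cfg <- phantom_config(n_slices = 10, canvas = c(32L, 32L), seed = 9)
  a <- make_healthy_scan(cfg)
  b <- make_healthy_scan(cfg)
  expect_identical(a$slices, b$slices)
  expect_true(all(a$slices >= 0 & a$slices <= 1))
  expect_identical(dim(a$slices), c(32L, 32L, 10L))
  expect_identical(a$label$group, "healthy")
})

test_that("zero drift and zero noise give identical slices", {
  cfg <- phantom_config(n_slices = 8, canvas = c(32L, 32L), drift = 0,
                        noise_sd = 0, seed = 2)
  scan <- make_healthy_scan(cfg)
  for (k in 2:8) expect_equal(scan$slices[, , k], scan$slices[, , 1])
})

test_that("inter-slice similarity decays with slice distance", {
  cfg <- phantom_config(n_slices = 30, canvas = c(48L, 48L), drift = 0.02,
                        noise_sd = 0.01, seed = 5)
  scan <- make_healthy_scan(cfg)
  mean_cor_at <- function(d) {
    mean(vapply(seq_len(30 - d), function(k) {
      cor(as.numeric(scan$slices[, , k]), as.numeric(scan$slices[, , k + d]))
    }, numeric(1)))
  }
  cors <- vapply(1:5, mean_cor_at, numeric(1))
  expect_gt(cors[1], cors[5])
  # on average non-increasing: allow tiny wobble between neighbours
  expect_true(all(diff(cors) < 0.005))
})

test_that("lesion injection stamps the requested number of bright blobs", {
  scan <- tiny_phantom(n_slices = 16, canvas = c(48L, 48L), seed = 21)
  spec <- anomaly_spec("hyperintense_lesion", magnitude = 0.5, count = 3,
                       radius_range = c(3, 4), seed = 77)
  mod <- inject_anomaly(scan, spec)
  expect_identical(mod$label$group, "abnormal")
  expect_identical(mod$label$subtype, "phantom_lesion")
  diff3 <- mod$slices - scan$slices
  # max-project the change over slices and count connected components
  proj <- apply(diff3 > 0.05, c(1, 2), any)
  lab <- label_components(proj)
  expect_identical(max(lab), 3L)
  # stamped voxels end up brighter than they were (clamp-limited)
  stamped <- diff3 > 0.05
  expect_gt(mean(mod$slices[stamped]), mean(scan$slices[stamped]) + 0.1)
})

test_that("lesions change nothing outside their compact stamps", {
  scan <- tiny_phantom(n_slices = 12, canvas = c(32L, 32L), seed = 4)
  spec <- anomaly_spec("hyperintense_lesion", count = 2, seed = 5)
  mod <- inject_anomaly(scan, spec)
  diff3 <- abs(mod$slices - scan$slices)
  changed <- diff3 > 0
  # changed voxels form compact stamps: their count is far below the volume
  expect_lt(mean(changed), 0.15)
  # slices outside the lesion run are bit-identical
  per_slice <- apply(changed, 3, any)
  expect_true(any(!per_slice))
  for (k in which(!per_slice)) {
    expect_identical(mod$slices[, , k], scan$slices[, , k])
  }
})

test_that("atrophy enlarges the dark cavity area", {
  scan <- tiny_phantom(n_slices = 16, canvas = c(48L, 48L), seed = 31,
                       noise_sd = 0.01)
  mod <- inject_anomaly(scan, anomaly_spec("atrophy", magnitude = 0.5,
                                           seed = 8))
  dark <- function(s) sum(s$slices < 0.25)
  expect_gt(dark(mod), dark(scan))
  expect_identical(mod$label$subtype, "phantom_atrophy")
})

test_that("anomaly magnitude must be positive", {
  expect_error(anomaly_spec("atrophy", magnitude = 0),
               class = "madgan_validation_error")
  expect_error(anomaly_spec("hyperintense_lesion", magnitude = -1),
               class = "madgan_validation_error")
})

test_that("cohorts are sized, labelled and partitioned correctly", {
  cfg <- phantom_config(n_slices = 8, canvas = c(32L, 32L))
  specs <- list(anomaly_spec("hyperintense_lesion", count = 1),
                anomaly_spec("atrophy"))
  co <- make_cohort(20, 10, cfg, specs, seed = 3, n_train = 14)
  m <- co$manifest
  expect_identical(nrow(m), 40L)
  expect_identical(sum(m$subtype == "phantom_healthy"), 20L)
  expect_identical(sum(m$subtype == "phantom_lesion"), 10L)
  expect_identical(sum(m$subtype == "phantom_atrophy"), 10L)
  expect_true(all(m$group[m$partition == "train"] == "healthy"))
  expect_identical(sum(m$partition == "train"), 14L)
  co2 <- make_cohort(20, 10, cfg, specs, seed = 3, n_train = 14)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$scans[["phantom_lesion_003"]]$slices,
                   co2$scans[["phantom_lesion_003"]]$slices)
})
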