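test_that("canvas mapping pads a narrower slice symmetrically with zeros", {
  sl <- matrix(runif(176 * 240), 176, 240)
  out <- to_canvas(sl, c(176L, 256L))
  expect_identical(dim(out), c(176L, 256L))
  expect_true(all(out[, 1:8] == 0))
  expect_true(all(out[, 249:256] == 0))
  expect_equal(out[, 9:248], sl)
})

test_that("canvas mapping is the identity on canvas-sized input and idempotent", {
  sl <- matrix(runif(176 * 256), 176, 256)
  expect_identical(to_canvas(sl, c(176L, 256L)), sl)
  odd <- matrix(runif(100 * 90), 100, 90)
  once <- to_canvas(odd, c(64L, 48L))
  expect_identical(to_canvas(once, c(64L, 48L)), once)
})

test_that("bilinear resampling preserves constant images and handles 460x460", {
  const <- matrix(0.37, 460, 460)
  out <- to_canvas(const, c(176L, 256L))
  expect_identical(dim(out), c(176L, 256L))
  expect_equal(out, matrix(0.37, 176, 256), tolerance = 1e-12)
  expect_error(to_canvas(const, c(0L, 10L)), class = "madgan_config_error")
})

test_that("per-scan normalisation scales by the percentile and clamps", {
  sl <- array(runif(8 * 8 * 6, 0, 200), c(8, 8, 6))
  sl[1, 1, 1] <- 200 # ensure max
  scan <- volume_scan(sl, check = FALSE)
  q <- quantile(sl, 0.995, names = FALSE)
  norm <- normalize_scan(scan)
  expect_true(all(norm$slices >= 0 & norm$slices <= 1))
  below <- sl < q
  expect_equal(norm$slices[below], sl[below] / q, tolerance = 1e-12)

  # one hot pixel at 10x the percentile clamps to exactly 1
  sl2 <- array(runif(8 * 8 * 6, 0, 1), c(8, 8, 6))
  q2 <- quantile(sl2, 0.995, names = FALSE)
  sl2[3, 3, 3] <- 10 * q2
  norm2 <- normalize_scan(volume_scan(sl2, check = FALSE))
  expect_equal(norm2$slices[3, 3, 3], 1)

  expect_warning(normalize_scan(volume_scan(array(0, c(4, 4, 6)))),
                 "all-zero")
})

test_that("triplet enumeration matches brute-force sliding windows", {
  scan <- tiny_phantom(n_slices = 12)
  pairs <- enumerate_triplet_pairs(scan)
  expect_length(pairs, 7L)
  for (j in seq_along(pairs)) {
    expect_identical(pairs[[j]]$start_index, j)
    expect_equal(pairs[[j]]$input, scan$slices[, , j:(j + 2), drop = FALSE])
    expect_equal(pairs[[j]]$target,
                 scan$slices[, , (j + 3):(j + 5), drop = FALSE])
  }
  # property: n slices -> n - 5 pairs; target centers cover 5..(n-1)
  for (n in c(6L, 9L, 23L, 40L)) {
    s <- volume_scan(array(runif(4 * 4 * n), c(4, 4, n)))
    p <- enumerate_triplet_pairs(s)
    expect_length(p, n - 5L)
    centers <- vapply(p, function(q) q$start_index + 4L, integer(1))
    expect_identical(centers, seq(5L, n - 1L))
  }
  short <- volume_scan(array(0.5, c(4, 4, 5)))
  expect_error(enumerate_triplet_pairs(short),
               class = "madgan_validation_error")
})

test_that("slice-range selection validates bounds and preserves labels", {
  scan <- tiny_phantom(n_slices = 20)
  sub <- select_slice_range(scan, 10, 14)
  expect_identical(sub$n_slices, 5L)
  expect_equal(sub$slices, scan$slices[, , 10:14, drop = FALSE])
  expect_identical(sub$label, scan$label)
  expect_identical(select_slice_range(scan, 1, 20)$slices, scan$slices)
  expect_error(select_slice_range(scan, 5, 4),
               class = "madgan_validation_error")
  expect_error(select_slice_range(scan, 1, 21),
               class = "madgan_validation_error")
})

test_that("image-stack round trip preserves slice count and order", {
  scan <- tiny_phantom(n_slices = 8, canvas = c(32L, 32L))
  dir <- withr::local_tempdir()
  write_scan_stack(scan, dir)
  back <- load_scan(dir, canvas = c(32L, 32L),
                    label = scan_label("phantom_healthy"),
                    normalize_mode = "none")
  expect_identical(back$n_slices, 8L)
  # PNG quantises to 8 bits
  expect_equal(back$slices, scan$slices, tolerance = 1 / 255)

  empty <- withr::local_tempdir()
  expect_error(load_scan(empty, canvas = c(32L, 32L)),
               class = "madgan_validation_error")
  expect_error(load_scan(file.path(empty, "nope.nii")),
               class = "madgan_io_error")
})

test_that("NIfTI volumes load with the third axis as slices", {
  vol <- array(runif(20 * 24 * 9, 0, 100), c(20, 24, 9))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  scan <- load_scan(f, canvas = c(20L, 24L), normalize_mode = "max")
  expect_identical(scan$n_slices, 9L)
  expect_identical(scan$source_format, "nifti")
  expect_equal(scan$slices, vol / max(vol), tolerance = 1e-6)
})

test_that("labels derive their group from the subtype map", {
  expect_identical(scan_label("CDR=0", "T1")$group, "healthy")
  expect_identical(scan_label("CDR=0.5", "T1")$group, "abnormal")
  expect_identical(scan_label("brain_metastases", "T1c")$group, "abnormal")
  expect_error(scan_label("mystery"), class = "madgan_validation_error")
  expect_identical(scan_label("mystery", group = "abnormal")$group,
                   "abnormal")
})

test_that("manifests round-trip and reject contradictory groups", {
  m <- data.frame(scan_id = c("a", "b"), path = c("pa", "pb"),
                  subtype = c("CDR=0", "CDR=1"),
                  group = c("healthy", "abnormal"),
                  sequence_tag = "T1", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f)
  back <- read_manifest(f)
  expect_identical(back$group, m$group)
  m$group[2] <- "healthy" # contradicts CDR=1
  write_manifest(m, f)
  expect_error(read_manifest(f), class = "madgan_validation_error")
})
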