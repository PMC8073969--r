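# Parametric phantom volumes: smooth nested "anatomy" with slice-wise
# drift, plus two anomaly injectors (diffuse cavity enlargement mimicking
# atrophy; compact hyperintense Gaussian blobs mimicking enhancing
# metastases).  The generator reproduces the statistical structure the
# reconstruction method relies on -- strong anatomical consistency across
# scans and smooth continuity between adjacent slices -- without any MRI
# physics.

#' Phantom generation settings
#'
#' @param n_slices number of axial slices (>= 6).
#' @param canvas slice dims `c(rows, cols)`; 64x64 is the desk-scale
#'   default, 176x256 is supported.
#' @param n_structures number of nested smooth regions; the innermost is a
#'   dark cavity standing in for the ventricles.
#' @param drift per-slice bound on smooth shape change, as a fraction of
#'   region radius; 0 makes all slices identical.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer; the same config + seed is bit-reproducible.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 30L, canvas = c(64L, 64L),
                           n_structures = 3L, drift = 0.02,
                           noise_sd = 0.02, seed = 1L) {
  if (!is_count(n_slices, 6L)) abort_config("n_slices must be >= 6")
  if (drift < 0 || noise_sd < 0) abort_config("drift and noise_sd must be >= 0")
  if (!is_count(n_structures, 1L)) abort_config("n_structures must be >= 1")
  structure(list(n_slices = as.integer(n_slices), canvas = as.integer(canvas),
                 n_structures = as.integer(n_structures), drift = drift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Anomaly injection settings
#'
#' Two anomaly classes mirror the two pathologies the method targets:
#' `"atrophy"` enlarges the interior dark cavity diffusely over many
#' contiguous slices (enlarged-ventricle-like); `"hyperintense_lesion"`
#' stamps compact bright Gaussian blobs on a contiguous slice run
#' (enhancing-metastasis-like).
#'
#' @param kind `"atrophy"` or `"hyperintense_lesion"`.
#' @param magnitude atrophy: fractional cavity enlargement (default 0.4);
#'   lesion: peak intensity above local background (default 0.5). Must be
#'   positive.
#' @param count lesions per scan (lesion kind only).
#' @param radius_range lesion radius range in pixels.
#' @param seed integer.
#' @return an object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind = c("hyperintense_lesion", "atrophy"),
                         magnitude = NULL, count = 3L,
                         radius_range = c(3, 6), seed = 1L) {
  kind <- match.arg(kind)
  magnitude <- magnitude %||% switch(kind, atrophy = 0.4,
                                     hyperintense_lesion = 0.5)
  if (!is.numeric(magnitude) || magnitude <= 0)
    abort_validation("magnitude must be > 0")
  if (kind == "hyperintense_lesion" && !is_count(count, 1L))
    abort_validation("lesion count must be >= 1")
  structure(list(kind = kind, magnitude = magnitude, count = as.integer(count),
                 radius_range = radius_range, seed = as.integer(seed)),
            class = "anomaly_spec")
}

# Draw per-scan geometry: nested superellipse-like regions perturbed by
# low-order angular harmonics.  Intensities: mid-grey outer tissue,
# brighter inner tissue, dark innermost cavity.
sample_phantom_params <- function(config) {
  S <- config$n_structures
  base <- 0.42 * 0.60^(seq_len(S) - 1)
  ints <- c(if (S > 1) seq(0.55, 0.75, length.out = S - 1), 0.10)
  lapply(seq_len(S), function(s) {
    list(r = base[s] * stats::runif(1, 0.9, 1.1),
         aspect = stats::runif(1, 0.85, 1.15),
         cx = 0.5 + stats::runif(1, -0.03, 0.03),
         cy = 0.5 + stats::runif(1, -0.03, 0.03),
         amp = stats::runif(3, 0, 0.06),        # harmonic orders 2..4
         phase = stats::runif(3, 0, 2 * pi),
         intensity = ints[s])
  })
}

# Inside-ness of one region on one slice: smooth (anti-aliased) indicator,
# hard-cut to exactly 0 far outside so edits stay compactly supported.
region_mask <- function(canvas, par, scale = 1, rot = 0, grow = 1) {
  H <- canvas[1]; W <- canvas[2]
  X <- matrix(seq_len(W) / W, H, W, byrow = TRUE) - par$cx
  Y <- matrix(seq_len(H) / H, H, W) - par$cy
  rx <- par$r * sqrt(par$aspect) * scale * grow
  ry <- par$r / sqrt(par$aspect) * scale * grow
  rho <- sqrt((X / rx)^2 + (Y / ry)^2)
  theta <- atan2(Y, X)
  B <- 1
  for (k in 1:3) B <- B + par$amp[k] * cos((k + 1) * theta + par$phase[k] + rot)
  edge <- 1.2 / (min(rx, ry) * min(H, W))
  m <- stats::plogis((B - rho) / edge)
  m[m < 1e-4] <- 0
  m
}

#' Generate a healthy phantom scan
#'
#' Renders `n_structures` nested smooth closed regions whose size and
#' orientation vary smoothly along the slice axis: a deterministic
#' quadratic axial profile plus a bounded random walk, both with per-slice
#' change at most `drift`. Gaussian noise of SD `noise_sd` is added and
#' the result clamped to \[0, 1\]. Identical config and seed give a
#' bit-identical volume.
#'
#' @param config a [phantom_config()].
#' @param scan_id identifier.
#' @return a `volume_scan` labelled `phantom_healthy`, with the generating
#'   parameters attached (used by [inject_anomaly()]).
#' @export
make_healthy_scan <- function(config, scan_id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_slices
  with_seed(config$seed, {
    pars <- sample_phantom_params(config)
    # axial profile: largest mid-stack, per-slice slope <= drift/2
    zc <- n * stats::runif(1, 0.45, 0.55)
    cprof <- config$drift * n / 8
    prof <- 1 - cprof * ((seq_len(n) - zc) / (n / 2))^2
    walk <- cumsum(c(0, stats::runif(n - 1, -config$drift / 2,
                                     config$drift / 2)))
    rotwalk <- cumsum(c(0, stats::runif(n - 1, -config$drift, config$drift)))
    scales <- prof * (1 + walk)
    noise <- if (config$noise_sd > 0) {
      array(stats::rnorm(prod(config$canvas) * n, 0, config$noise_sd),
            c(config$canvas, n))
    } else NULL
    vol <- array(0, c(config$canvas, n))
    for (z in seq_len(n)) {
      img <- matrix(0, config$canvas[1], config$canvas[2])
      for (s in seq_along(pars)) {
        m <- region_mask(config$canvas, pars[[s]], scale = scales[z],
                         rot = rotwalk[z])
        img <- img * (1 - m) + pars[[s]]$intensity * m
      }
      if (!is.null(noise)) img <- img + noise[, , z]
      vol[, , z] <- clamp01(img)
    }
    scan <- volume_scan(vol, scan_id = scan_id,
                        label = scan_label("phantom_healthy", "phantom"))
    attr(scan, "phantom_params") <- list(pars = pars, scales = scales,
                                         rotwalk = rotwalk, config = config)
    scan
  })
}

#' Inject an anomaly into a healthy phantom
#'
#' Atrophy re-renders the innermost dark cavity enlarged by `magnitude`
#' (tapered smoothly over a long contiguous slice run, so the deformation
#' is diffuse); lesions add `count` compactly supported Gaussian-profile
#' bright blobs at random in-anatomy positions over a random contiguous
#' slice run, with an intensity profile that waxes and wanes along the
#' run. Pixels outside the deformed/stamped regions are untouched. The
#' label group becomes `abnormal` with the spec's kind as subtype.
#'
#' @param scan a healthy phantom from [make_healthy_scan()].
#' @param spec an [anomaly_spec()].
#' @return the modified `volume_scan`.
#' @export
inject_anomaly <- function(scan, spec) {
  stopifnot(inherits(scan, "volume_scan"), inherits(spec, "anomaly_spec"))
  pp <- attr(scan, "phantom_params")
  if (is.null(pp))
    abort_validation("inject_anomaly needs a phantom scan with attached parameters")
  n <- scan$n_slices
  canvas <- dim(scan$slices)[1:2]
  out <- scan
  with_seed(spec$seed, {
    if (spec$kind == "atrophy") {
      len <- max(6L, as.integer(round(0.7 * n)))
      z0 <- sample.int(n - len + 1L, 1L)
      run <- z0:(z0 + len - 1L)
      taper <- sin(pi * (seq_along(run)) / (len + 1))
      cav <- pp$pars[[length(pp$pars)]]
      for (i in seq_along(run)) {
        z <- run[i]
        grow <- 1 + spec$magnitude * taper[i]
        m <- region_mask(canvas, cav, scale = pp$scales[z],
                         rot = pp$rotwalk[z], grow = grow)
        img <- out$slices[, , z]
        out$slices[, , z] <- img * (1 - m) + cav$intensity * m
      }
      subtype <- "phantom_atrophy"
    } else {
      mid <- scan$slices[, , ceiling(n / 2)]
      anat <- which(mid > 0.3 & mid < 0.95, arr.ind = TRUE)
      if (nrow(anat) == 0L)
        abort_validation("lesion placement impossible: anatomy mask empty")
      len <- max(4L, as.integer(round(n / 4)))
      for (b in seq_len(spec$count)) {
        ctr <- anat[sample.int(nrow(anat), 1L), ]
        rad <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
        z0 <- sample.int(n - len + 1L, 1L)
        prof <- spec$magnitude * sin(pi * seq_len(len) / (len + 1))
        ii <- matrix(seq_len(canvas[1]), canvas[1], canvas[2])
        jj <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE)
        d2 <- (ii - ctr[1])^2 + (jj - ctr[2])^2
        blob <- exp(-d2 / (2 * (rad / 2)^2))
        blob[d2 > (1.5 * rad)^2] <- 0  # compact support
        for (i in seq_len(len)) {
          z <- z0 + i - 1L
          out$slices[, , z] <- clamp01(out$slices[, , z] + prof[i] * blob)
        }
      }
      subtype <- "phantom_lesion"
    }
  })
  out$label <- scan_label(subtype, "phantom")
  out
}

#' Generate a labelled phantom cohort
#'
#' Healthy scans are split into a training partition and a held-out test
#' partition; abnormal scans (one batch per anomaly spec) go to the test
#' partition only, so the training set contains healthy anatomy
#' exclusively -- the unsupervised-learning contract of the method.
#'
#' @param n_healthy total healthy scans.
#' @param n_abnormal_per_kind abnormal scans per anomaly spec.
#' @param config a [phantom_config()] (its seed is ignored; per-scan seeds
#'   are derived from `seed`).
#' @param specs list of [anomaly_spec()]s.
#' @param seed integer cohort seed.
#' @param n_train healthy scans assigned to training (default two thirds).
#' @return a `scan_cohort`: list of scans plus a manifest data.frame with
#'   `scan_id, subtype, group, sequence_tag, partition`.
#' @export
make_cohort <- function(n_healthy, n_abnormal_per_kind,
                        config = phantom_config(),
                        specs = list(anomaly_spec("hyperintense_lesion"),
                                     anomaly_spec("atrophy")),
                        seed = 1L,
                        n_train = ceiling(2 * n_healthy / 3)) {
  stopifnot(is_count(n_healthy), is_count(n_abnormal_per_kind, 0L))
  scans <- list()
  rows <- list()
  add <- function(scan, partition) {
    scans[[scan$scan_id]] <<- scan
    rows[[length(rows) + 1L]] <<-
      data.frame(scan_id = scan$scan_id, subtype = scan$label$subtype,
                 group = scan$label$group,
                 sequence_tag = scan$label$sequence_tag,
                 partition = partition, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_healthy)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("healthy", i))
    add(make_healthy_scan(cfg, sprintf("healthy_%03d", i)),
        if (i <= n_train) "train" else "test")
  }
  for (k in seq_along(specs)) {
    for (i in seq_len(n_abnormal_per_kind)) {
      cfg <- config
      cfg$seed <- derive_seed(seed, paste0("abnormal", k, "_", i))
      base <- make_healthy_scan(cfg, sprintf("%s_%03d", specs[[k]]$kind, i))
      sp <- specs[[k]]
      sp$seed <- derive_seed(seed, paste0("inject", k, "_", i))
      add(inject_anomaly(base, sp), "test")
    }
  }
  structure(list(scans = scans, manifest = do.call(rbind, rows)),
            class = "scan_cohort")
}

#' @export
print.scan_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<scan_cohort> %d scans (%d train / %d test)\n",
              nrow(m), sum(m$partition == "train"),
              sum(m$partition == "test")))
  print(table(m$subtype, m$partition))
  invisible(x)
}

#' Write a cohort as manifest CSV + PNG slice stacks
#'
#' @param cohort a `scan_cohort`.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort$manifest
  m$path <- file.path(dir, m$scan_id)
  for (id in names(cohort$scans)) {
    write_scan_stack(cohort$scans[[id]], file.path(dir, id))
  }
  write_manifest(m, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
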