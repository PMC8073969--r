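# Scan ingestion: volumes onto the training canvas, labels, triplet pairs.

#' Scan labels and the subtype-to-group mapping
#'
#' A scan carries a free-text `subtype` (e.g. `"CDR=0.5"`,
#' `"brain_metastases"`, `"phantom_lesion"`) and a coarse `group`
#' (`"healthy"` or `"abnormal"`) derived deterministically from the subtype
#' via [subtype_group_map()]. Only unambiguously healthy subtypes map to
#' `"healthy"`; training enforces that contract.
#'
#' @param subtype free-text fine label.
#' @param sequence_tag acquisition tag, e.g. `"T1"`, `"T1c"`, `"phantom"`.
#' @param group optional override; required when `subtype` is not in the map.
#' @return an object of class `scan_label`.
#' @export
scan_label <- function(subtype, sequence_tag = "phantom", group = NULL) {
  stopifnot(is.character(subtype), length(subtype) == 1L)
  map <- subtype_group_map()
  if (is.null(group)) {
    if (!subtype %in% names(map)) {
      abort_validation("unknown subtype '", subtype,
                       "': supply group= explicitly or extend subtype_group_map()")
    }
    group <- unname(map[[subtype]])
  }
  group <- match.arg(group, c("healthy", "abnormal"))
  structure(list(group = group, subtype = subtype,
                 sequence_tag = sequence_tag),
            class = "scan_label")
}

#' @rdname scan_label
#' @export
subtype_group_map <- function() {
  c("CDR=0" = "healthy", "CDR=0.5" = "abnormal", "CDR=1" = "abnormal",
    "CDR=2" = "abnormal", "normal" = "healthy", "healthy" = "healthy",
    "brain_metastases" = "abnormal", "various_diseases" = "abnormal",
    "phantom_healthy" = "healthy", "phantom_lesion" = "abnormal",
    "phantom_atrophy" = "abnormal")
}

#' Construct a scan volume
#'
#' The unit of diagnosis: an ordered stack of equally sized 2D slices in
#' ascending axial order, intensities in \[0, 1\] after normalisation.
#'
#' @param slices numeric array `rows x cols x n_slices`.
#' @param scan_id character identifier.
#' @param label a [scan_label()].
#' @param source_format one of `"nifti"`, `"image_stack"`, `"phantom"`.
#' @param check validate intensity range (set `FALSE` for raw pre-normalised
#'   data).
#' @return an object of class `volume_scan`.
#' @export
volume_scan <- function(slices, scan_id = "scan",
                        label = scan_label("phantom_healthy"),
                        source_format = c("phantom", "nifti", "image_stack"),
                        check = TRUE) {
  source_format <- match.arg(source_format)
  if (!is.array(slices) || length(dim(slices)) != 3L)
    abort_validation("slices must be a rows x cols x n_slices array")
  if (check) {
    if (anyNA(slices) || !all(is.finite(slices)))
      abort_validation("slices contain non-finite values")
    rng <- range(slices)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      abort_validation("slice intensities outside [0,1]; normalise first")
  }
  stopifnot(inherits(label, "scan_label"))
  structure(list(scan_id = scan_id, slices = slices,
                 n_slices = dim(slices)[3], label = label,
                 source_format = source_format),
            class = "volume_scan")
}

#' @export
print.volume_scan <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<volume_scan '%s'> %d slices of %dx%d, %s (%s, %s)\n",
              x$scan_id, x$n_slices, d[1], d[2], x$label$group,
              x$label$subtype, x$label$sequence_tag))
  invisible(x)
}

#' Map a slice onto the training canvas
#'
#' Slices whose row count matches the canvas and whose column count is
#' smaller are zero-padded symmetrically along the column axis (the
#' 176x240 to 176x256 case: 8 zero columns on each side). Any other shape
#' is resampled to the canvas by bilinear interpolation with half-pixel
#' centres, under which a constant image stays constant.
#'
#' @param slice numeric matrix.
#' @param canvas integer vector `c(rows, cols)`, default `c(176, 256)`.
#' @return a `canvas[1] x canvas[2]` matrix.
#' @export
to_canvas <- function(slice, canvas = c(176L, 256L)) {
  if (length(canvas) != 2L || any(canvas < 1))
    abort_config("canvas dims must be two positive integers")
  if (!is.matrix(slice) || any(dim(slice) < 1))
    abort_validation("slice must be a non-empty matrix")
  d <- dim(slice)
  if (all(d == canvas)) return(slice)
  if (d[1] == canvas[1] && d[2] < canvas[2]) {
    deficit <- canvas[2] - d[2]
    left <- deficit %/% 2L
    out <- matrix(0, canvas[1], canvas[2])
    out[, (left + 1L):(left + d[2])] <- slice
    return(out)
  }
  bilinear_resample(slice, canvas)
}

# Bilinear resampling with half-pixel alignment (align_corners = FALSE
# dialect); sampling coordinates are clamped at the borders.
bilinear_resample <- function(slice, out_dim) {
  d <- dim(slice)
  sr <- d[1] / out_dim[1]
  sc <- d[2] / out_dim[2]
  ri <- pmin(pmax((seq_len(out_dim[1]) - 0.5) * sr - 0.5, 0), d[1] - 1)
  ci <- pmin(pmax((seq_len(out_dim[2]) - 0.5) * sc - 0.5, 0), d[2] - 1)
  r0 <- pmin(floor(ri), d[1] - 1); r1 <- pmin(r0 + 1, d[1] - 1)
  c0 <- pmin(floor(ci), d[2] - 1); c1 <- pmin(c0 + 1, d[2] - 1)
  fr <- ri - r0; fc <- ci - c0
  a <- slice[r0 + 1, c0 + 1, drop = FALSE]
  b <- slice[r1 + 1, c0 + 1, drop = FALSE]
  cc <- slice[r0 + 1, c1 + 1, drop = FALSE]
  dd <- slice[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, out_dim[1], out_dim[2])
  wc <- matrix(fc, out_dim[1], out_dim[2], byrow = TRUE)
  (a * (1 - wr) + b * wr) * (1 - wc) + (cc * (1 - wr) + dd * wr) * wc
}

#' Normalise scan intensities to \[0, 1\]
#'
#' Default mode rescales the whole scan linearly so the 99.5th-percentile
#' intensity maps to 1 (0 maps to 0), then clamps to \[0, 1\]. Scaling is
#' per scan, not per slice, which preserves inter-slice brightness
#' gradients that the reconstruction model must learn. An externally fixed
#' `scale` supports joint normalisation across a pooled multi-sequence
#' cohort.
#'
#' @param scan a `volume_scan` (possibly with raw, unnormalised slices).
#' @param mode `"percentile"` (default), `"max"`, or `"none"`.
#' @param percentile quantile mapped to 1 in percentile mode.
#' @param scale optional fixed divisor overriding the estimated one.
#' @return the scan with slices in \[0, 1\].
#' @export
normalize_scan <- function(scan, mode = c("percentile", "max", "none"),
                           percentile = 0.995, scale = NULL) {
  stopifnot(inherits(scan, "volume_scan"))
  mode <- match.arg(mode)
  x <- scan$slices
  if (anyNA(x) || !all(is.finite(x)) || any(x < 0))
    abort_validation("raw intensities must be finite and non-negative")
  if (mode == "none" && is.null(scale)) {
    scan$slices <- clamp01(x)
    return(scan)
  }
  s <- scale %||% switch(mode,
    percentile = stats::quantile(x, percentile, names = FALSE),
    max = max(x))
  if (is.null(s) || s <= 0) {
    if (all(x == 0)) {
      warning("all-zero scan '", scan$scan_id, "': returned unchanged")
      return(scan)
    }
    s <- max(x)
  }
  scan$slices <- clamp01(x / s)
  scan
}

#' Load a scan volume from disk
#'
#' Reads either a NIfTI file (`.nii` / `.nii.gz`; the third axis is taken
#' as the axial slice axis) or a directory of equally sized 2D PNG/TIFF
#' slices in lexicographic order, maps every slice onto the canvas and
#' normalises the result.
#'
#' @param path file or directory path.
#' @param canvas target `c(rows, cols)`.
#' @param label a [scan_label()] to attach.
#' @param normalize_mode passed to [normalize_scan()].
#' @param scan_id defaults to the file/directory base name.
#' @return a `volume_scan`.
#' @export
load_scan <- function(path, canvas = c(176L, 256L),
                      label = scan_label("healthy", "T1"),
                      normalize_mode = "percentile", scan_id = NULL) {
  if (!file.exists(path)) abort_io("path does not exist: ", path)
  scan_id <- scan_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      abort_validation("no PNG/TIFF slices found in ", path)
    slices <- lapply(files, read_slice_image)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      abort_validation("inconsistent slice dimensions within ", path)
    fmt <- "image_stack"
  } else {
    vol <- tryCatch(RNifti::readNifti(path),
                    error = function(e) abort_io("cannot read NIfTI ", path,
                                                 ": ", conditionMessage(e)))
    vol <- as.array(vol)
    if (length(dim(vol)) == 4L) vol <- vol[, , , 1, drop = TRUE]
    if (length(dim(vol)) != 3L)
      abort_validation("NIfTI volume must be 3D, got ",
                       length(dim(vol)), "D")
    slices <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k])
    fmt <- "nifti"
  }
  mapped <- vapply(slices, to_canvas, canvas = canvas,
                   FUN.VALUE = matrix(0, canvas[1], canvas[2]))
  raw <- volume_scan(mapped, scan_id = scan_id, label = label,
                     source_format = fmt, check = FALSE)
  normalize_scan(raw, mode = normalize_mode)
}

read_slice_image <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
    png::readPNG(f)
  } else {
    tiff::readTIFF(f)
  }
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                              drop = FALSE], c(1, 2), mean)
  img
}

#' Enumerate sliding triplet pairs of a scan
#'
#' A scan of n slices yields n - 5 stride-1 pairs: pair j maps input
#' slices \{j, j+1, j+2\} to target slices \{j+3, j+4, j+5\} (so a
#' 40-slice scan yields all 35 possible 3-to-3 setups). Triplets are
#' returned as `rows x cols x 3` arrays, slices stacked channel-wise like
#' the colour channels of an RGB image.
#'
#' @param scan a `volume_scan` with at least 6 slices.
#' @return list of `triplet_pair` objects, each with `input`, `target`,
#'   `start_index` (1-based).
#' @export
enumerate_triplet_pairs <- function(scan) {
  stopifnot(inherits(scan, "volume_scan"))
  n <- scan$n_slices
  if (n < 6L)
    abort_validation("scan too short for 3->3 reconstruction (n_slices = ",
                     n, " < 6)")
  lapply(seq_len(n - 5L), function(j) {
    structure(list(input = scan$slices[, , j:(j + 2L), drop = FALSE],
                   target = scan$slices[, , (j + 3L):(j + 5L), drop = FALSE],
                   start_index = j),
              class = "triplet_pair")
  })
}

#' Restrict a scan to a contiguous slice range
#'
#' Stands in for the anatomical slice selection of the full pipeline
#' (mid-brain slices showing hippocampus/amygdala/ventricles) as an
#' explicit, configurable index range.
#'
#' @param scan a `volume_scan`.
#' @param first,last 1-based inclusive bounds.
#' @return the sub-stack as a `volume_scan`, label preserved.
#' @export
select_slice_range <- function(scan, first, last) {
  stopifnot(inherits(scan, "volume_scan"))
  if (!is_count(first) || !is_count(last) || first > last ||
      last > scan$n_slices)
    abort_validation("invalid slice range [", first, ", ", last,
                     "] for scan with ", scan$n_slices, " slices")
  scan$slices <- scan$slices[, , first:last, drop = FALSE]
  scan$n_slices <- dim(scan$slices)[3]
  scan
}

#' Read / write scan manifests
#'
#' A manifest is a CSV with columns `scan_id, path, subtype, group,
#' sequence_tag` (plus optional `partition`); `group` is rederived from
#' `subtype` where the mapping knows it, so manifests cannot silently
#' mislabel a scan.
#'
#' @param file CSV path.
#' @return a data.frame.
#' @export
read_manifest <- function(file) {
  if (!file.exists(file)) abort_io("manifest not found: ", file)
  m <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("scan_id", "subtype")
  if (!all(need %in% names(m)))
    abort_validation("manifest must contain columns: ",
                     paste(need, collapse = ", "))
  map <- subtype_group_map()
  known <- m$subtype %in% names(map)
  derived <- ifelse(known, unname(map[m$subtype]), m$group %||% NA)
  if ("group" %in% names(m) && any(known & m$group != derived))
    abort_validation("manifest group column contradicts subtype mapping")
  m$group <- derived
  m
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, file) {
  utils::write.csv(manifest, file, row.names = FALSE)
  invisible(file)
}

#' Write a scan as a numbered PNG slice stack
#'
#' @param scan a `volume_scan`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_scan_stack <- function(scan, dir) {
  stopifnot(inherits(scan, "volume_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(scan$n_slices)) {
    png::writePNG(clamp01(scan$slices[, , k]),
                  file.path(dir, sprintf("slice_%04d.png", k)))
  }
  invisible(dir)
}
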