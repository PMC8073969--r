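# Diagnosis stage: reconstruct every sliding triplet of an unseen scan,
# score the scan by its average pixel-sum squared error (whole-scan or
# highest-loss 10-consecutive-set window), and separate healthy from
# abnormal scans by ROC/AUC.

#' Reconstruct all slice triplets of a scan
#'
#' Runs the generator in eval mode (deterministic: dropout off, running
#' batch-norm statistics) over every triplet pair of the scan, yielding
#' one `reconstruction_result` per pair in order.
#'
#' @param scan a `volume_scan` with at least 6 slices.
#' @param model a fitted `madgan` object, a checkpoint entry from its
#'   `checkpoints` list, or any function mapping an `H x W x 3` input
#'   triplet to a reconstructed triplet (useful for stub oracles).
#' @param batch_size triplets evaluated per generator call.
#' @return list of `reconstruction_result` objects with fields
#'   `start_index`, `target_triplet`, `reconstructed_triplet`,
#'   `error_map` (a `pixel_error_map`), `l2`.
#' @export
reconstruct_scan <- function(scan, model, batch_size = 16L) {
  stopifnot(inherits(scan, "volume_scan"))
  pairs <- enumerate_triplet_pairs(scan)
  recon <- vector("list", length(pairs))
  if (is.function(model)) {
    for (i in seq_along(pairs)) {
      out <- model(pairs[[i]]$input)
      dim(out) <- dim(pairs[[i]]$input)
      recon[[i]] <- out
    }
  } else {
    gen <- model$generator
    spec <- model$spec
    if (is.null(gen) || is.null(spec))
      abort_validation("model must be a fitted madgan object, a checkpoint, or a function")
    idx <- seq_along(pairs)
    for (grp in split(idx, ceiling(idx / batch_size))) {
      X <- array(0, c(dim(pairs[[1]]$input), length(grp)))
      for (k in seq_along(grp)) X[, , , k] <- pairs[[grp[k]]]$input
      Yh <- generator_forward(gen, X, spec, train = FALSE)
      for (k in seq_along(grp)) {
        recon[[grp[k]]] <- Yh[, , , k, drop = TRUE]
      }
    }
  }
  lapply(seq_along(pairs), function(i) {
    em <- l2_error(pairs[[i]]$target, recon[[i]])
    structure(list(start_index = pairs[[i]]$start_index,
                   target_triplet = pairs[[i]]$target,
                   reconstructed_triplet = recon[[i]],
                   error_map = em, l2 = em$l2),
              class = "reconstruction_result")
  })
}

#' Score a scan from its reconstruction results
#'
#' `whole` mode averages the pixel-sum squared error over all triplet
#' sets; `top10` takes the maximum over start positions of the mean of
#' `window` consecutive per-set errors (the highest-loss continuous
#' 10-set score), reporting the 1-based winning start. With fewer sets
#' than the window, `top10` falls back to the whole-scan mean with a
#' note. Ties break toward the smallest start.
#'
#' @param results list from [reconstruct_scan()].
#' @param mode `"whole"` or `"top10"`.
#' @param window window length for `top10`.
#' @param scan_id,label carried through for bookkeeping.
#' @return an object of class `scan_score` with `mean_l2_whole`,
#'   `mean_l2_top10`, `top10_start`, `n_sets`, `score` (the mode's value),
#'   `mean_l2_per_pixel`.
#' @export
score_scan <- function(results, mode = c("whole", "top10"), window = 10L,
                       scan_id = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (length(results) == 0L) abort_validation("empty reconstruction results")
  l2 <- vapply(results, `[[`, numeric(1), "l2")
  n_sets <- length(l2)
  whole <- mean(l2)
  if (n_sets < window) {
    top10 <- whole
    top10_start <- 1L
    message("fewer sets (", n_sets, ") than window (", window,
            "): top10 falls back to whole-scan mean")
  } else {
    wm <- vapply(seq_len(n_sets - window + 1L),
                 function(j) mean(l2[j:(j + window - 1L)]), numeric(1))
    top10_start <- which.max(wm)   # smallest start wins ties
    top10 <- wm[top10_start]
  }
  P <- results[[1]]$error_map$P
  structure(list(scan_id = scan_id, label = label,
                 mean_l2_whole = whole, mean_l2_top10 = top10,
                 top10_start = as.integer(top10_start), n_sets = n_sets,
                 score = if (mode == "whole") whole else top10,
                 mode = mode, per_set_l2 = l2,
                 mean_l2_per_pixel = whole / P),
            class = "scan_score")
}

#' @export
print.scan_score <- function(x, ...) {
  cat(sprintf(
    "<scan_score '%s'> whole %.4g  top10 %.4g (start %d)  sets %d\n",
    x$scan_id %||% "?", x$mean_l2_whole, x$mean_l2_top10, x$top10_start,
    x$n_sets))
  invisible(x)
}

#' ROC curve and AUC over scored scans
#'
#' Higher score means more abnormal. AUC is the Mann-Whitney
#' probability of concordance (ties count one half), identical to
#' trapezoidal integration of the ROC and invariant under strictly
#' monotone score transforms. `positive_subtypes` restricts the abnormal
#' side to chosen subtypes (e.g. healthy vs metastasis-like lesions
#' only).
#'
#' @param scores a data.frame with columns `score` and `group` (and
#'   optionally `subtype`), or a list of `scan_score` objects.
#' @param positive_subtypes optional character vector of abnormal
#'   subtypes to keep.
#' @return an object of class `roc_result`: `auc`, `roc` (data.frame with
#'   `threshold`, `tpr`, `fpr`), `n_pos`, `n_neg`.
#' @export
evaluate_cohort <- function(scores, positive_subtypes = NULL) {
  df <- scores_as_df(scores)
  if (!is.null(positive_subtypes)) {
    df <- df[df$group == "healthy" | df$subtype %in% positive_subtypes, ]
  }
  pos <- df$score[df$group == "abnormal"]
  neg <- df$score[df$group == "healthy"]
  if (length(pos) == 0L || length(neg) == 0L)
    abort_validation("need at least one positive and one negative scan")
  auc <- auc_concordance(pos, neg)
  th <- sort(unique(c(-Inf, df$score, Inf)), decreasing = TRUE)
  roc <- data.frame(
    threshold = th,
    tpr = vapply(th, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(neg >= t), numeric(1)))
  structure(list(auc = auc, roc = roc, n_pos = length(pos),
                 n_neg = length(neg),
                 positive_subtypes = positive_subtypes),
            class = "roc_result")
}

# Mann-Whitney concordance with half-credit for ties
auc_concordance <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  rp <- sum(r[seq_along(pos)])
  (rp - length(pos) * (length(pos) + 1) / 2) / (length(pos) * length(neg))
}

scores_as_df <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("score", "group") %in% names(scores)))
      abort_validation("scores data.frame needs columns score, group")
    if (is.null(scores$subtype)) scores$subtype <- scores$group
    return(scores)
  }
  if (is.list(scores) && all(vapply(scores, inherits, logical(1),
                                    "scan_score"))) {
    return(do.call(rbind, lapply(scores, function(s) {
      data.frame(scan_id = s$scan_id %||% NA_character_,
                 score = s$score,
                 group = if (is.null(s$label)) NA_character_ else s$label$group,
                 subtype = if (is.null(s$label)) NA_character_ else s$label$subtype,
                 stringsAsFactors = FALSE)
    })))
  }
  abort_validation("scores must be a data.frame or list of scan_score objects")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f  (%d abnormal vs %d healthy)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Jet colormap
#'
#' The classic blue-cyan-yellow-red ramp used for error overlays.
#'
#' @param v numeric values in \[0, 1\].
#' @return matrix `length(v) x 3` of RGB values in \[0, 1\].
#' @export
jet_colors <- function(v) {
  v <- clamp01(v)
  r <- clamp01(1.5 - abs(4 * v - 3))
  g <- clamp01(1.5 - abs(4 * v - 2))
  b <- clamp01(1.5 - abs(4 * v - 1))
  cbind(r, g, b)
}

#' Render an error heatmap overlay
#'
#' Clips the per-pixel squared error to `[0, clip_max]`, maps it through
#' the Jet colormap and alpha-blends it onto the ground-truth slices
#' (0.2 is the published display range for T1 scans, 0.06 for T1c).
#'
#' @param result a `reconstruction_result`.
#' @param clip_max upper clip of the error display range.
#' @param alpha blend weight of the colormap in (0, 1].
#' @return array `H x W x 3(RGB) x 3(slices)` in \[0, 1\].
#' @export
render_heatmap <- function(result, clip_max = 0.2, alpha = 0.5) {
  stopifnot(inherits(result, "reconstruction_result"))
  if (clip_max <= 0) abort_config("clip_max must be > 0")
  if (alpha <= 0 || alpha > 1) abort_config("alpha must be in (0, 1]")
  err <- result$error_map$values
  gt <- result$target_triplet
  d <- dim(gt)
  out <- array(0, c(d[1], d[2], 3L, d[3]))
  for (s in seq_len(d[3])) {
    v <- pmin(err[, , s], clip_max) / clip_max
    cols <- jet_colors(as.numeric(v))
    base <- as.numeric(gt[, , s])
    for (ch in 1:3) {
      out[, , ch, s] <- matrix((1 - alpha) * base + alpha * cols[, ch],
                               d[1], d[2])
    }
  }
  out
}

#' Write a reconstruction panel as PNG files
#'
#' One PNG per target slice with input, ground truth, reconstruction and
#' heatmap overlay side by side (the published figure layout).
#'
#' @param result a `reconstruction_result`.
#' @param input_triplet the matching input triplet.
#' @param dir output directory.
#' @param clip_max,alpha passed to [render_heatmap()].
#' @return the directory, invisibly.
#' @export
write_heatmap_panel <- function(result, input_triplet, dir,
                                clip_max = 0.2, alpha = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ov <- render_heatmap(result, clip_max, alpha)
  for (s in seq_len(dim(ov)[4])) {
    gray <- function(m) {
      a <- array(0, c(dim(m), 3L)); a[, , 1] <- a[, , 2] <- a[, , 3] <- m; a
    }
    panel <- abind_w(gray(input_triplet[, , s]),
                     gray(result$target_triplet[, , s]),
                     gray(result$reconstructed_triplet[, , s]),
                     ov[, , , s])
    png::writePNG(clamp01(panel),
                  file.path(dir, sprintf("set%03d_slice%d.png",
                                         result$start_index, s)))
  }
  invisible(dir)
}

# column-wise concatenation of H x W x 3 images with a 2px gap
abind_w <- function(...) {
  imgs <- list(...)
  H <- dim(imgs[[1]])[1]
  gap <- array(1, c(H, 2L, 3L))
  pieces <- list()
  for (i in seq_along(imgs)) {
    pieces[[length(pieces) + 1L]] <- imgs[[i]]
    if (i < length(imgs)) pieces[[length(pieces) + 1L]] <- gap
  }
  W <- sum(vapply(pieces, function(p) dim(p)[2], integer(1)))
  out <- array(0, c(H, W, 3L))
  at <- 1L
  for (p in pieces) {
    w <- dim(p)[2]
    out[, at:(at + w - 1L), ] <- p
    at <- at + w
  }
  out
}
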