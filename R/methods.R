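# S3 methods for fitted madgan objects.

#' @export
print.madgan <- function(x, ...) {
  cat(sprintf(
    "<madgan> %s variant, depth %d, base %d channels, canvas %dx%d\n",
    x$spec$sa_variant, x$spec$depth, x$spec$base_channels,
    x$spec$canvas[1], x$spec$canvas[2]))
  cat(sprintf("  trained %d steps (batch %d, lr %g) on %d scans / %d pairs\n",
              x$control$total_steps, x$control$batch_size,
              x$control$learning_rate, x$n_scans, x$n_pairs))
  h <- x$history
  cat(sprintf("  final losses: critic %.3f, gp %.3f, l1/pixel %.4f\n",
              h$critic_loss[nrow(h)], h$gp[nrow(h)],
              h$gen_l1_per_pixel[nrow(h)]))
  invisible(x)
}

#' @export
summary.madgan <- function(object, ...) {
  out <- list(
    spec = object$spec, loss = object$loss, control = object$control,
    n_scans = object$n_scans, n_pairs = object$n_pairs,
    n_params_generator = n_parameters(object$generator),
    n_params_critic = n_parameters(object$critic),
    n_attention = length(object$spec$sa_sites),
    history = object$history)
  class(out) <- "summary.madgan"
  out
}

#' @export
print.summary.madgan <- function(x, ...) {
  cat(sprintf(
    "Adversarial slice-reconstruction model (%s, %d attention modules)\n",
    x$spec$sa_variant, x$n_attention))
  cat(sprintf("  generator: %d parameters; critic: %d parameters\n",
              x$n_params_generator, x$n_params_critic))
  cat(sprintf("  objective: lambda_l1 = %s, lambda_gp = %g\n",
              if (x$loss$use_l1) format(x$loss$lambda_l1) else "off",
              x$loss$lambda_gp))
  cat(sprintf("  schedule: %d steps, batch %d, lr %g, flip 1/%d\n",
              x$control$total_steps, x$control$batch_size,
              x$control$learning_rate, x$control$flip_period))
  h <- x$history
  cat(sprintf("  l1/pixel: first %.4f -> last %.4f\n",
              h$gen_l1_per_pixel[1], h$gen_l1_per_pixel[nrow(h)]))
  invisible(x)
}

#' Loss curves of a fitted model
#'
#' @param x a `madgan` object.
#' @param which `"l1"` (per-pixel reconstruction), `"critic"` or `"gp"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.madgan <- function(x, which = c("l1", "critic", "gp"), ...) {
  which <- match.arg(which)
  h <- x$history
  y <- switch(which, l1 = h$gen_l1_per_pixel, critic = h$critic_loss,
              gp = h$gp)
  lab <- switch(which, l1 = "generator L1 per pixel",
                critic = "critic loss", gp = "gradient penalty")
  graphics::plot(h$step, y, type = "l", xlab = "step", ylab = lab, ...)
  invisible(x)
}

#' @export
coef.madgan <- function(object, ...) {
  c(generator = n_parameters(object$generator),
    critic = n_parameters(object$critic))
}

#' Reconstruct and score unseen scans with a fitted model
#'
#' @param object a fitted `madgan`.
#' @param newdata a `volume_scan`, a list of them, or a `scan_cohort`
#'   (its test partition is used).
#' @param type `"score"` for per-scan anomaly scores (a data.frame),
#'   `"reconstruction"` for the full `reconstruction_result` lists.
#' @param mode scoring mode, `"whole"` or `"top10"`.
#' @param window `top10` window length.
#' @param ... unused.
#' @return a data.frame of scan scores (`scan_id, subtype, group, score,
#'   mean_l2_whole, mean_l2_top10, top10_start, n_sets,
#'   mean_l2_per_pixel`), or a named list of reconstruction lists.
#' @export
predict.madgan <- function(object, newdata, type = c("score", "reconstruction"),
                           mode = c("whole", "top10"), window = 10L, ...) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  scans <- if (inherits(newdata, "volume_scan")) {
    setNames(list(newdata), newdata$scan_id)
  } else if (inherits(newdata, "scan_cohort")) {
    ids <- newdata$manifest$scan_id[newdata$manifest$partition == "test"]
    newdata$scans[ids]
  } else if (is.list(newdata)) {
    setNames(newdata, vapply(newdata, `[[`, "", "scan_id"))
  } else {
    abort_validation("newdata must be scan(s) or a scan_cohort")
  }
  recons <- lapply(scans, reconstruct_scan, model = object)
  if (type == "reconstruction") return(recons)
  rows <- lapply(names(recons), function(id) {
    s <- score_scan(recons[[id]], mode = mode, window = window,
                    scan_id = id, label = scans[[id]]$label)
    data.frame(scan_id = id, subtype = s$label$subtype,
               group = s$label$group, score = s$score,
               mean_l2_whole = s$mean_l2_whole,
               mean_l2_top10 = s$mean_l2_top10,
               top10_start = s$top10_start, n_sets = s$n_sets,
               mean_l2_per_pixel = s$mean_l2_per_pixel,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
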