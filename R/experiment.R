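# One-shot desk-scale experiment: phantom cohort -> train variants ->
# score test scans -> AUC table (rows: model variant x scoring mode,
# columns: positive-subtype comparisons).

#' Experiment configuration
#'
#' Bundles every stage's settings; a config plus its seed fully
#' determines the experiment's outputs. Can be round-tripped through
#' YAML with [read_experiment_config()].
#'
#' @param phantom a [phantom_config()].
#' @param n_healthy,n_abnormal_per_kind,n_train cohort sizes (see
#'   [make_cohort()]).
#' @param specs list of [anomaly_spec()]s.
#' @param variants character vector of `sa_variant` values to train.
#' @param base_channels,depth,critic_depth architecture scale for all
#'   variants.
#' @param loss a [loss_config()].
#' @param control a [train_control()].
#' @param modes scoring modes to evaluate.
#' @param comparisons named list of positive-subtype filters (NULL entry
#'   means all abnormal subtypes).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outdir optional directory for CSV outputs.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(),
                              n_healthy = 30L, n_abnormal_per_kind = 15L,
                              n_train = 20L,
                              specs = list(anomaly_spec("hyperintense_lesion"),
                                           anomaly_spec("atrophy")),
                              variants = "none",
                              base_channels = 4L, depth = 3L,
                              critic_depth = 3L,
                              loss = loss_config(),
                              control = train_control(),
                              modes = c("whole", "top10"),
                              comparisons = list(
                                all_abnormal = NULL,
                                lesion = "phantom_lesion",
                                atrophy = "phantom_atrophy"),
                              seed = 1L, outdir = NULL) {
  structure(list(phantom = phantom, n_healthy = as.integer(n_healthy),
                 n_abnormal_per_kind = as.integer(n_abnormal_per_kind),
                 n_train = as.integer(n_train), specs = specs,
                 variants = variants, base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 critic_depth = as.integer(critic_depth), loss = loss,
                 control = control, modes = modes, comparisons = comparisons,
                 seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

#' Run a full train-diagnose-evaluate experiment
#'
#' Generates a phantom cohort, trains every requested model variant on
#' the healthy training partition, scores the held-out test scans, and
#' tabulates AUCs per variant, scoring mode and comparison. All
#' randomness derives from `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return an object of class `madgan_experiment`: `auc_table`
#'   (data.frame), `scores` (per-variant score data.frames), `models`,
#'   `cohort`, `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- "cohort"
  res <- tryCatch({
    cohort <- make_cohort(config$n_healthy, config$n_abnormal_per_kind,
                          config$phantom, config$specs,
                          seed = derive_seed(config$seed, "cohort"),
                          n_train = config$n_train)
    models <- list()
    scores <- list()
    rows <- list()
    for (v in config$variants) {
      stage <- paste0("train_", v)
      spec <- model_spec(sa_variant = v,
                         base_channels = config$base_channels,
                         depth = config$depth,
                         canvas = config$phantom$canvas,
                         critic_depth = config$critic_depth)
      ctl <- config$control
      ctl$seed <- derive_seed(config$seed, paste0("train_", v))
      if (verbose) message("training variant ", v)
      fit <- madgan(cohort, spec, config$loss, ctl, verbose = verbose)
      models[[v]] <- fit
      stage <- paste0("score_", v)
      sc <- predict(fit, cohort, type = "score")
      scores[[v]] <- sc
      for (m in config$modes) {
        sc$score <- if (m == "whole") sc$mean_l2_whole else sc$mean_l2_top10
        for (cmp in names(config$comparisons)) {
          roc <- evaluate_cohort(sc, config$comparisons[[cmp]])
          rows[[length(rows) + 1L]] <- data.frame(
            variant = v, mode = m, comparison = cmp, auc = roc$auc,
            n_pos = roc$n_pos, n_neg = roc$n_neg,
            stringsAsFactors = FALSE)
        }
      }
    }
    auc_table <- do.call(rbind, rows)
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(auc_table,
                       file.path(config$outdir, "auc_table.csv"),
                       row.names = FALSE)
      for (v in names(scores)) {
        utils::write.csv(scores[[v]],
                         file.path(config$outdir,
                                   paste0("scores_", v, ".csv")),
                         row.names = FALSE)
      }
    }
    structure(list(auc_table = auc_table, scores = scores, models = models,
                   cohort = cohort, config = config),
              class = "madgan_experiment")
  }, error = function(e) {
    stop(errorCondition(
      sprintf("experiment failed at stage '%s' (seed %d): %s", stage,
              config$seed, conditionMessage(e)),
      class = c("madgan_experiment_error", class(e))))
  })
  res
}

#' @export
print.madgan_experiment <- function(x, ...) {
  cat("<madgan_experiment> AUC table:\n")
  print(x$auc_table, row.names = FALSE)
  invisible(x)
}

#' Read / write experiment configs as YAML
#'
#' @param file YAML path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(file) {
  y <- yaml::read_yaml(file)
  experiment_config(
    phantom = do.call(phantom_config, y$phantom %||% list()),
    n_healthy = y$n_healthy %||% 30L,
    n_abnormal_per_kind = y$n_abnormal_per_kind %||% 15L,
    n_train = y$n_train %||% 20L,
    specs = lapply(y$specs %||% list(list(kind = "hyperintense_lesion"),
                                     list(kind = "atrophy")),
                   function(s) do.call(anomaly_spec, s)),
    variants = y$variants %||% "none",
    base_channels = y$base_channels %||% 4L,
    depth = y$depth %||% 3L,
    critic_depth = y$critic_depth %||% 3L,
    loss = do.call(loss_config, y$loss %||% list()),
    control = do.call(train_control, y$control %||% list()),
    modes = y$modes %||% c("whole", "top10"),
    comparisons = y$comparisons %||% list(all_abnormal = NULL,
                                          lesion = "phantom_lesion",
                                          atrophy = "phantom_atrophy"),
    seed = y$seed %||% 1L,
    outdir = y$outdir)
}

#' @rdname read_experiment_config
#' @param config an `experiment_config`.
#' @export
write_experiment_config <- function(config, file) {
  y <- list(phantom = unclass(config$phantom),
            n_healthy = config$n_healthy,
            n_abnormal_per_kind = config$n_abnormal_per_kind,
            n_train = config$n_train,
            specs = lapply(config$specs, unclass),
            variants = config$variants,
            base_channels = config$base_channels, depth = config$depth,
            critic_depth = config$critic_depth,
            loss = unclass(config$loss), control = unclass(config$control),
            modes = config$modes, comparisons = config$comparisons,
            seed = config$seed, outdir = config$outdir)
  yaml::write_yaml(y, file)
  invisible(file)
}
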