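# Training loop: alternating critic/generator Adam updates on batches of
# healthy slice triplets, with gradient penalty and periodic real/fake
# role flipping.

#' Training schedule configuration
#'
#' Full-scale defaults follow the published schedule (batch 16, Adam at
#' learning rate 2e-4, label flipping once in three steps); `total_steps`
#' defaults to a desk-scale budget rather than the published 1.8e6.
#'
#' @param total_steps optimisation steps (one step = `n_critic` critic
#'   updates plus one generator update).
#' @param batch_size triplet pairs per batch.
#' @param learning_rate Adam learning rate for both networks.
#' @param adam_beta1,adam_beta2 Adam moment decays (image-to-image GAN
#'   convention 0.5 / 0.999).
#' @param flip_period flip the critic's real/reconstructed roles every
#'   `flip_period`-th step ("once in three times").
#' @param flip_stochastic flip with probability `1/flip_period` instead of
#'   deterministically.
#' @param checkpoint_steps steps at which parameter snapshots are kept.
#' @param seed integer; fixes initialisation, shuffling, dropout and
#'   interpolation draws.
#' @param log_every record losses every so many steps (the final step is
#'   always recorded).
#' @return an object of class `train_control`.
#' @export
train_control <- function(total_steps = 2000L, batch_size = 16L,
                          learning_rate = 2e-4, adam_beta1 = 0.5,
                          adam_beta2 = 0.999, flip_period = 3L,
                          flip_stochastic = FALSE,
                          checkpoint_steps = integer(0), seed = 1L,
                          log_every = 25L) {
  stopifnot(is_count(total_steps), is_count(batch_size),
            learning_rate >= 0, is_count(flip_period))
  if (length(checkpoint_steps) &&
      (any(checkpoint_steps < 1) || any(checkpoint_steps > total_steps)))
    abort_config("checkpoint_steps must lie in [1, total_steps]")
  structure(list(total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, flip_period = as.integer(flip_period),
                 flip_stochastic = flip_stochastic,
                 checkpoint_steps = as.integer(checkpoint_steps),
                 seed = as.integer(seed), log_every = as.integer(log_every)),
            class = "train_control")
}

#' Label-flip schedule
#'
#' Deterministic realisation of "flip the critic's real/synthetic labels
#' once in `flip_period` times": flips exactly when
#' `step %% flip_period == 0`, so the flipped fraction over any multiple
#' of the period is exactly `1/flip_period`.
#'
#' @param step step counter (1-based).
#' @param flip_period integer period.
#' @return logical: is this step flipped?
#' @export
flip_schedule <- function(step, flip_period = 3L) {
  stopifnot(all(step >= 1), is_count(flip_period))
  step %% flip_period == 0L
}

new_train_state <- function(spec, loss, control) {
  gen <- init_generator(spec)
  crit <- init_critic(spec)
  list(gen = gen, crit = crit,
       opt_g = adam_init(gen$params), opt_c = adam_init(crit$params),
       spec = spec, loss = loss, control = control, step = 0L)
}

#' One optimisation step
#'
#' Runs `n_critic` critic updates (Wasserstein loss with gradient penalty,
#' real/reconstructed roles exchanged on flip steps) followed by one
#' generator update (adversarial term plus the weighted pixel-sum L1
#' term) on a fixed batch. Deterministic given RNG state.
#'
#' @param state training state (internal structure; create via
#'   [madgan()] or `madgan:::new_train_state`).
#' @param batch list with `input` and `target` arrays `H x W x 3 x B`.
#' @return list: updated `state` and a one-row data.frame `record` of the
#'   step's losses.
#' @export
train_step <- function(state, batch) {
  spec <- state$spec; loss <- state$loss; ctl <- state$control
  X <- batch$input; Y <- batch$target
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  if (length(dim(Y)) == 3L) dim(Y) <- c(dim(Y), 1L)
  B <- dim(X)[4]
  state$step <- state$step + 1L
  flip <- if (ctl$flip_stochastic) {
    stats::runif(1) < 1 / ctl$flip_period
  } else {
    flip_schedule(state$step, ctl$flip_period)
  }

  gfwd <- generator_forward(state$gen, X, spec, train = TRUE,
                            keep_cache = TRUE)
  state$gen$state <- gfwd$state
  fake <- gfwd$y

  crec <- list(critic = NA_real_, gp = NA_real_)
  for (ic in seq_len(loss$n_critic)) {
    real_b <- if (flip) fake else Y
    fake_b <- if (flip) Y else fake
    fr <- critic_forward(state$crit, fake_b, spec, keep_cache = TRUE)
    rr <- critic_forward(state$crit, real_b, spec, keep_cache = TRUE)
    eps <- stats::runif(B)
    e <- rep(eps, each = prod(dim(Y)[1:3]))
    xhat <- array(e * Y + (1 - e) * fake, dim(Y))
    gp <- critic_gp(state$crit, spec, xhat, want_grads = TRUE)
    bw_f <- critic_backward(state$crit, spec, fr, rep(1 / B, B))
    bw_r <- critic_backward(state$crit, spec, rr, rep(-1 / B, B))
    grads <- bw_f$grads
    for (nm in names(bw_r$grads)) grads <- acc_grad(grads, nm, bw_r$grads[[nm]])
    for (nm in names(gp$grads))
      grads <- acc_grad(grads, nm, loss$lambda_gp * gp$grads[[nm]])
    c_loss <- mean(fr$scores) - mean(rr$scores) + loss$lambda_gp * gp$penalty
    if (!is.finite(c_loss))
      stop(errorCondition(
        sprintf("non-finite critic loss at step %d", state$step),
        class = c("madgan_training_error", "error")))
    up <- adam_step(state$crit$params, grads, state$opt_c,
                    ctl$learning_rate, ctl$adam_beta1, ctl$adam_beta2)
    state$crit$params <- up$params
    state$opt_c <- up$state
    crec <- list(critic = c_loss, gp = gp$penalty)
  }

  fr2 <- critic_forward(state$crit, fake, spec, keep_cache = TRUE)
  adv_dx <- critic_backward(state$crit, spec, fr2, rep(-1 / B, B),
                            want_params = FALSE, want_input = TRUE)$dx
  dy <- adv_dx
  l1 <- l1_loss(Y, fake) / B
  if (loss$use_l1) dy <- dy + loss$lambda_l1 / B * sign(fake - Y)
  g_adv <- -mean(fr2$scores)
  g_loss <- if (loss$use_l1) g_adv + loss$lambda_l1 * l1 else g_adv
  if (!is.finite(g_loss))
    stop(errorCondition(
      sprintf("non-finite generator loss at step %d", state$step),
      class = c("madgan_training_error", "error")))
  ggrads <- generator_backward(state$gen, spec, gfwd, dy)
  up <- adam_step(state$gen$params, ggrads, state$opt_g,
                  ctl$learning_rate, ctl$adam_beta1, ctl$adam_beta2)
  state$gen$params <- up$params
  state$opt_g <- up$state

  record <- data.frame(step = state$step, critic_loss = crec$critic,
                       gp = crec$gp, gen_adv = g_adv, gen_l1 = l1,
                       gen_l1_per_pixel = l1 / prod(dim(Y)[1:3]),
                       flipped = flip)
  list(state = state, record = record)
}

training_scans <- function(x) {
  if (inherits(x, "volume_scan")) return(list(x))
  if (inherits(x, "scan_cohort")) {
    ids <- x$manifest$scan_id[x$manifest$partition == "train"]
    return(x$scans[ids])
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "volume_scan")))
    return(x)
  abort_validation("data must be a volume_scan, a list of them, or a scan_cohort")
}

#' Fit a slice-reconstruction anomaly detection model
#'
#' The main fitting function. Trains the adversarial next-triplet
#' reconstructor on the healthy training scans of `data` (a
#' [make_cohort()] cohort uses its training partition; a list of scans or
#' a single scan is used as-is). Any non-healthy scan in the training
#' data is an error: the method's contract is strictly unsupervised
#' learning of healthy anatomy.
#'
#' @param data training data (healthy scans only).
#' @param spec a [model_spec()]; its canvas must match the scan dims.
#' @param loss a [loss_config()].
#' @param control a [train_control()].
#' @param verbose print progress lines.
#' @return an object of class `madgan` with elements `generator`,
#'   `critic`, `spec`, `loss`, `control`, `history` (per-logged-step
#'   losses), `checkpoints`, `n_pairs`. Use [predict.madgan()] to
#'   reconstruct and score unseen scans.
#' @export
madgan <- function(data, spec = model_spec(), loss = loss_config(),
                   control = train_control(), verbose = FALSE) {
  scans <- training_scans(data)
  if (length(scans) == 0L) abort_validation("no training scans")
  bad <- vapply(scans, function(s) s$label$group != "healthy", logical(1))
  if (any(bad))
    abort_validation("training data contains non-healthy scans: ",
                     paste(vapply(scans[bad], `[[`, "", "scan_id"),
                           collapse = ", "),
                     " (unsupervised contract: train on healthy only)")
  dims <- vapply(scans, function(s) dim(s$slices)[1:2], integer(2))
  if (any(dims[1, ] != spec$canvas[1]) || any(dims[2, ] != spec$canvas[2]))
    abort_config("scan dims do not match spec canvas ",
                 paste(spec$canvas, collapse = "x"))
  pairs <- do.call(rbind, lapply(seq_along(scans), function(i) {
    n <- scans[[i]]$n_slices
    if (n < 6L) abort_validation("scan too short for 3->3 reconstruction")
    data.frame(scan = i, start = seq_len(n - 5L))
  }))
  cl <- match.call()
  ctl <- control
  set.seed(derive_seed(ctl$seed, "train"))
  state <- new_train_state(spec, loss, ctl)
  history <- list()
  checkpoints <- list()
  order_idx <- integer(0)
  ptr <- 1L
  H <- spec$canvas[1]; W <- spec$canvas[2]
  for (step in seq_len(ctl$total_steps)) {
    X <- array(0, c(H, W, 3L, ctl$batch_size))
    Y <- array(0, c(H, W, 3L, ctl$batch_size))
    for (b in seq_len(ctl$batch_size)) {
      if (ptr > length(order_idx)) {
        order_idx <- sample.int(nrow(pairs))
        ptr <- 1L
      }
      row <- pairs[order_idx[ptr], ]
      ptr <- ptr + 1L
      sl <- scans[[row$scan]]$slices
      X[, , , b] <- sl[, , row$start:(row$start + 2L)]
      Y[, , , b] <- sl[, , (row$start + 3L):(row$start + 5L)]
    }
    res <- train_step(state, list(input = X, target = Y))
    state <- res$state
    if (step %% ctl$log_every == 0L || step == ctl$total_steps || step == 1L) {
      history[[length(history) + 1L]] <- res$record
      if (verbose)
        message(sprintf(
          "step %d/%d  critic %.3f  gp %.3f  l1/px %.4f", step,
          ctl$total_steps, res$record$critic_loss, res$record$gp,
          res$record$gen_l1_per_pixel))
    }
    if (step %in% ctl$checkpoint_steps) {
      checkpoints[[as.character(step)]] <-
        list(step = step, generator = state$gen, critic = state$crit,
             spec = spec)
    }
  }
  structure(list(generator = state$gen, critic = state$crit, spec = spec,
                 loss = loss, control = ctl,
                 history = do.call(rbind, history),
                 checkpoints = checkpoints, n_pairs = nrow(pairs),
                 n_scans = length(scans), call = cl),
            class = "madgan")
}
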