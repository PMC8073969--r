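# Training objective: Wasserstein critic loss with gradient penalty, plus
# a heavily weighted pixel-sum L1 reconstruction term on the generator
# (lambda = 100, defined against the pixel-sum so the published balance
# between the adversarial and reconstruction terms is preserved).  The
# diagnosis error is the pixel-sum squared difference L2.

#' Loss configuration
#'
#' @param lambda_l1 weight of the pixel-sum L1 reconstruction term
#'   (default 100; the published objective). `use_l1 = FALSE` gives the
#'   pure adversarial ablation ("w/o L1 loss").
#' @param lambda_gp gradient-penalty weight (default 10, the canonical
#'   WGAN-GP value).
#' @param use_l1 include the reconstruction term.
#' @param n_critic critic updates per generator update.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(lambda_l1 = 100, lambda_gp = 10, use_l1 = TRUE,
                        n_critic = 1L) {
  stopifnot(lambda_l1 >= 0, lambda_gp >= 0, is_count(n_critic))
  structure(list(lambda_l1 = lambda_l1, lambda_gp = lambda_gp,
                 use_l1 = use_l1, n_critic = as.integer(n_critic)),
            class = "loss_config")
}

check_same_shape <- function(x, x_prime) {
  dx <- dim(x) %||% length(x)
  dy <- dim(x_prime) %||% length(x_prime)
  if (!identical(dx, dy))
    abort_validation("shape mismatch: ", paste(dx, collapse = "x"), " vs ",
                     paste(dy, collapse = "x"))
}

#' Pixel-sum L1 loss
#'
#' `sum_i |x_i - x'_i|` over all P pixels (all channels of a triplet).
#'
#' @param x,x_prime arrays of identical shape.
#' @return non-negative scalar, zero iff the images are identical.
#' @export
l1_loss <- function(x, x_prime) {
  check_same_shape(x, x_prime)
  sum(abs(x - x_prime))
}

#' Pixel-sum squared error (L2) with per-pixel map
#'
#' `sum_i (x_i - x'_i)^2` over all P pixels; the diagnosis error. Also
#' returns the per-pixel squared-difference map used for heatmap overlays.
#'
#' @param x,x_prime arrays of identical shape.
#' @return list of class `pixel_error_map` with elements `l2` (scalar),
#'   `values` (per-pixel map, same shape as `x`) and `P` (pixel count);
#'   `sum(values) == l2`.
#' @export
l2_error <- function(x, x_prime) {
  check_same_shape(x, x_prime)
  m <- (x - x_prime)^2
  structure(list(l2 = sum(m), values = m, P = length(m)),
            class = "pixel_error_map")
}

#' Gradient penalty of a critic
#'
#' The WGAN-GP penalty `mean_s (||grad_x critic(x_hat_s)||_2 - 1)^2`
#' evaluated at per-sample interpolates
#' `x_hat = eps * real + (1 - eps) * fake`, `eps ~ U(0,1)` drawn once per
#' sample and shared across that sample's pixels.
#'
#' For a fitted critic (a list with `params`, as built by
#' [init_critic()]), the input gradient comes from the critic's exact
#' backward pass. For an arbitrary scoring function, supply `grad_fn(x)`
#' returning the input gradient, or leave it `NULL` to fall back on
#' central finite differences (small inputs only).
#'
#' @param critic a critic list or a function `x -> scalar score` taking a
#'   single `H x W x C` array.
#' @param real,fake batches `H x W x C x N` (single samples promoted).
#' @param eps numeric vector of per-sample draws in \[0,1\]; defaults to
#'   fresh uniform draws.
#' @param spec the [model_spec()] (fitted critic only).
#' @param grad_fn optional analytic input-gradient function.
#' @param fd_step finite-difference step.
#' @return non-negative scalar; zero iff every interpolate has a unit-norm
#'   input gradient.
#' @export
gradient_penalty <- function(critic, real, fake, eps = NULL, spec = NULL,
                             grad_fn = NULL, fd_step = 1e-5) {
  if (length(dim(real)) == 3L) dim(real) <- c(dim(real), 1L)
  if (length(dim(fake)) == 3L) dim(fake) <- c(dim(fake), 1L)
  check_same_shape(real, fake)
  N <- dim(real)[4]
  eps <- eps %||% stats::runif(N)
  stopifnot(length(eps) == N, all(eps >= 0 & eps <= 1))
  e <- rep(eps, each = prod(dim(real)[1:3]))
  xhat <- array(e * real + (1 - e) * fake, dim(real))
  if (is.list(critic) && !is.null(critic$params)) {
    if (is.null(spec)) abort_config("spec required for a fitted critic")
    return(critic_gp(critic, spec, xhat, want_grads = FALSE)$penalty)
  }
  if (!is.function(critic))
    abort_validation("critic must be a fitted critic or a scoring function")
  norms <- vapply(seq_len(N), function(n) {
    xs <- array(xhat[, , , n], dim(xhat)[1:3])
    g <- if (!is.null(grad_fn)) grad_fn(xs) else numeric_input_grad(critic, xs, fd_step)
    sqrt(sum(g * g))
  }, numeric(1))
  mean((norms - 1)^2)
}

numeric_input_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' Critic (Wasserstein) loss
#'
#' `mean(fake_scores) - mean(real_scores) + lambda_gp * gp`.
#'
#' @param real_scores,fake_scores numeric score vectors of equal length.
#' @param gp gradient-penalty scalar.
#' @param config a [loss_config()].
#' @return scalar.
#' @export
critic_loss <- function(real_scores, fake_scores, gp = 0,
                        config = loss_config()) {
  if (length(real_scores) != length(fake_scores))
    abort_validation("mismatched batch sizes")
  mean(fake_scores) - mean(real_scores) + config$lambda_gp * gp
}

#' Generator loss
#'
#' `-mean(fake_scores) + lambda_l1 * l1_loss(target, reconstructed)` when
#' the reconstruction term is enabled, else the pure adversarial term.
#' For batches the L1 term is the mean over samples of per-sample
#' pixel-sum L1.
#'
#' @param fake_scores critic scores of the reconstructed batch.
#' @param target,reconstructed triplet batches (may be `NULL` when
#'   `use_l1` is off).
#' @param config a [loss_config()].
#' @return scalar.
#' @export
generator_loss <- function(fake_scores, target = NULL, reconstructed = NULL,
                           config = loss_config()) {
  adv <- -mean(fake_scores)
  if (!config$use_l1) return(adv)
  check_same_shape(target, reconstructed)
  nb <- if (length(dim(target)) == 4L) dim(target)[4] else 1L
  adv + config$lambda_l1 * l1_loss(target, reconstructed) / nb
}
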