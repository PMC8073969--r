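# Network primitives over the compiled convolution kernels.  All feature
# maps are H x W x C x N arrays (column-major, batch last); parameters of
# a network live in one flat named list of numeric arrays so the Adam
# update and gradient bookkeeping stay generic.

conv_fwd <- function(x, w, b, stride = 2L, pad = 1L) {
  .nn_conv_fwd(x, w, b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, w, dy, stride = 2L, pad = 1L,
                     want_dx = TRUE, want_dw = TRUE) {
  .nn_conv_bwd(x, w, dy, as.integer(stride), as.integer(pad),
               want_dx, want_dw)
}

# Transposed convolution (stride-2 upsampling).  The weight is stored in
# the orientation of the underlying adjoint convolution:
# kh x kw x Cout x Cin, so the forward pass is that convolution's
# input-gradient and the backward passes swap roles.
deconv_fwd <- function(x, w, b, stride = 2L, pad = 1L) {
  d <- dim(x)
  y <- .nn_conv_bwd_input(w, x, as.integer(stride), as.integer(pad),
                          as.integer(d[1] * stride), as.integer(d[2] * stride))
  yd <- dim(y)
  y + rep(b, each = yd[1] * yd[2])
}

deconv_bwd <- function(x, w, dy, stride = 2L, pad = 1L) {
  dx <- conv_fwd(dy, w, numeric(dim(w)[4]), stride, pad)
  g <- conv_bwd(dy, w, x, stride, pad, want_dx = FALSE, want_dw = TRUE)
  yd <- dim(dy)
  dim(dy) <- c(yd[1] * yd[2], yd[3], yd[4])
  list(dx = dx, dw = g$dw, db = rowSums(colSums(dy)))
}

lrelu_fwd <- function(x, alpha = 0.2) {
  f <- ifelse(x > 0, 1, alpha)
  list(y = x * f, f = f)
}

relu_fwd <- function(x) {
  f <- (x > 0) * 1
  list(y = x * f, f = f)
}

dropout_fwd <- function(x, rate) {
  keep <- 1 - rate
  m <- (array(stats::runif(length(x)), dim(x)) < keep) / keep
  list(y = x * m, m = m)
}

# per-channel batch normalisation over (H, W, N)
bn_fwd <- function(x, gamma, beta, state, key, train = TRUE,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (train) {
    dim(x) <- c(HW, C, N)
    mu <- rowMeans(colSums(x)) / HW
    xc <- x - rep(mu, each = HW)
    v <- rowMeans(colSums(xc * xc)) / HW
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * rep(invstd, each = HW)
    y <- xhat * rep(gamma, each = HW) + rep(beta, each = HW)
    dim(y) <- d; dim(xhat) <- d
    state[[paste0(key, "_rm")]] <-
      (1 - momentum) * (state[[paste0(key, "_rm")]] %||% 0) + momentum * mu
    state[[paste0(key, "_rv")]] <-
      (1 - momentum) * (state[[paste0(key, "_rv")]] %||% 1) + momentum * v
    list(y = y, xhat = xhat, invstd = invstd, state = state)
  } else {
    rm <- state[[paste0(key, "_rm")]] %||% rep(0, C)
    rv <- state[[paste0(key, "_rv")]] %||% rep(1, C)
    invstd <- 1 / sqrt(rv + eps)
    y <- (x - rep(rm, each = HW)) * rep(gamma * invstd, each = HW) +
      rep(beta, each = HW)
    dim(y) <- d
    list(y = y, xhat = NULL, invstd = invstd, state = state)
  }
}

bn_bwd <- function(dy, gamma, cache) {
  d <- dim(dy); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- HW * N
  xhat <- cache$xhat
  dim(dy) <- c(HW, C, N); dim(xhat) <- c(HW, C, N)
  dbeta <- rowSums(colSums(dy))
  dgamma <- rowSums(colSums(dy * xhat))
  dxhat <- dy * rep(gamma, each = HW)
  s1 <- rowSums(colSums(dxhat))
  s2 <- gamma * dgamma   # = per-channel sum(dxhat * xhat)
  dx <- (dxhat - rep(s1, each = HW) / M - xhat * rep(s2, each = HW) / M) *
    rep(cache$invstd, each = HW)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dense_fwd <- function(x, w, b) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  as.numeric(crossprod(xm, w)) + b
}

dense_bwd <- function(x, w, dscore) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  dx <- array(w %o% dscore, d)
  list(dx = dx, dw = as.numeric(xm %*% dscore), db = sum(dscore))
}

init_w <- function(dims, sd = 0.02) array(stats::rnorm(prod(dims), 0, sd), dims)

# Adam optimizer over a flat named list of arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# accumulate gradient contributions into a flat named list
acc_grad <- function(grads, nm, g) {
  grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  grads
}
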