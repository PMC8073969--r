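# Self-attention over spatial positions (SAGAN-style): softmax-weighted
# aggregation of all positions through 1x1 query/key/value projections,
# added back through a learnable scalar gate gamma initialised at 0 (so a
# freshly inserted module is the identity).

#' Initialise self-attention parameters
#'
#' @param channels feature channels C at the insertion point.
#' @param ratio channel-reduction ratio for the query/key projections
#'   (default 8); the value projection uses C/2 channels. C must be at
#'   least `ratio`.
#' @return flat named list: `wq`, `wk` (C x C/ratio), `wv` (C x C/2),
#'   `wo` (C/2 x C), `gamma` (scalar, 0).
#' @export
self_attention_params <- function(channels, ratio = 8L) {
  if (channels < ratio)
    abort_config("self-attention needs >= ", ratio, " channels, got ",
                 channels)
  cq <- max(1L, channels %/% ratio)
  cv <- max(1L, channels %/% 2L)
  list(wq = init_w(c(channels, cq)), wk = init_w(c(channels, cq)),
       wv = init_w(c(channels, cv)), wo = init_w(c(cv, channels)),
       gamma = 0)
}

#' Self-attention forward pass
#'
#' For each sample, features are flattened to a positions-by-channels
#' matrix X (P = H*W). Attention weights A = softmax_rows(XWq (XWk)') form
#' a row-stochastic P x P matrix; the output is
#' `X + gamma * (A X Wv) Wo`, reshaped back -- shape is always preserved,
#' and at `gamma = 0` the module is exactly the identity.
#'
#' @param x feature array `H x W x C x N`.
#' @param params from [self_attention_params()].
#' @param cache keep intermediates for the backward pass.
#' @return if `cache` is `FALSE`, the output array; otherwise a list with
#'   `y` and per-sample caches (including the attention matrices `A`).
#' @export
self_attention_forward <- function(x, params, cache = FALSE) {
  d <- dim(x)
  if (length(d) == 3L) {dim(x) <- d <- c(d, 1L)}
  P <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (nrow(params$wq) != C)
    abort_config("attention params built for ", nrow(params$wq),
                 " channels, input has ", C)
  y <- x
  caches <- vector("list", N)
  for (n in seq_len(N)) {
    X <- matrix(x[, , , n], P, C)
    Q <- X %*% params$wq
    K <- X %*% params$wk
    S <- tcrossprod(Q, K)
    S <- S - apply(S, 1, max)          # row-wise stabilisation
    A <- exp(S)
    A <- A / rowSums(A)
    V <- X %*% params$wv
    O <- A %*% V
    Z <- O %*% params$wo
    y[, , , n] <- array(X + params$gamma * Z, c(d[1], d[2], C))
    if (cache) caches[[n]] <- list(X = X, Q = Q, K = K, A = A, V = V, O = O)
  }
  if (!cache) return(y)
  list(y = y, caches = caches, dims = d)
}

self_attention_backward <- function(dy, params, fwd) {
  d <- fwd$dims
  P <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dx <- dy
  g <- list(wq = params$wq * 0, wk = params$wk * 0, wv = params$wv * 0,
            wo = params$wo * 0, gamma = 0)
  for (n in seq_len(N)) {
    cc <- fwd$caches[[n]]
    dYn <- matrix(dy[, , , n], P, C)
    Z <- cc$O %*% params$wo
    g$gamma <- g$gamma + sum(dYn * Z)
    dZ <- params$gamma * dYn
    g$wo <- g$wo + crossprod(cc$O, dZ)
    dO <- tcrossprod(dZ, params$wo)
    dV <- crossprod(cc$A, dO)
    dA <- tcrossprod(dO, cc$V)
    # softmax rows backward
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dQ <- dS %*% cc$K
    dK <- crossprod(dS, cc$Q)
    dXn <- dYn +
      tcrossprod(dQ, params$wq) + tcrossprod(dK, params$wk) +
      tcrossprod(dV, params$wv)
    g$wq <- g$wq + crossprod(cc$X, dQ)
    g$wk <- g$wk + crossprod(cc$X, dK)
    g$wv <- g$wv + crossprod(cc$X, dV)
    dx[, , , n] <- array(dXn, c(d[1], d[2], C))
  }
  list(dx = dx, grads = g)
}
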