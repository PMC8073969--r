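# Architecture: a U-Net-like generator (strided 4x4 convolutions down,
# transposed convolutions up, skip connections, batch norm, leaky-ReLU /
# ReLU, two 0.5 dropout layers in the deepest decoder blocks, output
# clamped to [0,1]) and a strided-convolution Wasserstein critic without
# normalisation (incompatible with the per-sample gradient penalty).
# Self-attention modules can be inserted at named sites; the none/3/7
# variants mirror the published architecture family.

#' Architecture specification
#'
#' @param sa_variant `"none"`, `"sa3"` or `"sa7"` -- 0, 3 or 7
#'   self-attention modules. `"sa3"` places them after the deepest encoder
#'   level, on the bottleneck, and after the deepest decoder level;
#'   `"sa7"` adds four more at the two next-larger feature-map scales on
#'   both sides (needs `depth >= 4`).
#' @param base_channels first-level feature channels (doubled per level,
#'   capped at 8x).
#' @param depth encoder/decoder levels; 4 reproduces the full-scale
#'   architecture (4 convolutions down, 4 deconvolutions up).
#' @param canvas input dims `c(rows, cols)`; both must be divisible by
#'   `2^depth`.
#' @param dropout_rate rate of the two decoder dropout layers.
#' @param sa_ratio channel-reduction ratio inside attention modules.
#' @param sa_sites optional explicit site names overriding the variant
#'   (subset of `enc2..encD`, `"mid"`, `decD..dec2`).
#' @param critic_depth critic convolution levels (3 or 4).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(sa_variant = c("none", "sa3", "sa7"),
                       base_channels = 64L, depth = 4L,
                       canvas = c(176L, 256L), dropout_rate = 0.5,
                       sa_ratio = 8L, sa_sites = NULL, critic_depth = 4L) {
  sa_variant <- match.arg(sa_variant)
  if (!is_count(depth, 2L)) abort_config("depth must be >= 2")
  if (any(canvas %% 2L^depth != 0L)) {
    ax <- which(canvas %% 2L^depth != 0L)[1]
    abort_config("canvas axis ", c("rows", "cols")[ax], " (", canvas[ax],
                 ") not divisible by 2^depth = ", 2L^depth)
  }
  if (!critic_depth %in% c(3L, 4L))
    abort_config("critic_depth must be 3 or 4")
  all_sites <- c(paste0("enc", 2:depth), "mid",
                 if (depth >= 2) paste0("dec", depth:2))
  if (is.null(sa_sites)) {
    sa_sites <- switch(sa_variant,
      none = character(0),
      sa3 = c(paste0("enc", depth), "mid", paste0("dec", depth)),
      sa7 = {
        if (depth < 4L)
          abort_config("sa7 needs depth >= 4 for 7 distinct sites")
        c(paste0("enc", (depth - 2):depth), "mid",
          paste0("dec", depth:(depth - 2)))
      })
  }
  if (!all(sa_sites %in% all_sites))
    abort_config("unknown sa_sites: ",
                 paste(setdiff(sa_sites, all_sites), collapse = ", "))
  structure(list(sa_variant = sa_variant,
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), canvas = as.integer(canvas),
                 input_channels = 3L, output_channels = 3L,
                 dropout_rate = dropout_rate, sa_ratio = as.integer(sa_ratio),
                 sa_sites = sa_sites,
                 critic_depth = as.integer(critic_depth)),
            class = "model_spec")
}

gen_channels <- function(spec) {
  pmin(spec$base_channels * 2L^(seq_len(spec$depth) - 1L),
       8L * spec$base_channels)
}

#' Initialise generator parameters
#'
#' @param spec a [model_spec()].
#' @return list with flat `params` named list and a `state` list holding
#'   batch-norm running statistics.
#' @export
init_generator <- function(spec) {
  d <- spec$depth
  f <- gen_channels(spec)
  p <- list()
  cin <- spec$input_channels
  for (k in seq_len(d)) {
    p[[paste0("enc", k, "_w")]] <- init_w(c(4, 4, cin, f[k]))
    p[[paste0("enc", k, "_b")]] <- numeric(f[k])
    if (k > 1) {
      p[[paste0("enc", k, "_bn_gamma")]] <- rep(1, f[k])
      p[[paste0("enc", k, "_bn_beta")]] <- numeric(f[k])
    }
    cin <- f[k]
  }
  for (j in d:1) {
    cin_j <- if (j == d) f[d] else 2L * f[j]
    cout_j <- if (j == 1) spec$output_channels else f[j - 1]
    p[[paste0("dec", j, "_w")]] <- init_w(c(4, 4, cout_j, cin_j))
    p[[paste0("dec", j, "_b")]] <- numeric(cout_j)
    if (j > 1) {
      p[[paste0("dec", j, "_bn_gamma")]] <- rep(1, cout_j)
      p[[paste0("dec", j, "_bn_beta")]] <- numeric(cout_j)
    }
  }
  for (site in spec$sa_sites) {
    ch <- sa_site_channels(spec, site)
    sa <- self_attention_params(ch, spec$sa_ratio)
    for (nm in names(sa)) p[[paste0("sa_", site, "_", nm)]] <- sa[[nm]]
  }
  list(params = p, state = list())
}

sa_site_channels <- function(spec, site) {
  f <- gen_channels(spec)
  if (site == "mid") return(f[spec$depth])
  k <- as.integer(sub("^(enc|dec)", "", site))
  if (startsWith(site, "enc")) f[k] else if (k == 1) 3L else f[k - 1]
}

sa_pack <- function(params, site) {
  list(wq = params[[paste0("sa_", site, "_wq")]],
       wk = params[[paste0("sa_", site, "_wk")]],
       wv = params[[paste0("sa_", site, "_wv")]],
       wo = params[[paste0("sa_", site, "_wo")]],
       gamma = params[[paste0("sa_", site, "_gamma")]])
}


#' Generator forward pass
#'
#' Maps an input slice triplet to the predicted next triplet. Training
#' mode uses batch statistics and active dropout; eval mode uses running
#' statistics with dropout off and is fully deterministic.
#'
#' @param gen from [init_generator()] (or the `generator` element of a
#'   fitted model).
#' @param x array `H x W x 3 x N` (a single `H x W x 3` triplet is
#'   promoted to a batch of one).
#' @param spec the [model_spec()].
#' @param train logical.
#' @param keep_cache keep intermediates for backprop (internal).
#' @return the output array (same shape as `x`, values in \[0,1\]);
#'   with `keep_cache`, a list `y`, `cache`, `state`.
#' @export
generator_forward <- function(gen, x, spec, train = FALSE,
                              keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d0 <- dim(x)
  if (d0[3] != spec$input_channels)
    abort_config("generator input must have ", spec$input_channels,
                 " channels")
  for (ax in 1:2) {
    if (d0[ax] %% 2L^spec$depth != 0L)
      abort_config("input axis ", c("rows", "cols")[ax], " (", d0[ax],
                   ") not divisible by 2^depth = ", 2L^spec$depth)
  }
  p <- gen$params
  state <- gen$state
  cache <- list()
  d <- spec$depth
  e <- vector("list", d)
  h <- x
  for (k in seq_len(d)) {
    cache[[paste0("enc", k, "_in")]] <- h
    a <- conv_fwd(h, p[[paste0("enc", k, "_w")]], p[[paste0("enc", k, "_b")]])
    if (k > 1) {
      bn <- bn_fwd(a, p[[paste0("enc", k, "_bn_gamma")]],
                   p[[paste0("enc", k, "_bn_beta")]], state,
                   paste0("enc", k, "_bn"), train)
      state <- bn$state
      cache[[paste0("enc", k, "_bn")]] <- bn[c("xhat", "invstd")]
      a <- bn$y
    }
    act <- lrelu_fwd(a)
    cache[[paste0("enc", k, "_act")]] <- act$f
    h <- act$y
    site <- paste0("enc", k)
    if (site %in% spec$sa_sites) {
      fwd <- self_attention_forward(h, sa_pack(p, site), cache = TRUE)
      cache[[paste0("sa_", site)]] <- fwd
      h <- fwd$y
    }
    e[[k]] <- h
  }
  if ("mid" %in% spec$sa_sites) {
    fwd <- self_attention_forward(h, sa_pack(p, "mid"), cache = TRUE)
    cache$sa_mid <- fwd
    h <- fwd$y
  }
  t <- h
  drop_sites <- paste0("dec", d:max(2L, d - 1L))[1:min(2L, d - 1L)]
  for (j in d:1) {
    inp <- if (j == d) t else {
      ch1 <- dim(t)[3]
      comb <- array(0, c(dim(t)[1:2], ch1 + dim(e[[j]])[3], dim(t)[4]))
      comb[, , seq_len(ch1), ] <- t
      comb[, , ch1 + seq_len(dim(e[[j]])[3]), ] <- e[[j]]
      comb
    }
    cache[[paste0("dec", j, "_in")]] <- inp
    a <- deconv_fwd(inp, p[[paste0("dec", j, "_w")]],
                    p[[paste0("dec", j, "_b")]])
    if (j > 1) {
      bn <- bn_fwd(a, p[[paste0("dec", j, "_bn_gamma")]],
                   p[[paste0("dec", j, "_bn_beta")]], state,
                   paste0("dec", j, "_bn"), train)
      state <- bn$state
      cache[[paste0("dec", j, "_bn")]] <- bn[c("xhat", "invstd")]
      act <- relu_fwd(bn$y)
      cache[[paste0("dec", j, "_act")]] <- act$f
      t <- act$y
      if (train && spec$dropout_rate > 0 && paste0("dec", j) %in% drop_sites) {
        dr <- dropout_fwd(t, spec$dropout_rate)
        cache[[paste0("dec", j, "_drop")]] <- dr$m
        t <- dr$y
      }
      site <- paste0("dec", j)
      if (site %in% spec$sa_sites) {
        fwd <- self_attention_forward(t, sa_pack(p, site), cache = TRUE)
        cache[[paste0("sa_", site)]] <- fwd
        t <- fwd$y
      }
    } else {
      cache$out_pre <- a
      t <- clamp01(a)
    }
  }
  if (!keep_cache) return(t)
  list(y = t, cache = cache, state = state)
}

# Backward pass through the generator given dL/dy; returns flat grads.
generator_backward <- function(gen, spec, fwd, dy) {
  p <- gen$params
  cache <- fwd$cache
  d <- spec$depth
  grads <- list()
  # output clamp: pass-through only inside (0,1)
  pre <- cache$out_pre
  g <- dy * ((pre > 0) & (pre < 1))
  skip_grads <- vector("list", d)
  for (j in 1:d) {
    if (j > 1) {
      site <- paste0("dec", j)
      if (site %in% spec$sa_sites) {
        sb <- self_attention_backward(g, sa_pack(p, site),
                                      cache[[paste0("sa_", site)]])
        for (nm in names(sb$grads))
          grads <- acc_grad(grads, paste0("sa_", site, "_", nm), sb$grads[[nm]])
        g <- sb$dx
      }
      dm <- cache[[paste0("dec", j, "_drop")]]
      if (!is.null(dm)) g <- g * dm
      g <- g * cache[[paste0("dec", j, "_act")]]
      bb <- bn_bwd(g, p[[paste0("dec", j, "_bn_gamma")]],
                   cache[[paste0("dec", j, "_bn")]])
      grads <- acc_grad(grads, paste0("dec", j, "_bn_gamma"), bb$dgamma)
      grads <- acc_grad(grads, paste0("dec", j, "_bn_beta"), bb$dbeta)
      g <- bb$dx
    }
    db <- deconv_bwd(cache[[paste0("dec", j, "_in")]],
                     p[[paste0("dec", j, "_w")]], g)
    grads <- acc_grad(grads, paste0("dec", j, "_w"), db$dw)
    grads <- acc_grad(grads, paste0("dec", j, "_b"), db$db)
    g <- db$dx
    if (j < d) {
      ch1 <- dim(g)[3] - dim(cache[[paste0("enc", j, "_act")]])[3]
      skip_grads[[j]] <- g[, , (ch1 + 1):dim(g)[3], , drop = FALSE]
      g <- g[, , seq_len(ch1), , drop = FALSE]
    }
  }
  if ("mid" %in% spec$sa_sites) {
    sb <- self_attention_backward(g, sa_pack(p, "mid"), cache$sa_mid)
    for (nm in names(sb$grads))
      grads <- acc_grad(grads, paste0("sa_mid_", nm), sb$grads[[nm]])
    g <- sb$dx
  }
  for (k in d:1) {
    if (k < d && !is.null(skip_grads[[k]])) g <- g + skip_grads[[k]]
    site <- paste0("enc", k)
    if (site %in% spec$sa_sites) {
      sb <- self_attention_backward(g, sa_pack(p, site),
                                    cache[[paste0("sa_", site)]])
      for (nm in names(sb$grads))
        grads <- acc_grad(grads, paste0("sa_", site, "_", nm), sb$grads[[nm]])
      g <- sb$dx
    }
    g <- g * cache[[paste0("enc", k, "_act")]]
    if (k > 1) {
      bb <- bn_bwd(g, p[[paste0("enc", k, "_bn_gamma")]],
                   cache[[paste0("enc", k, "_bn")]])
      grads <- acc_grad(grads, paste0("enc", k, "_bn_gamma"), bb$dgamma)
      grads <- acc_grad(grads, paste0("enc", k, "_bn_beta"), bb$dbeta)
      g <- bb$dx
    }
    cb <- conv_bwd(cache[[paste0("enc", k, "_in")]],
                   p[[paste0("enc", k, "_w")]], g,
                   want_dx = (k > 1), want_dw = TRUE)
    grads <- acc_grad(grads, paste0("enc", k, "_w"), cb$dw)
    grads <- acc_grad(grads, paste0("enc", k, "_b"), cb$db)
    if (k > 1) g <- cb$dx
  }
  grads
}

#' Initialise critic parameters
#'
#' A strided-convolution encoder (leaky ReLU, no normalisation) followed
#' by a linear projection to one unbounded real score per input -- the
#' standard Wasserstein critic contract.
#'
#' @param spec a [model_spec()].
#' @return list with flat `params`.
#' @export
init_critic <- function(spec) {
  L <- spec$critic_depth
  f <- pmin(spec$base_channels * 2L^(seq_len(L) - 1L),
            8L * spec$base_channels)
  p <- list()
  cin <- spec$input_channels
  h <- spec$canvas[1]; w <- spec$canvas[2]
  for (l in seq_len(L)) {
    p[[paste0("c", l, "_w")]] <- init_w(c(4, 4, cin, f[l]))
    p[[paste0("c", l, "_b")]] <- numeric(f[l])
    cin <- f[l]
    h <- h %/% 2L; w <- w %/% 2L
  }
  p$dense_w <- init_w(c(h * w * cin)) ; dim(p$dense_w) <- NULL
  p$dense_b <- 0
  list(params = p, n_features = h * w * cin)
}

#' Critic forward pass
#'
#' @param crit from [init_critic()].
#' @param x triplet batch `H x W x 3 x N` (single triplet promoted).
#' @param spec the [model_spec()].
#' @param keep_cache keep intermediates (internal).
#' @return numeric vector of N real scores (or a list with `scores` and
#'   `cache`).
#' @export
critic_forward <- function(crit, x, spec, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  p <- crit$params
  L <- spec$critic_depth
  cache <- list(inputs = vector("list", L), masks = vector("list", L))
  h <- x
  for (l in seq_len(L)) {
    cache$inputs[[l]] <- h
    a <- conv_fwd(h, p[[paste0("c", l, "_w")]], p[[paste0("c", l, "_b")]])
    act <- lrelu_fwd(a)
    cache$masks[[l]] <- act$f
    h <- act$y
  }
  cache$top <- h
  scores <- dense_fwd(h, p$dense_w, p$dense_b)
  if (!keep_cache) return(scores)
  list(scores = scores, cache = cache)
}

# Parameter gradients of sum(dscore * score); optionally also the input
# gradient (needed by the generator update and the gradient penalty).
critic_backward <- function(crit, spec, fwd, dscore, want_params = TRUE,
                            want_input = FALSE, store_chain = FALSE) {
  p <- crit$params
  L <- spec$critic_depth
  cache <- fwd$cache
  grads <- list()
  db <- dense_bwd(cache$top, p$dense_w, dscore)
  if (want_params) {
    grads$dense_w <- db$dw
    grads$dense_b <- db$db
  }
  g <- db$dx
  chain <- if (store_chain) vector("list", L) else NULL
  for (l in L:1) {
    g <- g * cache$masks[[l]]          # delta at pre-activation a_l
    if (store_chain) chain[[l]] <- g
    cb <- conv_bwd(cache$inputs[[l]], p[[paste0("c", l, "_w")]], g,
                   want_dx = (l > 1 || want_input), want_dw = want_params)
    if (want_params) {
      grads <- acc_grad(grads, paste0("c", l, "_w"), cb$dw)
      grads <- acc_grad(grads, paste0("c", l, "_b"), cb$db)
    }
    if (l > 1 || want_input) g <- cb$dx
  }
  list(grads = grads, dx = if (want_input) g else NULL, chain = chain)
}

# Gradient of the critic score w.r.t. its input, per sample.
critic_input_grad <- function(crit, spec, x, dscore = NULL) {
  fwd <- critic_forward(crit, x, spec, keep_cache = TRUE)
  n <- length(fwd$scores)
  critic_backward(crit, spec, fwd, dscore %||% rep(1, n),
                  want_params = FALSE, want_input = TRUE)$dx
}

# Gradient penalty and its parameter gradients by an explicit
# double-backward pass.  For the piecewise-linear critic (convolutions,
# leaky ReLU, final linear map) the activation masks are locally constant,
# so freezing them makes the input-gradient g(theta) an explicitly
# differentiable chain of linear maps; the second pass propagates
# v = dpenalty/dg forward through that chain, yielding exact gradients
# almost everywhere.
critic_gp <- function(crit, spec, xhat, want_grads = TRUE) {
  p <- crit$params
  L <- spec$critic_depth
  fwd <- critic_forward(crit, xhat, spec, keep_cache = TRUE)
  N <- length(fwd$scores)
  bw <- critic_backward(crit, spec, fwd, rep(1, N), want_params = FALSE,
                        want_input = TRUE, store_chain = TRUE)
  g <- bw$dx                            # H x W x 3 x N
  gm <- matrix(g, ncol = N)
  norms <- sqrt(colSums(gm * gm))
  penalty <- mean((norms - 1)^2)
  if (!want_grads) return(list(penalty = penalty, grad_norms = norms))
  # v = d penalty / d g  (per sample; zero-norm gradient contributes 0)
  coef <- ifelse(norms > 1e-12, 2 * (norms - 1) / norms / N, 0)
  v <- array(sweep(gm, 2, coef, "*"), dim(g))
  grads <- list()
  pcur <- v
  for (l in seq_len(L)) {
    # site: delta_{h_{l-1}} = conv_bwd_input(delta_{a_l}, W_l)
    dw <- conv_bwd(pcur, p[[paste0("c", l, "_w")]], bw$chain[[l]],
                   want_dx = FALSE, want_dw = TRUE)$dw
    grads <- acc_grad(grads, paste0("c", l, "_w"), dw)
    t <- conv_fwd(pcur, p[[paste0("c", l, "_w")]],
                  numeric(dim(p[[paste0("c", l, "_w")]])[4]))
    pcur <- t * fwd$cache$masks[[l]]
  }
  grads$dense_w <- as.numeric(matrix(pcur, ncol = N) %*% rep(1, N))
  list(penalty = penalty, grad_norms = norms, grads = grads)
}

#' Count trainable parameters
#'
#' @param net a list with a `params` element (generator or critic).
#' @return integer total.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}
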