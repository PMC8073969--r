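# Shared fixtures: tiny architectures and phantoms sized for fast tests.

tiny_spec <- function(sa_variant = "none", canvas = c(16L, 16L), depth = 2L,
                      base_channels = 4L, critic_depth = 3L, ...) {
  model_spec(sa_variant = sa_variant, base_channels = base_channels,
             depth = depth, canvas = canvas, critic_depth = critic_depth,
             ...)
}

tiny_phantom <- function(n_slices = 12L, canvas = c(32L, 32L), seed = 1L,
                         ...) {
  make_healthy_scan(phantom_config(n_slices = n_slices, canvas = canvas,
                                   seed = seed, ...))
}

# independent loop-based accumulation oracles for the pixel losses
l1_oracle <- function(x, y) {
  acc <- 0
  for (i in seq_along(x)) acc <- acc + abs(x[i] - y[i])
  acc
}

l2_oracle <- function(x, y) {
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  acc
}

# brute-force pairwise concordance AUC (ties half-credited)
auc_oracle <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# 4-neighbour connected-component labelling (oracle for lesion counting)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask))
          next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- cur
        stack <- c(stack, list(p + c(1L, 0L)), list(p - c(1L, 0L)),
                   list(p + c(0L, 1L)), list(p - c(0L, 1L)))
      }
    }
  }
  lab
}

# exhaustive best contiguous-window mean
top_window_oracle <- function(v, w) {
  best <- -Inf; best_j <- NA_integer_
  for (j in seq_len(length(v) - w + 1)) {
    m <- mean(v[j:(j + w - 1)])
    if (m > best) { best <- m; best_j <- j }
  }
  list(mean = best, start = best_j)
}
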