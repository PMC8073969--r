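test_that("self-attention is the identity at gamma = 0", {
  set.seed(1)
  x <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  p <- self_attention_params(8L, ratio = 8L)
  expect_identical(p$gamma, 0)
  expect_equal(self_attention_forward(x, p), x, tolerance = 1e-14)
})

test_that("attention rows are a probability distribution over positions", {
  set.seed(2)
  x <- array(rnorm(3 * 3 * 8), c(3, 3, 8, 1))
  p <- self_attention_params(8L)
  p$gamma <- 0.5
  fwd <- self_attention_forward(x, p, cache = TRUE)
  A <- fwd$caches[[1]]$A
  expect_identical(dim(A), c(9L, 9L))
  expect_equal(rowSums(A), rep(1, 9), tolerance = 1e-6)
  expect_true(all(A >= 0))
})

test_that("a 4-position instance matches a dense-matrix oracle", {
  # 1 channel, 2x2 grid, unit projections: out = X + gamma * A X with
  # A = softmax_rows(X X^T), computed densely by hand
  x <- array(c(0.2, -0.4, 1.1, 0.6), c(2, 2, 1, 1))
  p <- list(wq = matrix(1), wk = matrix(1), wv = matrix(1), wo = matrix(1),
            gamma = 0.9)
  X <- matrix(as.numeric(x), 4, 1)
  S <- X %*% t(X)
  A <- exp(S) / rowSums(exp(S))
  expected <- array(X + 0.9 * (A %*% X), c(2, 2, 1, 1))
  got <- self_attention_forward(x, p)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("attention requires enough channels for the reduction ratio", {
  expect_error(self_attention_params(4L, ratio = 8L),
               class = "madgan_config_error")
  x <- array(rnorm(2 * 2 * 8), c(2, 2, 8, 1))
  p <- self_attention_params(8L)
  expect_error(self_attention_forward(array(rnorm(2 * 2 * 16), c(2, 2, 16, 1)), p),
               class = "madgan_config_error")
})

test_that("generator preserves shape, range and eval determinism", {
  set.seed(3)
  spec <- tiny_spec("sa3", canvas = c(16L, 16L), depth = 2L, base_channels = 8L)
  gen <- init_generator(spec)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y1 <- generator_forward(gen, x, spec)
  expect_identical(dim(y1), dim(x))
  expect_true(all(y1 >= 0 & y1 <= 1))
  expect_identical(y1, generator_forward(gen, x, spec))
  # single triplet promoted to batch of one
  y3 <- generator_forward(gen, x[, , , 1], spec)
  expect_identical(dim(y3), c(16L, 16L, 3L, 1L))
  # indivisible dims rejected with the axis named
  expect_error(generator_forward(gen, array(0.5, c(15, 16, 3, 1)), spec),
               "rows", class = "madgan_config_error")
})

test_that("an all-zero generator maps any input to a constant output", {
  spec <- tiny_spec(canvas = c(16L, 16L), depth = 2L)
  gen <- init_generator(spec)
  gen$params <- lapply(gen$params, function(p) p * 0)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y <- generator_forward(gen, x, spec)
  expect_identical(length(unique(as.numeric(y))), 1L)
})

test_that("attention insertion changes no tensor shapes", {
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  for (v in c("none", "sa3")) {
    spec <- tiny_spec(v, canvas = c(16L, 16L), depth = 2L, base_channels = 8L)
    set.seed(4)
    gen <- init_generator(spec)
    expect_identical(dim(generator_forward(gen, x, spec)), dim(x))
  }
})

test_that("parameter counts order the attention variants", {
  specs <- lapply(c("none", "sa3", "sa7"), function(v)
    model_spec(v, base_channels = 8L, depth = 4L, canvas = c(32L, 32L),
               critic_depth = 3L))
  counts <- vapply(specs, function(s) n_parameters(init_generator(s)),
                   numeric(1))
  expect_true(counts[3] > counts[2])
  expect_true(counts[2] > counts[1])
  expect_identical(length(specs[[3]]$sa_sites), 7L)
  expect_identical(length(specs[[2]]$sa_sites), 3L)
})

test_that("critic returns one finite unbounded score per input", {
  set.seed(5)
  spec <- tiny_spec(canvas = c(16L, 16L))
  crit <- init_critic(spec)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  s <- critic_forward(crit, x, spec)
  expect_length(s, 4L)
  expect_true(all(is.finite(s)))
  # response to intensity scaling is continuous (no saturating activation)
  base <- array(0.25, c(16, 16, 3, 1))
  s1 <- critic_forward(crit, base, spec)
  s2 <- critic_forward(crit, 2 * base, spec)
  s3 <- critic_forward(crit, 2.01 * base, spec)
  expect_gt(abs(s2 - s1), 0)
  expect_lt(abs(s3 - s2), abs(s2 - s1))
})

test_that("generator backward matches finite differences on spot checks", {
  set.seed(6)
  spec <- tiny_spec("sa3", canvas = c(16L, 16L), depth = 2L, base_channels = 8L)
  spec$dropout_rate <- 0
  gen <- init_generator(spec)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  fw <- generator_forward(gen, x, spec, train = TRUE, keep_cache = TRUE)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  gr <- madgan:::generator_backward(gen, spec, fw, dy)
  for (nm in c("enc1_w", "dec1_w", "sa_mid_gamma")) {
    p0 <- gen$params[[nm]]
    idx <- seq_len(min(length(p0), 6L))
    fd <- vapply(idx, function(i) {
      h <- 1e-6
      gp <- gen; gp$params[[nm]][i] <- p0[i] + h
      gm <- gen; gm$params[[nm]][i] <- p0[i] - h
      (sum(generator_forward(gp, x, spec, train = TRUE,
                             keep_cache = TRUE)$y * dy) -
       sum(generator_forward(gm, x, spec, train = TRUE,
                             keep_cache = TRUE)$y * dy)) / (2 * h)
    }, numeric(1))
    expect_equal(as.numeric(gr[[nm]])[idx], fd, tolerance = 1e-4)
  }
})
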