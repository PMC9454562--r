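test_that("generator output shape equals input shape for valid (N, S)", {
  for (N in c(1L, 2L, 3L)) {
    S <- max(8L, as.integer(2^N))  # small but divisible sizes
    set.seed(N)
    G <- build_generator(generator_config(N = N, base_channels = 2L), S)
    out <- apply_generator(G, array(runif(S^3, -1, 1), c(S, S, S)))
    expect_identical(dim(out), rep(S, 3L))
    expect_true(all(out >= -1 & out <= 1))
  }
})

test_that("invalid generator geometry is rejected with a configuration error", {
  expect_error(build_generator(generator_config(N = 5L, base_channels = 2L),
                               48L), class = "ec_config_error")
  expect_error(build_generator(generator_config(N = 3L, base_channels = 2L),
                               20L), class = "ec_config_error")
  G <- build_generator(generator_config(N = 3L, base_channels = 2L), 32L)
  expect_error(apply_generator(G, array(0, c(20, 20, 20))),
               class = "ec_contract_error")
})

test_that("discriminator patch grid matches the layer-arithmetic oracle", {
  # oracle: walk the layer stack (three stride-2 k4 p1 convs, two stride-1)
  oracle <- function(S) {
    n <- S
    for (i in 1:3) n <- (n + 2L - 4L) %/% 2L + 1L
    for (i in 1:2) n <- (n + 2L - 4L) + 1L
    n
  }
  for (S in c(32L, 48L)) {
    set.seed(S)
    D <- build_discriminator(S, base_channels = 2L)
    sc <- discriminator_scores(D, array(runif(S^3, -1, 1), c(S, S, S)),
                               array(runif(S^3, -1, 1), c(S, S, S)))
    expect_identical(dim(sc), rep(oracle(S), 3))
    expect_identical(patch_grid_size(S), oracle(S))
    expect_true(all(sc > 0 & sc < 1))
  }
  expect_identical(patch_grid_size(128L), 14L)
  expect_error(build_discriminator(8L), class = "ec_config_error")
  expect_error(build_discriminator(16L), class = "ec_config_error")
})

test_that("adversarial and L1 losses match closed forms and brute force", {
  expect_equal(adversarial_loss(rep(0.5, 8), rep(0.5, 8)), 2 * log(0.5))
  # optimum approaches zero from below
  expect_lt(adversarial_loss(rep(1 - 1e-9, 8), rep(1e-9, 8)), 0)
  expect_gt(adversarial_loss(rep(1 - 1e-9, 8), rep(1e-9, 8)), -1e-6)
  expect_error(adversarial_loss(c(0.5, 1.4), c(0.5)),
               class = "ec_contract_error")

  expect_equal(l1_loss(array(1, c(3, 3, 3)), array(1, c(3, 3, 3))), 0)
  expect_equal(l1_loss(array(0.3, c(3, 3, 3)), array(0.4, c(3, 3, 3))), 0.1)
  expect_error(l1_loss(array(0, c(2, 2, 2)), array(0, c(3, 3, 3))),
               class = "ec_contract_error")

  set.seed(21)
  for (rep in 1:25) {
    r <- runif(8, 0.01, 0.99); f <- runif(8, 0.01, 0.99)
    expect_equal(adversarial_loss(r, f), brute_adv(r, f), tolerance = 1e-9)
    y <- array(runif(27, -1, 1), c(3, 3, 3))
    g <- array(runif(27, -1, 1), c(3, 3, 3))
    expect_equal(l1_loss(y, g), brute_l1(y, g), tolerance = 1e-9)
  }
})

test_that("the generator objective combines its terms linearly", {
  expect_equal(generator_objective(0.7, 0.3, loss_config(0)), 0.7)
  expect_equal(generator_objective(0, 0.02, loss_config(100)), 2.0)
  base <- generator_objective(0.5, 0.25, loss_config(10))
  doubled <- generator_objective(0.5, 0.25, loss_config(20))
  expect_equal(doubled - base, 10 * 0.25)
})

test_that("backpropagation matches finite differences", {
  # generator
  set.seed(31)
  G <- build_generator(generator_config(N = 2L, base_channels = 2L), 8L)
  dims <- c(8L, 8L, 8L)
  xv <- matrix(rnorm(512, 0, 0.5), 1)
  yv <- matrix(rnorm(512, 0, 0.5), 1)
  loss_g <- function(params) {
    out <- ecgan:::g_forward(ecgan:::set_params(G, params), xv, dims)$out
    mean(abs(out - yv)) + 0.5 * mean(out^2)
  }
  gf <- ecgan:::g_forward(G, xv, dims, keep = TRUE)
  dout <- sign(gf$out - yv) / length(gf$out) + gf$out / length(gf$out)
  ana <- ecgan:::g_backward(G, gf$cache, dout)$grads
  p0 <- ecgan:::get_params(G)
  for (key in names(p0)) {
    ii <- sample(length(p0[[key]]), 1)
    eps <- 1e-6
    p0[[key]][ii] <- p0[[key]][ii] + eps; lp <- loss_g(p0)
    p0[[key]][ii] <- p0[[key]][ii] - 2 * eps; lm <- loss_g(p0)
    p0[[key]][ii] <- p0[[key]][ii] + eps
    expect_equal(ana[[key]][ii], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
  # discriminator, including the input gradient used by the generator step
  set.seed(32)
  D <- build_discriminator(24L, base_channels = 2L)
  ddims <- c(24L, 24L, 24L)
  x2 <- matrix(rnorm(2 * prod(ddims), 0, 0.5), 2)
  loss_d <- function(params) {
    out <- ecgan:::d_forward(ecgan:::set_params(D, params), x2, ddims)$out
    -mean(log(pmin(pmax(out, 1e-12), 1 - 1e-12)))
  }
  df <- ecgan:::d_forward(D, x2, ddims, keep = TRUE)
  ds <- -(1 / length(df$out)) / pmin(pmax(df$out, 1e-12), 1 - 1e-12)
  ana_d <- ecgan:::d_backward(D, df$cache, ds)
  pd <- ecgan:::get_params(D)
  for (key in names(pd)) {
    ii <- sample(length(pd[[key]]), 1)
    eps <- 1e-6
    pd[[key]][ii] <- pd[[key]][ii] + eps; lp <- loss_d(pd)
    pd[[key]][ii] <- pd[[key]][ii] - 2 * eps; lm <- loss_d(pd)
    pd[[key]][ii] <- pd[[key]][ii] + eps
    expect_equal(ana_d$grads[[key]][ii], (lp - lm) / (2 * eps),
                 tolerance = 1e-4)
  }
  for (ii in sample(length(x2), 5)) {
    eps <- 1e-6; v <- x2
    v[ii] <- v[ii] + eps
    lp <- -mean(log(pmin(pmax(ecgan:::d_forward(D, v, ddims)$out, 1e-12),
                         1 - 1e-12)))
    v[ii] <- v[ii] - 2 * eps
    lm <- -mean(log(pmin(pmax(ecgan:::d_forward(D, v, ddims)$out, 1e-12),
                         1 - 1e-12)))
    expect_equal(ana_d$dx[ii], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("training is deterministic, skippable and reduces reconstruction error", {
  nets <- tiny_gan(32L, base = 2L)
  pairs <- list(rand_pair(32L, seed = 41))
  lcfg <- loss_config(100)

  # epochs = 0 leaves the networks untouched
  res0 <- train_gan(pairs, nets$G, nets$D,
                    train_config(epochs = 0L, seed = 1L), lcfg)
  expect_identical(bytes_of(res0$G), bytes_of(nets$G))
  expect_identical(bytes_of(res0$D), bytes_of(nets$D))
  expect_identical(nrow(res0$history), 0L)
  expect_error(train_gan(list(), nets$G, nets$D,
                         train_config(epochs = 1L), lcfg),
               class = "ec_validation_error")

  # a self-pair is learnable: final L1 under the initial one
  p <- pairs[[1]]; p$y <- p$x
  tcfg <- train_config(epochs = 50L, batch_size = 1L, learning_rate = 2e-4,
                       seed = 2L)
  res <- train_gan(list(p), nets$G, nets$D, tcfg, lcfg)
  expect_lt(res$history$g_l1[50], res$history$g_l1[1])
  expect_lt(res$history$g_l1[50],
            l1_loss(p$y$values, apply_generator(nets$G, p$x)$values))

  # bit-identical repetition under the same seed
  res2 <- train_gan(list(p), nets$G, nets$D, tcfg, lcfg)
  expect_identical(res$history, res2$history)
  expect_identical(bytes_of(ecgan:::get_params(res$G)),
                   bytes_of(ecgan:::get_params(res2$G)))

  # inference is deterministic with fixed weights
  o1 <- apply_generator(res$G, p$x)
  o2 <- apply_generator(res$G, p$x)
  expect_identical(o1$values, o2$values)
})
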