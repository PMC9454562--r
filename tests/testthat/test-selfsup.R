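# Loop-semantics tests run with epochs = 0 (no parameter updates), so they
# exercise the bookkeeping of the feedback loop itself at negligible cost.

zero_train <- function(seed = 1L) train_config(epochs = 0L, seed = seed)

make_fixed_set <- function(n, S = 24L, seed = 50L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) rand_pair(S, "fixed"))
}

test_that("pretrain validates provenance and records the fixed set", {
  fixed <- make_fixed_set(6)
  gcfg <- generator_config(N = 2L, base_channels = 2L)
  st <- pretrain(fixed, gcfg, zero_train(), loss_config())
  expect_identical(st$iteration, 0L)
  expect_length(st$fixed_pairs, 6)
  expect_length(st$dynamic_pairs, 0)
  dyn <- list(ecgan:::voi_pair(rand_voi(24), rand_voi(24), "dynamic"))
  expect_error(pretrain(c(fixed, dyn), gcfg, zero_train(), loss_config()),
               class = "ec_validation_error")
  # same seed twice -> identical states
  st2 <- pretrain(fixed, gcfg, zero_train(), loss_config())
  expect_identical(bytes_of(st), bytes_of(st2))
})

test_that("each iteration regenerates dynamic targets with the current generator", {
  fixed <- make_fixed_set(4)
  gcfg <- generator_config(N = 2L, base_channels = 2L)
  st <- pretrain(fixed, gcfg, zero_train(), loss_config())
  uncleansed <- lapply(1:3, function(i) rand_voi(24, seed = 60 + i))
  st <- seed_dynamic_pairs(st, uncleansed, "threshold")
  fixed_before <- bytes_of(st$fixed_pairs)
  cfg <- selfsup_config(iterations = 3L, per_iteration_train = zero_train())
  for (k in 1:3) {
    st <- selfsup_iteration(st, cfg)
    expect_identical(st$iteration, k)
    for (p in st$dynamic_pairs)
      expect_identical(p$y$values, apply_generator(st$G, p$x)$values)
  }
  # fixed pairs byte-identical throughout
  expect_identical(bytes_of(st$fixed_pairs), fixed_before)
  # per-iteration training set = fixed + dynamic
  expect_identical(st$last_train_size, 7L)
})

test_that("an identity generator makes dynamic pairs a fixed point", {
  fixed <- make_fixed_set(2)
  st <- pretrain(fixed, generator_config(N = 2L, base_channels = 2L),
                 zero_train(), loss_config())
  st$G <- fn_generator(identity)
  st <- seed_dynamic_pairs(st, lapply(1:2, function(i) rand_voi(24, i)),
                           "identity")
  cfg <- selfsup_config(iterations = 2L, per_iteration_train = zero_train())
  st <- selfsup_iteration(st, cfg)
  for (p in st$dynamic_pairs) expect_identical(p$y$values, p$x$values)
  before <- bytes_of(st$dynamic_pairs)
  st <- selfsup_iteration(st, cfg)
  expect_identical(bytes_of(st$dynamic_pairs), before)
})

test_that("iterating without seeded dynamic pairs is an error", {
  st <- pretrain(make_fixed_set(2),
                 generator_config(N = 2L, base_channels = 2L),
                 zero_train(), loss_config())
  expect_error(selfsup_iteration(st, selfsup_config(
    per_iteration_train = zero_train())), class = "ec_validation_error")
})

test_that("zero iterations reproduce pre-training bit-exactly", {
  fixed <- make_fixed_set(4, S = 24L)
  gcfg <- generator_config(N = 2L, base_channels = 2L)
  tcfg <- train_config(epochs = 2L, batch_size = 2L, learning_rate = 1e-3,
                       seed = 3L)
  st_pre <- pretrain(fixed, gcfg, tcfg, loss_config())
  st_run <- run_selfsup(fixed, lapply(1:2, function(i) rand_voi(24L, i)),
                        selfsup_config(iterations = 0L,
                                       per_iteration_train = tcfg),
                        gcfg, loss_config())
  expect_identical(bytes_of(ecgan:::get_params(st_pre$G)),
                   bytes_of(ecgan:::get_params(st_run$G)))
  expect_identical(bytes_of(ecgan:::get_params(st_pre$D)),
                   bytes_of(ecgan:::get_params(st_run$D)))
})

test_that("run_selfsup records one PSNR report per stage", {
  fixed <- make_fixed_set(4, S = 24L)
  gcfg <- generator_config(N = 2L, base_channels = 2L)
  eval_pairs <- lapply(1:2, function(i) {
    set.seed(70 + i)
    ecgan:::voi_pair(rand_voi(24L), rand_voi(24L), "fixed")
  })
  st <- run_selfsup(fixed, lapply(1:2, function(i) rand_voi(24L, 80 + i)),
                    selfsup_config(iterations = 2L,
                                   per_iteration_train = zero_train()),
                    gcfg, loss_config(), eval_pairs = eval_pairs)
  expect_length(st$psnr_history, 3)
  curve <- iteration_curve(st$psnr_history)
  expect_identical(curve$iteration, 0:2)
})

test_that("tiled whole-volume inference blends consistently", {
  # a generator mock that returns constant 1 proves the blend weights sum to 1
  ones <- fn_generator(function(a) array(1, dim = dim(a)))
  set.seed(90)
  nv <- normalized_volume(array(runif(40 * 24 * 24, -1, 1), c(40, 24, 24)))
  out <- apply_full_volume(ones, nv, tile_S = 16L, overlap = 8L)
  expect_true(all(abs(out$values - 1) < 1e-12))

  # identity mock: tiling must not alter the volume
  idout <- apply_full_volume(fn_generator(identity), nv, tile_S = 16L,
                             overlap = 8L)
  expect_equal(idout$values, nv$values, tolerance = 1e-12)

  # an exactly tile-sized volume with no overlap equals direct application
  nets <- tiny_gan(32L, base = 2L)
  cube <- normalized_volume(array(runif(32^3, -1, 1), c(32, 32, 32)))
  tiled <- apply_full_volume(nets$G, cube, tile_S = 32L, overlap = 0L)
  direct <- apply_generator(nets$G, cube$values)
  expect_equal(tiled$values, direct, tolerance = 1e-12)

  # volumes smaller than the tile are padded and cropped back
  small <- normalized_volume(array(runif(10 * 24 * 24, -1, 1), c(10, 24, 24)))
  sm_out <- apply_full_volume(fn_generator(identity), small, tile_S = 16L,
                              overlap = 4L)
  expect_identical(dim(sm_out$values), dim(small$values))
  expect_equal(sm_out$values, small$values, tolerance = 1e-12)
  expect_error(apply_full_volume(ones, nv, tile_S = 16L, overlap = 16L),
               class = "ec_validation_error")
})
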