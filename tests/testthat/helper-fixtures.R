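# Shared fixtures: everything is generated in code at test time.

rand_voi <- function(S, seed = NULL, lo = -1, hi = 1) {
  if (!is.null(seed)) set.seed(seed)
  voi(array(runif(S^3, lo, hi), dim = c(S, S, S)))
}

rand_pair <- function(S, provenance = "fixed", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- voi(array(runif(S^3, -1, 1), dim = c(S, S, S)),
           center = c(1L, 1L, 1L))
  y <- voi(array(runif(S^3, -1, 1), dim = c(S, S, S)),
           center = c(1L, 1L, 1L))
  ecgan:::voi_pair(x, y, provenance)
}

# a small, fast phantom spec used across tests
test_phantom_spec <- function(...) {
  args <- list(grid_shape = c(48L, 24L, 24L), spacing = c(1, 1, 1),
               lumen_radius = 5, wall_thickness = 1.5, fold_amplitude = 0.8,
               blur_fwhm = 0, noise_sigma = 0, seed = 11L)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

tiny_gan <- function(S = 32L, base = 2L, seed = 5L) {
  set.seed(seed)
  list(G = build_generator(generator_config(N = 3L, base_channels = base,
                                            dropout_rate = 0), S),
       D = build_discriminator(S, base_channels = base))
}

# ---- independent brute-force oracles (never reuse package internals) ----

brute_mse <- function(I, J) {
  d <- dim(I)
  acc <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    acc <- acc + (I[i, j, k] - J[i, j, k])^2
  acc / prod(d)
}

brute_psnr <- function(I, J, max_hu = 1024) {
  m <- brute_mse(I, J)
  10 * log10(max_hu^2 / m)
}

brute_l1 <- function(y, g) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + abs(y[i] - g[i])
  acc / length(y)
}

brute_adv <- function(r, f) {
  sr <- 0
  for (i in seq_along(r)) sr <- sr + log(r[i])
  sf <- 0
  for (i in seq_along(f)) sf <- sf + log(1 - f[i])
  sr / length(r) + sf / length(f)
}

bytes_of <- function(x) serialize(x, NULL)
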