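#' Generator configuration
#'
#' Architecture knobs of the 3D U-Net generator: `N` down/upsampling stages
#' (each a stride-2 kernel-4 padding-1 convolution or transposed
#' convolution, so the input size `S` must be divisible by `2^N`),
#' `base_channels` feature maps at the first stage doubling per stage and
#' capped at `8 * base_channels`, encoder-to-decoder skip connections, and
#' optional decoder dropout. Instance normalisation is applied in every
#' block except the first encoder and last decoder block.
#'
#' @param N number of downsampling (and upsampling) stages, >= 1.
#' @param base_channels feature maps at the first stage, >= 1.
#' @param kernel_size convolution kernel edge, voxels.
#' @param use_skip_connections concatenate encoder features into the
#'   decoder (U-Net style)?
#' @param dropout_rate dropout fraction in the innermost decoder blocks
#'   during training (0 disables).
#' @return an object of class `ec_generator_config`.
#' @export
generator_config <- function(N = 5L, base_channels = 64L, kernel_size = 4L,
                             use_skip_connections = TRUE,
                             dropout_rate = 0) {
  assert_that(N >= 1, "N must be >= 1")
  assert_that(base_channels >= 1, "base_channels must be >= 1")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must lie in [0, 1)")
  structure(list(N = as.integer(N), base_channels = as.integer(base_channels),
                 kernel_size = as.integer(kernel_size),
                 use_skip_connections = isTRUE(use_skip_connections),
                 dropout_rate = dropout_rate),
            class = "ec_generator_config")
}

#' Build the 3D U-Net generator
#'
#' Constructs the generator G that translates an uncleansed S^3 normalized
#' volume into its virtually cleansed counterpart: N strided-convolution
#' encoder stages (LeakyReLU 0.2), N transposed-convolution decoder stages
#' (ReLU), encoder-to-decoder skip connections, and a final tanh squashing
#' to `[-1, 1]`. Output shape always equals input shape. Weights are drawn
#' from the current R RNG state (N(0, 0.02)); seed the RNG for reproducible
#' initialisation.
#'
#' @param cfg a [generator_config()].
#' @param S input edge length in voxels; must satisfy `S %% 2^N == 0` with
#'   `S / 2^N >= 1`.
#' @return an object of class `ec_generator`.
#' @export
build_generator <- function(cfg, S) {
  assert_that(inherits(cfg, "ec_generator_config"), "cfg must be a generator_config")
  N <- cfg$N
  if (S %% 2^N != 0 || S %/% 2^N < 1)
    stop_ec("input size S = %d is not divisible by 2^N = %d (N = %d)",
            S, 2^N, N, class = "ec_config_error")
  ch <- cfg$base_channels * pmin(2^(0:(N - 1)), 8)
  k <- cfg$kernel_size
  enc <- vector("list", N)
  cin <- 1L
  for (i in seq_len(N)) {
    enc[[i]] <- conv_layer_init(cin, ch[i], k = k, stride = 2L, pad = 1L,
                                norm = i > 1)
    cin <- ch[i]
  }
  dec <- vector("list", N)
  for (j in seq_len(N)) {
    skip_ch <- if (j == 1 || !cfg$use_skip_connections) 0L else ch[N - j + 1]
    din <- (if (j == 1) ch[N] else ch[N - j + 1]) + skip_ch
    dout <- if (j < N) ch[N - j] else 1L
    dec[[j]] <- convt_layer_init(din, dout, k = k, stride = 2L, pad = 1L,
                                 norm = j < N)
    # pix2pix applies dropout in the innermost decoder blocks
    dec[[j]]$dropout <- if (j <= min(3L, N - 1L)) cfg$dropout_rate else 0
  }
  structure(list(config = cfg, S = as.integer(S), enc = enc, dec = dec),
            class = "ec_generator")
}

#' @export
print.ec_generator <- function(x, ...) {
  np <- sum(vapply(get_params(x), length, integer(1)))
  cat(sprintf("<3D U-Net generator> N = %d, S = %d, base %d channels, %d parameters\n",
              x$config$N, x$S, x$config$base_channels, np))
  invisible(x)
}

# forward pass on one sample; x is a 1 x S^3 matrix
g_forward <- function(G, x, dims, train = FALSE, keep = FALSE) {
  N <- G$config$N
  skips <- vector("list", N)
  sdims <- vector("list", N)
  cache <- if (keep) list(enc = vector("list", N),
                          dec = vector("list", N)) else NULL
  h <- x; hd <- dims
  for (i in seq_len(N)) {
    l <- G$enc[[i]]
    cf <- conv_fwd(l, h, hd, keep = keep)
    z <- cf$y
    if (l$norm) {
      nf <- inorm_fwd(l$gamma, l$beta, z)
      a_in <- nf$y
    } else {
      nf <- NULL
      a_in <- z
    }
    a <- lrelu_fwd(a_in, 0.2)
    if (keep)
      cache$enc[[i]] <- list(col = cf$col, xdims = hd, nf = nf, a_in = a_in)
    skips[[i]] <- a
    sdims[[i]] <- cf$odims
    h <- a; hd <- cf$odims
  }
  out <- NULL
  for (j in seq_len(N)) {
    l <- G$dec[[j]]
    if (j == 1 || !G$config$use_skip_connections) {
      inp <- h
    } else {
      inp <- rbind(h, skips[[N - j + 1]])
    }
    tf <- convt_fwd(l, inp, hd)
    z <- tf$y
    if (j < N) {
      nf <- inorm_fwd(l$gamma, l$beta, z)
      a <- nf$y
      drop_mask <- NULL
      if (train && l$dropout > 0) {
        drop_mask <- matrix((runif(length(a)) >= l$dropout) /
                              (1 - l$dropout), nrow = nrow(a))
        a <- a * drop_mask
      }
      h_new <- relu_fwd(a)
      if (keep)
        cache$dec[[j]] <- list(x = inp, xdims = hd, odims = tf$odims,
                               nf = nf, a = a, drop_mask = drop_mask)
      h <- h_new; hd <- tf$odims
    } else {
      out <- tanh(z)
      if (keep)
        cache$dec[[j]] <- list(x = inp, xdims = hd, odims = tf$odims,
                               out = out)
      hd <- tf$odims
    }
  }
  list(out = out, odims = hd, cache = cache)
}

# backward pass; dout matches the generator output (1 x S^3)
g_backward <- function(G, cache, dout) {
  N <- G$config$N
  grads <- list()
  dskips <- vector("list", N)
  dh <- NULL
  for (j in rev(seq_len(N))) {
    l <- G$dec[[j]]
    cc <- cache$dec[[j]]
    if (j == N) {
      dz <- tanh_bwd(cc$out, dout)
    } else {
      da <- relu_bwd(cc$a, dh)
      if (!is.null(cc$drop_mask)) da <- da * cc$drop_mask
      nb <- inorm_bwd(l$gamma, cc$nf$xhat, cc$nf$inv, da)
      grads[[sprintf("l%02d.gamma", N + j)]] <- nb$dgamma
      grads[[sprintf("l%02d.beta", N + j)]] <- nb$dbeta
      dz <- nb$dx
    }
    tb <- convt_bwd(l, cc$x, cc$xdims, dz, cc$odims)
    grads[[sprintf("l%02d.W", N + j)]] <- tb$dW
    grads[[sprintf("l%02d.b", N + j)]] <- tb$db
    dinp <- tb$dx
    if (j == 1 || !G$config$use_skip_connections) {
      dh <- dinp
      if (j == 1) dskips[[N]] <- acc_mat(dskips[[N]], dinp)
    } else {
      top <- G$dec[[j]]$cin - G$enc[[N - j + 1]]$cout
      dh <- dinp[seq_len(top), , drop = FALSE]
      dskips[[N - j + 1]] <- acc_mat(dskips[[N - j + 1]],
                                     dinp[-seq_len(top), , drop = FALSE])
    }
  }
  # note: when skips are enabled, the j == 1 decoder input is skips[[N]]
  # itself (dh above), already accumulated via dskips[[N]]
  da_next <- NULL
  for (i in rev(seq_len(N))) {
    l <- G$enc[[i]]
    cc <- cache$enc[[i]]
    da <- dskips[[i]] %||% 0
    if (!is.null(da_next)) da <- da + da_next
    dz_in <- lrelu_bwd(cc$a_in, da, 0.2)
    if (l$norm) {
      nb <- inorm_bwd(l$gamma, cc$nf$xhat, cc$nf$inv, dz_in)
      grads[[sprintf("l%02d.gamma", i)]] <- nb$dgamma
      grads[[sprintf("l%02d.beta", i)]] <- nb$dbeta
      dz <- nb$dx
    } else dz <- dz_in
    cb <- conv_bwd(l, cc$col, cc$xdims, dz)
    grads[[sprintf("l%02d.W", i)]] <- cb$dW
    grads[[sprintf("l%02d.b", i)]] <- cb$db
    da_next <- cb$dx
  }
  list(grads = grads, dx = da_next)
}

acc_mat <- function(a, b) if (is.null(a)) b else a + b

#' Apply the generator to a volume of interest
#'
#' Runs G in inference mode (no dropout, no parameter updates); repeated
#' application with fixed weights is bitwise deterministic. Accepts and
#' returns either a [voi()] or a bare 3D array; output values lie in
#' `[-1, 1]`.
#'
#' `apply_generator` is generic so that lightweight mock generators (see
#' [fn_generator()]) can stand in for a trained network in tests and in the
#' self-supervised loop.
#'
#' @param G a generator (from [build_generator()] or [fn_generator()]).
#' @param x a [voi()] or 3D array of normalized values.
#' @return same type as `x`.
#' @export
apply_generator <- function(G, x) UseMethod("apply_generator")

#' @export
apply_generator.ec_generator <- function(G, x) {
  vals <- if (inherits(x, "ec_voi")) x$values else x
  d <- dim(vals)
  assert_that(length(d) == 3 && all(d %% 2^G$config$N == 0),
              "input shape (%s) is incompatible with the generator (N = %d)",
              paste(d, collapse = "x"), G$config$N,
              class = "ec_contract_error")
  res <- g_forward(G, matrix(as.numeric(vals), nrow = 1), d,
                   train = FALSE, keep = FALSE)
  out <- array(res$out[1, ], dim = d)
  if (inherits(x, "ec_voi"))
    voi(out, center = x$center, source_id = x$source_id)
  else out
}

#' Wrap a plain function as a generator
#'
#' Creates a mock generator from any array-to-array function, useful for
#' testing loop semantics (e.g. `fn_generator(identity)`) and tiled
#' inference without training a network.
#'
#' @param f function mapping a 3D array to a 3D array of the same shape.
#' @return an object of class `ec_fn_generator`.
#' @export
fn_generator <- function(f) {
  structure(list(f = f), class = "ec_fn_generator")
}

#' @export
apply_generator.ec_fn_generator <- function(G, x) {
  vals <- if (inherits(x, "ec_voi")) x$values else x
  out <- G$f(vals)
  assert_that(identical(dim(out), dim(vals)),
              "mock generator changed the array shape",
              class = "ec_contract_error")
  if (inherits(x, "ec_voi"))
    voi(out, center = x$center, source_id = x$source_id)
  else out
}
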