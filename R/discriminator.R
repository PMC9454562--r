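#' Build the 3D PatchGAN discriminator
#'
#' Constructs the discriminator D that scores local patches of a candidate
#' cleansing: it takes the 2-channel concatenation of the uncleansed volume
#' x and a candidate EC volume (the registered truth y for a "real pair",
#' or G(x) for a "fake pair") and emits a 3D grid of per-patch
#' probabilities in (0, 1). The stack is three stride-2 kernel-4
#' convolutions, two stride-1 kernel-4 convolutions, and a sigmoid; with
#' padding 1 the patch-score grid has side `S/8 - 2`, so `S` must be
#' divisible by 8 and at least 24. LeakyReLU(0.2) activations; instance
#' normalisation in all but the first and last blocks.
#'
#' @param S input edge length in voxels.
#' @param base_channels feature maps of the first block (doubling per
#'   stride-2 block; the classic full-scale setting is 64, the package's
#'   desk-scale experiments use 8).
#' @return an object of class `ec_discriminator`.
#' @export
build_discriminator <- function(S, base_channels = 8L) {
  f <- S / 8 - 2
  if (S %% 8 != 0 || f < 1)
    stop_ec("discriminator input size S = %d unsupported: need S divisible by 8 with S/8 - 2 >= 1",
            S, class = "ec_config_error")
  b <- as.integer(base_channels)
  layers <- list(
    conv_layer_init(2L, b, stride = 2L, norm = FALSE),
    conv_layer_init(b, 2L * b, stride = 2L, norm = TRUE),
    conv_layer_init(2L * b, 4L * b, stride = 2L, norm = TRUE),
    conv_layer_init(4L * b, 8L * b, stride = 1L, pad = 1L, norm = TRUE),
    conv_layer_init(8L * b, 1L, stride = 1L, pad = 1L, norm = FALSE)
  )
  structure(list(S = as.integer(S), base_channels = b, layers = layers),
            class = "ec_discriminator")
}

#' @export
print.ec_discriminator <- function(x, ...) {
  cat(sprintf("<PatchGAN discriminator> S = %d, patch grid %d^3, base %d channels\n",
              x$S, x$S / 8 - 2, x$base_channels))
  invisible(x)
}

#' Discriminator patch-grid side length
#'
#' The spatial side of the patch-score grid for input size `S` under the
#' kernel-4 / padding-1 convention: three stride-2 halvings followed by two
#' stride-1 convolutions each shrinking the side by one, i.e. `S/8 - 2`.
#'
#' @param S input edge length in voxels.
#' @return integer side length.
#' @export
patch_grid_size <- function(S) as.integer(S / 8 - 2)

# forward on one sample; x2 is a 2 x S^3 matrix
d_forward <- function(D, x2, dims, keep = FALSE) {
  h <- x2; hd <- dims
  cache <- if (keep) vector("list", length(D$layers)) else NULL
  for (i in seq_along(D$layers)) {
    l <- D$layers[[i]]
    cf <- conv_fwd(l, h, hd, keep = keep)
    z <- cf$y
    last <- i == length(D$layers)
    if (l$norm) {
      nf <- inorm_fwd(l$gamma, l$beta, z)
      a_in <- nf$y
    } else {
      nf <- NULL
      a_in <- z
    }
    a <- if (last) sigmoid_fwd(a_in) else lrelu_fwd(a_in, 0.2)
    if (keep)
      cache[[i]] <- list(col = cf$col, xdims = hd, nf = nf, a_in = a_in,
                         a = a)
    h <- a; hd <- cf$odims
  }
  list(out = h, odims = hd, cache = cache)
}

# backward; dscore matches the 1 x P^3 output. Returns parameter grads and
# the gradient w.r.t. the 2-channel input (rows 1 = x, 2 = candidate EC).
d_backward <- function(D, cache, dscore) {
  grads <- list()
  dy <- dscore
  for (i in rev(seq_along(D$layers))) {
    l <- D$layers[[i]]
    cc <- cache[[i]]
    last <- i == length(D$layers)
    dz_in <- if (last) sigmoid_bwd(cc$a, dy) else lrelu_bwd(cc$a_in, dy, 0.2)
    if (l$norm) {
      nb <- inorm_bwd(l$gamma, cc$nf$xhat, cc$nf$inv, dz_in)
      grads[[sprintf("l%02d.gamma", i)]] <- nb$dgamma
      grads[[sprintf("l%02d.beta", i)]] <- nb$dbeta
      dz <- nb$dx
    } else dz <- dz_in
    cb <- conv_bwd(l, cc$col, cc$xdims, dz)
    grads[[sprintf("l%02d.W", i)]] <- cb$dW
    grads[[sprintf("l%02d.b", i)]] <- cb$db
    dy <- cb$dx
  }
  list(grads = grads, dx = dy)
}

#' Score a candidate cleansing with the discriminator
#'
#' Convenience inference wrapper: concatenates `x` and the candidate EC
#' volume and returns the 3D patch-score grid, every value strictly in
#' (0, 1).
#'
#' @param D an `ec_discriminator`.
#' @param x,candidate [voi()] objects or 3D arrays of the same shape.
#' @return 3D array of patch scores.
#' @export
discriminator_scores <- function(D, x, candidate) {
  xv <- if (inherits(x, "ec_voi")) x$values else x
  cv <- if (inherits(candidate, "ec_voi")) candidate$values else candidate
  assert_that(identical(dim(xv), dim(cv)), "shape mismatch",
              class = "ec_contract_error")
  res <- d_forward(D, rbind(as.numeric(xv), as.numeric(cv)), dim(xv))
  array(res$out[1, ], dim = res$odims)
}
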