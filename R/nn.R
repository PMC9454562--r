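# Volumetric conv-net engine.
#
# Feature maps are C x V matrices over an (n1,n2,n3) voxel grid (column-major
# voxel linearisation), so convolutions reduce to im2col/col2im (compiled)
# plus BLAS matrix products, and channel concatenation is rbind(). All
# randomness (weight init, dropout, shuffling) goes through the R RNG, so a
# single set.seed() makes training bit-reproducible.

conv_out_dims <- function(dims, k, s, p) (dims + 2 * p - k) %/% s + 1
convt_out_dims <- function(dims, k, s, p) (dims - 1) * s - 2 * p + k

# weight init follows the pix2pix convention: N(0, 0.02) for conv kernels,
# N(1, 0.02) / 0 for the normalisation scale/shift
conv_layer_init <- function(cin, cout, k = 4L, stride = 2L, pad = 1L,
                            norm = FALSE) {
  l <- list(W = matrix(rnorm(cout * cin * k^3, 0, 0.02), nrow = cout),
            b = numeric(cout), k = k, stride = stride, pad = pad,
            cin = cin, cout = cout, norm = norm)
  if (norm) {
    l$gamma <- rnorm(cout, 1, 0.02)
    l$beta <- numeric(cout)
  }
  l
}

convt_layer_init <- function(cin, cout, k = 4L, stride = 2L, pad = 1L,
                             norm = FALSE) {
  l <- list(W = matrix(rnorm(cin * cout * k^3, 0, 0.02), nrow = cin),
            b = numeric(cout), k = k, stride = stride, pad = pad,
            cin = cin, cout = cout, norm = norm)
  if (norm) {
    l$gamma <- rnorm(cout, 1, 0.02)
    l$beta <- numeric(cout)
  }
  l
}

conv_fwd <- function(l, x, dims, keep = FALSE) {
  col <- im2col3(x, as.integer(dims), l$k, l$stride, l$pad)
  y <- l$W %*% col + l$b
  list(y = y, odims = conv_out_dims(dims, l$k, l$stride, l$pad),
       col = if (keep) col else NULL)
}

# `col` is the cached im2col of the forward input
conv_bwd <- function(l, col, dims, dy) {
  dW <- tcrossprod(dy, col)
  db <- rowSums(dy)
  dx <- col2im3(crossprod(l$W, dy), as.integer(dims), l$cin, l$k, l$stride,
                l$pad)
  list(dx = dx, dW = dW, db = db)
}

convt_fwd <- function(l, x, dims) {
  odims <- convt_out_dims(dims, l$k, l$stride, l$pad)
  y <- col2im3(crossprod(l$W, x), as.integer(odims), l$cout, l$k, l$stride,
               l$pad)
  list(y = y + l$b, odims = odims)
}

convt_bwd <- function(l, x, dims, dy, odims) {
  dycol <- im2col3(dy, as.integer(odims), l$k, l$stride, l$pad)
  dx <- l$W %*% dycol
  dW <- tcrossprod(x, dycol)
  db <- rowSums(dy)
  list(dx = dx, dW = dW, db = db)
}

# instance normalisation: per channel over the voxels of one sample
inorm_fwd <- function(gamma, beta, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = gamma * xhat + beta, xhat = xhat, inv = inv)
}

inorm_bwd <- function(gamma, xhat, inv, dy) {
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, alpha = 0.2) pmax(x, 0) + alpha * pmin(x, 0)
lrelu_bwd <- function(x, dy, alpha = 0.2) dy * (alpha + (1 - alpha) * (x > 0))
relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dy) dy * (x > 0)
tanh_bwd <- function(y, dy) dy * (1 - y * y)
sigmoid_fwd <- function(x) 1 / (1 + exp(-clamp(x, -40, 40)))
sigmoid_bwd <- function(y, dy) dy * y * (1 - y)

# ---- flat parameter handling + Adam -----------------------------------

param_names <- c("W", "b", "gamma", "beta")

layers_of <- function(net) {
  if (inherits(net, "ec_generator")) c(net$enc, net$dec) else net$layers
}

get_params <- function(net) {
  out <- list()
  ls <- layers_of(net)
  for (i in seq_along(ls)) {
    for (pn in param_names) {
      if (!is.null(ls[[i]][[pn]]))
        out[[sprintf("l%02d.%s", i, pn)]] <- ls[[i]][[pn]]
    }
  }
  out
}

set_params <- function(net, params) {
  if (inherits(net, "ec_generator")) {
    nenc <- length(net$enc)
    for (i in seq_along(net$enc))
      for (pn in param_names) {
        key <- sprintf("l%02d.%s", i, pn)
        if (!is.null(params[[key]])) net$enc[[i]][[pn]] <- params[[key]]
      }
    for (j in seq_along(net$dec))
      for (pn in param_names) {
        key <- sprintf("l%02d.%s", nenc + j, pn)
        if (!is.null(params[[key]])) net$dec[[j]][[pn]] <- params[[key]]
      }
  } else {
    for (i in seq_along(net$layers))
      for (pn in param_names) {
        key <- sprintf("l%02d.%s", i, pn)
        if (!is.null(params[[key]])) net$layers[[i]][[pn]] <- params[[key]]
      }
  }
  net
}

zero_like <- function(params) lapply(params, function(p) p * 0)

acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (k in names(b)) a[[k]] <- a[[k]] + b[[k]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.5, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}
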