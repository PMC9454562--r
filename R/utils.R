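`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ec <- function(fmt, ..., class) {
  stop(structure(class = c(class, "ec_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assert_that <- function(ok, fmt, ..., class = "ec_validation_error") {
  if (!isTRUE(ok)) stop_ec(fmt, ..., class = class)
  invisible(TRUE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Separable Gaussian smoothing of a 3D array
#'
#' Filters along each axis in turn with a normalised Gaussian kernel
#' (kernel mass renormalised at the array borders, so constants are
#' preserved exactly). `sigma` is given per axis in voxel units; axes with
#' `sigma < 0.05` are left untouched.
#'
#' @param a 3D numeric array.
#' @param sigma length-3 numeric, standard deviation in voxels per axis.
#' @return filtered array of the same dimensions.
#' @keywords internal
gauss_smooth3 <- function(a, sigma) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s < 0.05 || d[ax] < 2) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    kern <- exp(-((-r:r)^2) / (2 * s^2))
    n <- d[ax]
    # dense banded smoothing matrix, rows renormalised at the borders
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      j <- idx + off
      keep <- j >= 1 & j <= n
      K[cbind(idx[keep], j[keep])] <- kern[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, nrow = dp[1])
    ap <- array(m, dp)
    a <- aperm(ap, order(perm))
  }
  a
}

# dilate a logical 3D mask by one voxel (6-connectivity)
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ]      <- out[-1, , ]      | m[-d[1], , ]
  out[-d[1], , ]   <- out[-d[1], , ]   | m[-1, , ]
  out[, -1, ]      <- out[, -1, ]      | m[, -d[2], ]
  out[, -d[2], ]   <- out[, -d[2], ]   | m[, -1, ]
  out[, , -1]      <- out[, , -1]      | m[, , -d[3]]
  out[, , -d[3]]   <- out[, , -d[3]]   | m[, , -1]
  out
}

# erode a logical 3D mask by one voxel (6-connectivity, outside = FALSE)
erode6 <- function(m) !dilate6(!m)

# deterministic small-integer seed derived from a base seed and a stage name;
# a single global seed drives every stage of a run through this
stage_seed <- function(seed, stage) {
  m <- 2147483587
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h + 1)
}
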