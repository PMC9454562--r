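#' Mean squared error between two volumes
#'
#' Sum of squared voxel differences divided by the number of voxels
#' (S^3 for a cubic VOI). Inputs are expected on the HU scale (after
#' [denormalize()]).
#'
#' @param I,J numeric arrays (or [ct_volume()]) of identical shape.
#' @return scalar MSE.
#' @export
mse <- function(I, J) {
  iv <- if (inherits(I, "ct_volume")) I$voxels else I
  jv <- if (inherits(J, "ct_volume")) J$voxels else J
  assert_that(identical(dim(iv) %||% length(iv), dim(jv) %||% length(jv)),
              "mse: shape mismatch", class = "ec_contract_error")
  mean((iv - jv)^2)
}

#' Peak signal-to-noise ratio in HU space
#'
#' `PSNR = 10 * log10(MAX^2 / MSE)` with `MAX = 1024` HU, computed after
#' the volumes have been scaled back from `[-1, 1]` to `[-1024, 1024]`.
#' Identical volumes give `Inf` (a documented sentinel; report code
#' excludes infinite values from means with a logged count).
#'
#' @param I desired EC volume (HU scale).
#' @param J generated volume (HU scale).
#' @param max_hu peak value, default 1024 HU.
#' @return PSNR in dB.
#' @export
psnr <- function(I, J, max_hu = 1024) {
  m <- mse(I, J)
  if (m == 0) return(Inf)
  10 * log10(max_hu^2 / m)
}

#' Evaluate a generator's cleansing quality over VOI pairs
#'
#' For every pair, applies the generator to the uncleansed VOI, scales both
#' the output and the desired EC VOI back to HU, and computes PSNR. Mean
#' and sample standard deviation (n - 1 denominator) are taken over the
#' finite per-VOI values; pairs with zero error (infinite PSNR) are counted
#' separately in `n_infinite`.
#'
#' @param G a generator.
#' @param eval_pairs non-empty list of `ec_voi_pair` (x uncleansed, y
#'   desired).
#' @param label optional condition label (e.g. `list(N = 5, iteration =
#'   3)`) carried into the report.
#' @return an object of class `ec_psnr_report` with fields `per_voi_psnr`,
#'   `mean`, `sd`, `n`, `n_infinite`, `label`.
#' @export
evaluate_generator <- function(G, eval_pairs, label = NULL) {
  assert_that(length(eval_pairs) >= 1, "eval_pairs is empty")
  ps <- vapply(eval_pairs, function(p) {
    gx <- apply_generator(G, p$x)
    psnr(denormalize(p$y$values), denormalize(gx$values))
  }, numeric(1))
  finite <- ps[is.finite(ps)]
  structure(list(
    per_voi_psnr = ps,
    mean = if (length(finite)) mean(finite) else Inf,
    sd = if (length(finite) >= 2) sd(finite) else NA_real_,
    n = length(ps),
    n_infinite = sum(is.infinite(ps)),
    label = label), class = "ec_psnr_report")
}

#' @export
print.ec_psnr_report <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else
    paste0(" [", paste(names(x$label), unlist(x$label), sep = "=",
                       collapse = ", "), "]")
  cat(sprintf("<PSNR report>%s n = %d: %.2f +/- %.2f dB%s\n", lab, x$n,
              x$mean, x$sd,
              if (x$n_infinite > 0)
                sprintf(" (%d infinite, excluded)", x$n_infinite) else ""))
  invisible(x)
}

#' Paired t-test on two PSNR samples
#'
#' Two-sided paired t-test with `df = n - 1`, used to compare cleansing
#' quality between conditions (layer counts, iterations) over the same VOI
#' set. Degenerate input (zero variance of the differences) raises an
#' error rather than returning NaN.
#'
#' @param a,b equal-length numeric vectors (n >= 2), paired by position.
#' @return an object of class `ec_ttest` with fields `t`, `p`, `df`.
#' @export
paired_ttest <- function(a, b) {
  assert_that(length(a) == length(b), "samples must have equal length")
  assert_that(length(a) >= 2, "need at least two pairs")
  d <- a - b
  assert_that(stats::var(d) > 0,
              "paired differences have zero variance (degenerate data)",
              class = "ec_degenerate_data_error")
  tt <- t.test(a, b, paired = TRUE)
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter)), class = "ec_ttest")
}

#' @export
print.ec_ttest <- function(x, ...) {
  cat(sprintf("<paired t-test> t = %.4f, df = %d, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Iteration-versus-PSNR curve
#'
#' Tabulates a list of PSNR reports (pre-training at iteration 0, then one
#' per self-supervised iteration) into a CSV-serialisable data frame of
#' `iteration`, `mean_psnr`, `sd_psnr`, `n`.
#'
#' @param history non-empty list of `ec_psnr_report`.
#' @return data frame with one row per report.
#' @export
iteration_curve <- function(history) {
  assert_that(length(history) >= 1, "history is empty")
  do.call(rbind, lapply(seq_along(history), function(k) {
    r <- history[[k]]
    it <- if (!is.null(r$label$iteration)) r$label$iteration else k - 1L
    data.frame(iteration = as.integer(it), mean_psnr = r$mean,
               sd_psnr = r$sd, n = r$n)
  }))
}
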