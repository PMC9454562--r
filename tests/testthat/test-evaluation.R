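test_that("mse and psnr match closed forms", {
  I <- array(0, c(4, 4, 4))
  expect_equal(mse(I, I), 0)
  expect_equal(mse(I, I + 1024), 1024^2)
  expect_equal(psnr(I, I + 1024), 0)
  expect_equal(psnr(I, I + 10.24), 40)
  expect_identical(psnr(I, I), Inf)
  expect_error(mse(array(0, c(2, 2, 2)), array(0, c(3, 3, 3))),
               class = "ec_contract_error")
})

test_that("mse and psnr agree with brute-force triple loops", {
  set.seed(100)
  for (rep in 1:25) {
    I <- array(runif(8, -1024, 1024), c(2, 2, 2))
    J <- array(runif(8, -1024, 1024), c(2, 2, 2))
    expect_equal(mse(I, J), brute_mse(I, J), tolerance = 1e-9)
    expect_equal(psnr(I, J), brute_psnr(I, J), tolerance = 1e-9)
  }
})

test_that("psnr is permutation invariant and decreases with added noise", {
  set.seed(101)
  I <- array(runif(6^3, -500, 500), c(6, 6, 6))
  J <- I + array(rnorm(6^3, 0, 20), c(6, 6, 6))
  perm <- sample(6^3)
  expect_equal(psnr(I, J), psnr(array(I[perm], dim(I)),
                                array(J[perm], dim(J))))
  vals <- vapply(c(5, 10, 20, 40, 80), function(s) {
    set.seed(102)
    psnr(I, I + array(rnorm(6^3, 0, s), dim(I)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("generator evaluation reports per-VOI PSNR with consistent summaries", {
  set.seed(103)
  pairs <- lapply(1:6, function(i) {
    x <- rand_voi(8)
    y <- voi(pmin(pmax(x$values + runif(1, 0.01, 0.1), -1), 1),
             center = x$center)
    ecgan:::voi_pair(x, y, "fixed")
  })
  rep_ <- evaluate_generator(fn_generator(identity), pairs,
                             label = list(iteration = 2L))
  expect_identical(rep_$n, 6L)
  expect_equal(rep_$mean, mean(rep_$per_voi_psnr), tolerance = 1e-9)
  expect_equal(rep_$sd, sd(rep_$per_voi_psnr), tolerance = 1e-9)
  expect_identical(rep_$label$iteration, 2L)
  expect_error(evaluate_generator(fn_generator(identity), list()),
               class = "ec_validation_error")

  # degenerate perfect reconstruction is flagged, not averaged
  selfp <- lapply(1:3, function(i) {
    x <- rand_voi(8)
    ecgan:::voi_pair(x, x, "fixed")
  })
  repd <- evaluate_generator(fn_generator(identity), selfp)
  expect_identical(repd$n_infinite, 3L)
  expect_true(all(is.infinite(repd$per_voi_psnr)))
})

test_that("paired t-test matches the closed form and is antisymmetric", {
  b <- c(10, 20, 30)
  a <- b + c(1, 2, 3)
  res <- paired_ttest(a, b)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_identical(res$df, 2)
  expect_equal(res$p, 2 * pt(-abs(res$t), df = 2), tolerance = 1e-9)
  swapped <- paired_ttest(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  expect_error(paired_ttest(a, a), class = "ec_degenerate_data_error")
  expect_error(paired_ttest(a, b[1:2]), class = "ec_validation_error")
  expect_error(paired_ttest(1, 2), class = "ec_validation_error")
})

test_that("iteration curves tabulate reports in order and survive CSV", {
  set.seed(104)
  hist <- lapply(0:8, function(it) {
    pairs <- lapply(1:3, function(i) {
      x <- rand_voi(8)
      y <- voi(pmin(pmax(x$values + 0.05, -1), 1), center = x$center)
      ecgan:::voi_pair(x, y, "fixed")
    })
    evaluate_generator(fn_generator(identity), pairs,
                       label = list(iteration = it))
  })
  curve <- iteration_curve(hist)
  expect_identical(nrow(curve), 9L)
  expect_identical(curve$iteration, 0:8)
  single <- iteration_curve(hist[1])
  expect_identical(nrow(single), 1L)
  expect_identical(single$iteration, 0L)
  path <- file.path(tempdir(), "curve.csv")
  write.csv(curve, path, row.names = FALSE)
  back <- read.csv(path)
  expect_equal(back, curve, tolerance = 1e-12)
})
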