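test_that("centerline of a straight cylinder lies on its axis", {
  d <- c(40L, 15L, 15L)
  mask <- array(FALSE, dim = d)
  for (x in 1:40) for (y in 1:15) for (z in 1:15)
    if ((y - 8)^2 + (z - 8)^2 <= 4.5^2) mask[x, y, z] <- TRUE
  cl <- compute_centerline(mask)
  expect_gt(nrow(cl$points), 10)
  off_axis <- sqrt((cl$points[, 2] - 8)^2 + (cl$points[, 3] - 8)^2)
  expect_true(all(off_axis <= 1))
  # ordered end-to-end with bounded steps
  steps <- sqrt(rowSums(diff(cl$points)^2))
  expect_true(all(steps <= 2))
  expect_true(all(mask[cl$points]))
})

test_that("centerline of a simulated phantom tracks the generating tube path", {
  pair <- generate_phantom(test_phantom_spec())
  cl <- compute_centerline(pair$lumen_mask)
  truth <- pair$centerline
  # every centerline point within 2 voxels of the generating path
  dmin <- vapply(seq_len(nrow(cl$points)), function(i) {
    min(sqrt(colSums((t(truth) - cl$points[i, ])^2)))
  }, numeric(1))
  expect_true(all(dmin <= 2))
  # and the path is substantially covered
  expect_gt(nrow(cl$points), 0.5 * nrow(truth))
})

test_that("degenerate centerline masks are rejected or repaired", {
  expect_error(compute_centerline(array(FALSE, c(4, 4, 4))),
               class = "ec_validation_error")
  two <- array(FALSE, c(20, 6, 6))
  two[2:8, 2:4, 2:4] <- TRUE
  two[14:19, 2:4, 2:4] <- TRUE
  expect_warning(cl <- compute_centerline(two), "components")
  expect_true(all(cl$points[, 1] <= 8))  # the larger block
})

test_that("positions are sampled at uniform arc length and clamped to the grid", {
  line <- cbind(1:100, 10, 10)
  centers <- sample_positions(line, 10, S = 8, grid_shape = c(100, 20, 20))
  expect_identical(nrow(centers), 10L)
  expect_true(all(diff(centers[, 1]) > 0))
  # n = 1 returns the arc-length midpoint
  mid <- sample_positions(line, 1, S = 8, grid_shape = c(100, 20, 20))
  expect_equal(mid[1, 1], 50, tolerance = 1)
  # centres near the border are pushed inside so the box fits
  edge <- sample_positions(cbind(1:3, 2, 2), 1, S = 8,
                           grid_shape = c(20, 20, 20))
  expect_true(all(edge - 8 %/% 2 >= 1) && all(edge + 8 - 1 - 8 %/% 2 <= 20))
  expect_error(sample_positions(line, 1, S = 32, grid_shape = c(100, 20, 20)),
               class = "ec_validation_error")
})

test_that("VOI extraction is exact for whole-grid boxes and validates size", {
  set.seed(10)
  nv <- normalized_volume(array(runif(16^3, -1, 1), c(16, 16, 16)),
                          source_id = "vol-a")
  whole <- extract_vois(nv, matrix(c(9, 9, 9), 1), S = 16)[[1]]
  expect_identical(whole$values, nv$values)
  expect_identical(whole$source_id, "vol-a")
  expect_error(extract_vois(nv, matrix(c(8, 8, 8), 1), S = 32),
               class = "ec_validation_error")
})

test_that("matched extraction from registered volumes differs only where they differ", {
  set.seed(11)
  a <- array(runif(20^3, -1, 1), c(20, 20, 20))
  b <- a
  b[5:8, 5:8, 5:8] <- 0.9  # localised "tagging"
  nva <- normalized_volume(a); nvb <- normalized_volume(b)
  centers <- matrix(c(7, 7, 7), 1)
  va <- extract_vois(nva, centers, S = 12)[[1]]
  vb <- extract_vois(nvb, centers, S = 12)[[1]]
  diff_mask <- va$values != vb$values
  expect_true(any(diff_mask))
  full_diff <- (a != b)[1:12, 1:12, 1:12]
  start <- 7 - 12 %/% 2
  expect_identical(diff_mask,
                   (a != b)[start:(start + 11), start:(start + 11),
                            start:(start + 11)])
})

test_that("fixed pairing requires matched centres and preserves counts", {
  set.seed(12)
  nv <- normalized_volume(array(runif(24^3, -1, 1), c(24, 24, 24)))
  centers <- sample_positions(cbind(1:24, 12, 12), 5, 8, c(24, 24, 24))
  tg <- extract_vois(nv, centers, 8)
  nt <- extract_vois(nv, centers, 8)
  pairs <- make_fixed_pairs(tg, nt)
  expect_length(pairs, 5)
  expect_true(all(vapply(pairs, function(p) p$provenance, "") == "fixed"))
  expect_identical(make_fixed_pairs(list(), list()), list())
  nt_bad <- extract_vois(nv, centers + c(1, 0, 0), 8)
  expect_error(make_fixed_pairs(tg, nt_bad), class = "ec_pairing_error")
  expect_error(make_fixed_pairs(tg, nt[1:3]), class = "ec_pairing_error")
})

test_that("dynamic pairing applies the initial-EC method", {
  vois <- lapply(1:4, function(i) rand_voi(8, seed = 100 + i))
  pairs <- make_dynamic_pairs(vois, function(x) x)
  expect_length(pairs, 4)
  expect_true(all(vapply(pairs, function(p) identical(p$x$values, p$y$values),
                         TRUE)))
  expect_true(all(vapply(pairs, function(p) p$provenance, "") == "dynamic"))
  expect_error(
    make_dynamic_pairs(vois, function(x) voi(array(0, c(4, 4, 4)))),
    class = "ec_contract_error")
})

test_that("threshold initial EC replaces tagged voxels and leaves the rest", {
  # tissue-like background at 0.02, a supra-threshold fluid block
  v <- array(0.02, c(10, 10, 10))
  v[3:6, 3:6, 3:6] <- 0.6
  x <- voi(v)
  y <- ec_threshold_initializer()(x)
  fluid <- v > 0.15
  # all previously tagged voxels dropped far below tissue
  expect_true(all(y$values[fluid] < 0))
  interior <- ecgan:::erode6(fluid)
  expect_true(all(y$values[interior] == -1))
  # untouched voxels are bit-identical
  expect_identical(y$values[!fluid], v[!fluid])
})
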