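#' Volume-of-interest container
#'
#' A cubic S^3 subvolume of normalized values together with the voxel
#' coordinate it was centred on and the identifier of its parent volume.
#'
#' @param values S x S x S numeric array with values in `[-1, 1]`.
#' @param center length-3 integer voxel coordinate in the parent volume.
#' @param source_id identifier of the parent volume.
#' @return an object of class `ec_voi`.
#' @export
voi <- function(values, center = c(NA, NA, NA), source_id = NA_character_) {
  d <- dim(values)
  assert_that(is.array(values) && length(d) == 3 && d[1] == d[2] &&
                d[2] == d[3], "VOI values must be a cubic 3D array")
  assert_that(all(values >= -1 - 1e-9) && all(values <= 1 + 1e-9),
              "VOI values must lie in [-1, 1]")
  structure(list(values = values, center = as.integer(center),
                 source_id = source_id), class = "ec_voi")
}

#' @export
print.ec_voi <- function(x, ...) {
  cat(sprintf("<VOI> %d^3 at (%s) from %s\n", dim(x$values)[1],
              paste(x$center, collapse = ","), x$source_id))
  invisible(x)
}

voi_pair <- function(x, y, provenance = c("fixed", "dynamic")) {
  provenance <- match.arg(provenance)
  assert_that(inherits(x, "ec_voi") && inherits(y, "ec_voi"),
              "pair members must be VOIs", class = "ec_pairing_error")
  assert_that(identical(dim(x$values), dim(y$values)),
              "paired VOIs must share their size",
              class = "ec_pairing_error")
  structure(list(x = x, y = y, provenance = provenance),
            class = "ec_voi_pair")
}

#' Sample VOI centre positions along a centerline
#'
#' Places `n` centres at uniform arc-length spacing along the centerline
#' (at the midpoints of `n` equal arc segments, so `n = 1` yields the
#' arc-length midpoint), then clamps each centre so the S^3 box fits the
#' grid. The box start index uses the floor convention: a VOI centred at
#' `c` spans `c - S %/% 2` to `c + S - 1 - S %/% 2`.
#'
#' @param centerline an `ec_centerline` (or bare n x 3 coordinate matrix).
#' @param n number of centres (>= 1).
#' @param S VOI edge length in voxels.
#' @param grid_shape dimensions of the parent volume.
#' @return n x 3 integer matrix of clamped centre coordinates.
#' @export
sample_positions <- function(centerline, n, S, grid_shape) {
  pts <- if (inherits(centerline, "ec_centerline")) centerline$points
         else as.matrix(centerline)
  assert_that(nrow(pts) >= 1, "centerline must contain at least one point")
  assert_that(n >= 1, "n must be at least 1")
  assert_that(all(grid_shape >= S),
              "VOI size S exceeds a grid dimension")
  s <- centerline_arclength(pts)
  L <- s[length(s)]
  targets <- L * (2 * seq_len(n) - 1) / (2 * n)
  centers <- t(vapply(targets, function(tt) {
    if (L == 0) return(as.numeric(pts[1, ]))
    i <- findInterval(tt, s, rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(pts) - 1)
    w <- (tt - s[i]) / max(s[i + 1] - s[i], 1e-12)
    (1 - w) * pts[i, ] + w * pts[i + 1, ]
  }, numeric(3)))
  centers <- round(centers)
  half <- S %/% 2
  for (ax in 1:3) {
    start <- clamp(centers[, ax] - half, 1, grid_shape[ax] - S + 1)
    centers[, ax] <- start + half
  }
  storage.mode(centers) <- "integer"
  dimnames(centers) <- NULL
  centers
}

#' Extract cubic VOIs at given centres
#'
#' Cuts axis-aligned S^3 subvolumes of a normalized volume at each centre
#' (floor convention for even S). Every box must fit the grid; use
#' [sample_positions()] to obtain clamped centres.
#'
#' @param nvol a [normalized_volume()].
#' @param centers n x 3 matrix of voxel coordinates.
#' @param S VOI edge length in voxels.
#' @return list of [voi()] objects.
#' @export
extract_vois <- function(nvol, centers, S) {
  assert_that(inherits(nvol, "ec_nvol"), "nvol must be a normalized volume")
  d <- dim(nvol$values)
  assert_that(all(d >= S), "VOI size S exceeds a grid dimension")
  centers <- matrix(as.integer(round(centers)), ncol = 3)
  half <- S %/% 2
  lapply(seq_len(nrow(centers)), function(k) {
    cc <- centers[k, ]
    start <- cc - half
    assert_that(all(start >= 1) && all(start + S - 1 <= d),
                "VOI box at (%s) does not fit the grid",
                paste(cc, collapse = ","))
    vals <- nvol$values[start[1]:(start[1] + S - 1),
                        start[2]:(start[2] + S - 1),
                        start[3]:(start[3] + S - 1)]
    voi(vals, center = cc, source_id = nvol$source_id)
  })
}

#' Assemble fixed-truth VOI pairs
#'
#' Pairs uncleansed (tagged) VOIs element-wise with their registered native
#' counterparts: the native VOI is the desired electronic-cleansing target
#' and never changes during training ("fixed truth"). Centres must match
#' element-wise; mismatches raise a pairing error.
#'
#' @param tagged_vois,native_vois equal-length lists of [voi()] extracted at
#'   matching centres from registered volumes.
#' @return list of `ec_voi_pair` with provenance `"fixed"`.
#' @export
make_fixed_pairs <- function(tagged_vois, native_vois) {
  assert_that(length(tagged_vois) == length(native_vois),
              "tagged and native VOI lists differ in length",
              class = "ec_pairing_error")
  lapply(seq_along(tagged_vois), function(k) {
    tx <- tagged_vois[[k]]; ny <- native_vois[[k]]
    assert_that(identical(tx$center, ny$center),
                "VOI centre mismatch at element %d", k,
                class = "ec_pairing_error")
    voi_pair(tx, ny, "fixed")
  })
}

#' Assemble dynamic-truth VOI pairs
#'
#' Pairs each uncleansed VOI with an estimated cleansing target produced by
#' an initial-EC method (any VOI-to-VOI callable; see
#' [ec_threshold_initializer()] for the default). These targets are
#' "dynamic truth": the self-supervised loop later regenerates them with
#' the evolving generator.
#'
#' @param uncleansed_vois list of [voi()].
#' @param initial_ec function mapping a VOI to a VOI of the same size.
#' @return list of `ec_voi_pair` with provenance `"dynamic"`.
#' @export
make_dynamic_pairs <- function(uncleansed_vois, initial_ec) {
  assert_that(is.function(initial_ec),
              "initial_ec must be a VOI-to-VOI function")
  lapply(uncleansed_vois, function(x) {
    y <- initial_ec(x)
    assert_that(inherits(y, "ec_voi") &&
                  identical(dim(y$values), dim(x$values)),
                "initial_ec returned a VOI of the wrong shape",
                class = "ec_contract_error")
    voi_pair(x, y, "dynamic")
  })
}

#' Threshold-based initial electronic cleansing
#'
#' Returns a transparent baseline initial-EC method used to seed the
#' self-supervised loop: voxels whose normalized value exceeds `threshold`
#' (default 0.15, about 150 HU — i.e. tagged fluid) are replaced with the
#' air value, and replaced voxels on the boundary of the replaced region
#' are then smoothed with a one-voxel (3^3 box) neighbourhood mean to soften
#' the cut edge. Voxels below the threshold are never modified. The method
#' is deliberately simple and fully swappable.
#'
#' @param threshold normalized-value threshold above which voxels are
#'   treated as tagged fluid.
#' @param air_value replacement value (default -1, i.e. -1024 HU).
#' @return a function mapping a [voi()] to a cleansed [voi()].
#' @export
ec_threshold_initializer <- function(threshold = 0.15, air_value = -1) {
  function(x) {
    v <- x$values
    mask <- v > threshold
    v[mask] <- air_value
    if (any(mask) && !all(mask)) {
      boundary <- mask & !erode6(mask)
      if (any(boundary)) {
        sm <- box_mean3(v)
        v[boundary] <- sm[boundary]
      }
    }
    voi(clamp(v, -1, 1), center = x$center, source_id = x$source_id)
  }
}

# 3^3 box mean with border renormalisation
box_mean3 <- function(a) {
  d <- dim(a)
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- clamp(seq_len(d[1]) + dx, 1, d[1])
    sy <- clamp(seq_len(d[2]) + dy, 1, d[2])
    sz <- clamp(seq_len(d[3]) + dz, 1, d[3])
    xs <- seq_len(d[1]) + dx; ok_x <- xs >= 1 & xs <= d[1]
    ys <- seq_len(d[2]) + dy; ok_y <- ys >= 1 & ys <= d[2]
    zs <- seq_len(d[3]) + dz; ok_z <- zs >= 1 & zs <= d[3]
    acc[ok_x, ok_y, ok_z] <- acc[ok_x, ok_y, ok_z] +
      a[xs[ok_x], ys[ok_y], zs[ok_z]]
    cnt[ok_x, ok_y, ok_z] <- cnt[ok_x, ok_y, ok_z] + 1
  }
  acc / cnt
}
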