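#' Digital colon-phantom specification
#'
#' Parameters of the digital colon-phantom simulator: a soft-tissue tube with
#' haustral-fold radius modulation following a smooth lumen path, partially
#' filled with contrast-tagged fluid pooling along gravity (`-z`). The
#' simulator produces registered native (empty-lumen) / tagged
#' (fluid-filled) volume pairs with known fluid masks and centerlines, the
#' stand-in for scanning a physical anthropomorphic phantom without and with
#' tagged fluid at increasing contrast concentrations.
#'
#' Default HU values: air -1000, soft tissue +40, background -100, tagging
#' 600 HU, with 300/600/900 HU as the low/moderate/high tagging levels used
#' by the end-to-end study (only their ordering matters to the method).
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing voxel size in mm.
#' @param lumen_path optional matrix of 3D control points (voxel coords,
#'   monotone in x) for the lumen path; `NULL` draws a smooth random path
#'   from `seed`.
#' @param lumen_radius,wall_thickness tube geometry in mm
#'   (`lumen_radius > wall_thickness >= 0`).
#' @param fold_amplitude,fold_frequency haustral-fold radius modulation:
#'   amplitude in mm, frequency in cycles per mm of centerline arc length.
#' @param fill_fraction fraction of each lumen cross-section filled by
#'   fluid, pooling toward `-z`; in `[0, 1]`.
#' @param tagging_hu,tissue_hu,air_hu,background_hu material attenuations in
#'   HU; must satisfy `air_hu < tissue_hu < tagging_hu`.
#' @param blur_fwhm Gaussian partial-volume blur, FWHM in mm.
#' @param noise_sigma additive Gaussian image noise, HU.
#' @param pseudo_enhancement_strength,pseudo_enhancement_range optional HU
#'   elevation of soft tissue near tagged fluid (strength in HU, decay range
#'   in mm); 0 disables.
#' @param seed integer RNG seed; the phantom is fully deterministic given
#'   the spec including this seed.
#' @return an object of class `ec_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 32, 32),
                         spacing = c(1, 1, 1),
                         lumen_path = NULL,
                         lumen_radius = 6,
                         wall_thickness = 2,
                         fold_amplitude = 1.2,
                         fold_frequency = 0.15,
                         fill_fraction = 0.35,
                         tagging_hu = 600,
                         tissue_hu = 40,
                         air_hu = -1000,
                         background_hu = -100,
                         blur_fwhm = 1.2,
                         noise_sigma = 15,
                         pseudo_enhancement_strength = 0,
                         pseudo_enhancement_range = 3,
                         seed = 1L) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    lumen_path = lumen_path, lumen_radius = lumen_radius,
    wall_thickness = wall_thickness, fold_amplitude = fold_amplitude,
    fold_frequency = fold_frequency, fill_fraction = fill_fraction,
    tagging_hu = tagging_hu, tissue_hu = tissue_hu, air_hu = air_hu,
    background_hu = background_hu, blur_fwhm = blur_fwhm,
    noise_sigma = noise_sigma,
    pseudo_enhancement_strength = pseudo_enhancement_strength,
    pseudo_enhancement_range = pseudo_enhancement_range,
    seed = as.integer(seed)), class = "ec_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  assert_that(length(spec$grid_shape) == 3 && all(spec$grid_shape >= 4),
              "grid_shape must be three dimensions of at least 4 voxels")
  assert_that(all(spec$spacing > 0), "spacing must be strictly positive")
  assert_that(spec$air_hu < spec$tissue_hu && spec$tissue_hu < spec$tagging_hu,
              "material ordering violated: need air_hu < tissue_hu < tagging_hu")
  assert_that(spec$fill_fraction >= 0 && spec$fill_fraction <= 1,
              "fill_fraction must lie in [0, 1]")
  assert_that(spec$lumen_radius > spec$wall_thickness &&
                spec$wall_thickness >= 0,
              "need lumen_radius > wall_thickness >= 0")
  assert_that(spec$blur_fwhm >= 0 && spec$noise_sigma >= 0,
              "blur_fwhm and noise_sigma must be non-negative")
  invisible(spec)
}

# per-x-slice lumen centre (voxel coords) and modulated radius (mm)
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing
  rmax_mm <- spec$lumen_radius + spec$fold_amplitude + spec$wall_thickness
  if (is.null(spec$lumen_path)) {
    margin_y <- rmax_mm / sp[2] + 1
    margin_z <- rmax_mm / sp[3] + 1
    cy0 <- (d[2] + 1) / 2
    cz0 <- (d[3] + 1) / 2
    ay <- runif(1, 0.2, 0.9) * max(0, (d[2] - 1) / 2 - margin_y)
    az <- runif(1, 0.2, 0.9) * max(0, (d[3] - 1) / 2 - margin_z)
    py <- runif(1, 0.8, 1.8) * d[1]
    pz <- runif(1, 0.8, 1.8) * d[1]
    phy <- runif(1, 0, 2 * pi)
    phz <- runif(1, 0, 2 * pi)
    xs <- seq_len(d[1])
    yc <- cy0 + ay * sin(2 * pi * xs / py + phy)
    zc <- cz0 + az * sin(2 * pi * xs / pz + phz)
  } else {
    pts <- as.matrix(spec$lumen_path)
    assert_that(ncol(pts) == 3 && nrow(pts) >= 2,
                "lumen_path must be a matrix of at least two 3D points")
    x0 <- max(1L, as.integer(ceiling(min(pts[, 1]))))
    x1 <- min(d[1], as.integer(floor(max(pts[, 1]))))
    assert_that(x1 > x0, "lumen_path spans less than two x slices",
                class = "ec_geometry_error")
    xs <- x0:x1
    yc <- spline(pts[, 1], pts[, 2], xout = xs)$y
    zc <- spline(pts[, 1], pts[, 3], xout = xs)$y
  }
  # arc length (mm) along the path, for fold phase
  if (length(xs) > 1) {
    step <- sqrt((diff(xs) * sp[1])^2 + (diff(yc) * sp[2])^2 +
                   (diff(zc) * sp[3])^2)
    s_mm <- c(0, cumsum(step))
  } else s_mm <- 0
  r_mm <- spec$lumen_radius +
    spec$fold_amplitude * sin(2 * pi * spec$fold_frequency * s_mm)
  r_mm <- pmax(r_mm, 0.6 * min(sp))
  # geometry check: tube plus wall must stay inside the grid
  rw <- r_mm + spec$wall_thickness
  ok <- all(yc - rw / sp[2] >= 1) && all(yc + rw / sp[2] <= d[2]) &&
    all(zc - rw / sp[3] >= 1) && all(zc + rw / sp[3] <= d[3])
  if (!ok)
    stop_ec("lumen path (plus wall) exits the grid; enlarge grid_shape or shrink the tube",
            class = "ec_geometry_error")
  list(xs = xs, yc = yc, zc = zc, r_mm = r_mm)
}

#' Generate a registered native/tagged phantom pair
#'
#' Builds the clean (native) and fluid-filled (tagged) volumes on the same
#' grid: lumen voxels are `air_hu` in the native volume; in the tagged
#' volume the lower `fill_fraction` of each lumen cross-section (by
#' z-height) is set to `tagging_hu`. Soft-tissue wall and background are
#' identical in both. Degradation is then applied in order: Gaussian
#' partial-volume blur, optional pseudo-enhancement of tissue near fluid
#' (tagged volume only), and independent additive Gaussian noise per volume.
#' The ground-truth `fluid_mask` and `lumen_mask` are pre-blur, and the
#' returned centerline is the generating tube path sampled per x slice.
#'
#' The output is fully deterministic given the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `ec_phantom_pair` with fields `native`,
#'   `tagged` (both [ct_volume()]), `fluid_mask`, `lumen_mask` (logical
#'   arrays), `centerline` (n x 3 matrix of voxel coordinates) and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  d <- spec$grid_shape
  sp <- spec$spacing
  geo <- phantom_geometry(spec)

  native <- array(spec$background_hu, dim = d)
  lumen <- array(FALSE, dim = d)
  fluid <- array(FALSE, dim = d)
  yy <- matrix(seq_len(d[2]), d[2], d[3])
  zz <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  for (i in seq_along(geo$xs)) {
    x <- geo$xs[i]
    d2 <- ((yy - geo$yc[i]) * sp[2])^2 + ((zz - geo$zc[i]) * sp[3])^2
    lum <- d2 <= geo$r_mm[i]^2
    wall <- d2 <= (geo$r_mm[i] + spec$wall_thickness)^2 & !lum
    sl <- native[x, , ]
    sl[wall] <- spec$tissue_hu
    sl[lum] <- spec$air_hu
    native[x, , ] <- sl
    lumen[x, , ] <- lum
    if (spec$fill_fraction > 0 && any(lum)) {
      z_of_lum <- zz[lum]
      z_cut <- if (spec$fill_fraction >= 1) max(z_of_lum)
               else quantile(z_of_lum, spec$fill_fraction, type = 1,
                             names = FALSE)
      fl <- lum & zz <= z_cut
      fluid[x, , ] <- fl
    }
  }
  tagged <- native
  tagged[fluid] <- spec$tagging_hu

  # partial-volume blur
  if (spec$blur_fwhm > 0) {
    sigma_vox <- spec$blur_fwhm / 2.354820045 / sp
    native <- gauss_smooth3(native, sigma_vox)
    tagged <- gauss_smooth3(tagged, sigma_vox)
  }
  # pseudo-enhancement: distance-decayed HU elevation of tissue near fluid,
  # tagged volume only (it is an artifact of the contrast material)
  if (spec$pseudo_enhancement_strength > 0 && any(fluid)) {
    steps <- max(1L, as.integer(ceiling(spec$pseudo_enhancement_range /
                                          min(sp))))
    dist_vox <- array(Inf, dim = d)
    m <- fluid
    dist_vox[m] <- 0
    for (k in seq_len(steps)) {
      m2 <- dilate6(m)
      ring <- m2 & !m
      dist_vox[ring] <- k
      m <- m2
    }
    dist_mm <- dist_vox * min(sp)
    elev <- spec$pseudo_enhancement_strength *
      pmax(0, 1 - dist_mm / spec$pseudo_enhancement_range)
    tissue_like <- !lumen & is.finite(dist_mm) & dist_mm > 0
    tagged[tissue_like] <- tagged[tissue_like] + elev[tissue_like]
  }
  # independent acquisition noise per volume
  if (spec$noise_sigma > 0) {
    native <- native + array(rnorm(prod(d), 0, spec$noise_sigma), dim = d)
    tagged <- tagged + array(rnorm(prod(d), 0, spec$noise_sigma), dim = d)
  }
  structure(list(
    native = ct_volume(native, spacing = sp),
    tagged = ct_volume(tagged, spacing = sp),
    fluid_mask = fluid, lumen_mask = lumen,
    centerline = cbind(x = geo$xs, y = geo$yc, z = geo$zc),
    spec = spec), class = "ec_phantom_pair")
}

#' @export
print.ec_phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom pair> grid %s, tagging %g HU, fluid voxels %d (%.1f%% of lumen)\n",
              paste(dim(x$native$voxels), collapse = "x"),
              x$spec$tagging_hu, sum(x$fluid_mask),
              100 * sum(x$fluid_mask) / max(1, sum(x$lumen_mask))))
  invisible(x)
}

#' Generate a batch of phantom pairs
#'
#' Produces `n` phantom pairs from a spec template with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n - 1`; when the template has
#' no explicit `lumen_path` each seed draws its own random tube path.
#' Reproducible: the same call yields bitwise-identical output.
#'
#' @param spec_template a [phantom_spec()] whose `seed` is overridden.
#' @param n number of pairs (>= 1).
#' @param base_seed first seed.
#' @return list of `ec_phantom_pair`.
#' @export
batch_generate <- function(spec_template, n, base_seed = 1L) {
  assert_that(n >= 1, "n must be at least 1")
  lapply(seq_len(n), function(i) {
    spec <- spec_template
    spec$seed <- as.integer(base_seed + i - 1)
    generate_phantom(spec)
  })
}

#' Write a phantom pair to disk
#'
#' Writes the native and tagged volumes plus masks as NIfTI (masks as 8-bit),
#' the centerline as a CSV of voxel coordinates, and the spec as YAML.
#'
#' @param pair an `ec_phantom_pair`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(pair$native, file.path(dir, "native.nii.gz"))
  write_volume(pair$tagged, file.path(dir, "tagged.nii.gz"))
  for (mk in c("fluid_mask", "lumen_mask")) {
    img <- RNifti::asNifti(array(as.integer(pair[[mk]]),
                                 dim = dim(pair[[mk]])))
    RNifti::pixdim(img) <- pair$native$spacing
    RNifti::writeNifti(img, file.path(dir, paste0(mk, ".nii.gz")),
                       datatype = "uint8")
  }
  write.csv(as.data.frame(pair$centerline),
            file.path(dir, "centerline.csv"), row.names = FALSE)
  spec <- pair$spec
  spec$lumen_path <- if (is.null(spec$lumen_path)) NULL
                     else apply(spec$lumen_path, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(unclass(spec), file.path(dir, "phantom_spec.yaml"))
  invisible(dir)
}
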