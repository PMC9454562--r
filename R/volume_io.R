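#' CT volume container
#'
#' A 3D grid of attenuation values in Hounsfield units (HU) together with its
#' voxel spacing and physical origin. This is the raw currency of the
#' pipeline: the simulator emits `ct_volume` pairs, and all I/O and
#' resampling operate on it. Axis convention is `(x, y, z)` with `z` axial;
#' voxel indices are 1-based throughout the package.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing length-3 numeric, voxel size in mm per axis (all > 0).
#' @param origin length-3 numeric, physical position of voxel `(1,1,1)` in mm.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3,
              "voxels must be a 3D array")
  assert_that(all(dim(voxels) >= 1), "grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3 && all(is.finite(spacing)) &&
                all(spacing > 0),
              "spacing must be three strictly positive values")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Normalized volume container
#'
#' A 3D grid of values in `[-1, 1]`, the representation consumed by the
#' networks. Produced by [normalize_hu()] and mapped back to HU by
#' [denormalize()].
#'
#' @param values 3D numeric array with all values in `[-1, 1]`.
#' @param spacing length-3 positive numeric, mm.
#' @param source_id optional identifier carried into extracted VOIs.
#' @return an object of class `ec_nvol`.
#' @export
normalized_volume <- function(values, spacing = c(1, 1, 1),
                              source_id = NA_character_) {
  assert_that(is.array(values) && length(dim(values)) == 3,
              "values must be a 3D array")
  assert_that(all(values >= -1 - 1e-9) && all(values <= 1 + 1e-9),
              "normalized values must lie in [-1, 1]")
  spacing <- as.numeric(spacing)
  assert_that(all(spacing > 0), "spacing must be strictly positive")
  structure(list(values = values, spacing = spacing, source_id = source_id),
            class = "ec_nvol")
}

#' @export
print.ec_nvol <- function(x, ...) {
  cat(sprintf("<normalized volume> %s voxels, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.(mhd|mha)$", path)) "metaimage"
  else if (dir.exists(path)) "dicom_series"
  else stop_ec("cannot infer volume format from '%s'", path,
               class = "ec_io_error")
}

#' Read a volumetric CT image
#'
#' Reads a CT volume in NIfTI (`.nii`/`.nii.gz`) or MetaImage
#' (`.mhd` + `.raw`, or single-file `.mha`) format, returning voxels in HU
#' with the spacing taken from the format metadata. NIfTI is the canonical
#' interchange format of the package. DICOM-series ingestion is not
#' available in this build and raises an informative error.
#'
#' @param path file path (or directory for a DICOM series).
#' @param format one of `"nifti"`, `"metaimage"`, `"dicom_series"`; inferred
#'   from the file extension when omitted.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("nifti", "metaimage", "dicom_series"))
  if (format == "dicom_series")
    stop_ec("DICOM-series ingestion is not supported in this build; convert the series to NIfTI",
            class = "ec_io_error")
  assert_that(file.exists(path), "file '%s' does not exist", path,
              class = "ec_io_error")
  if (format == "nifti") {
    if (file.info(path)$size == 0)
      stop_ec("file '%s' is empty", path, class = "ec_io_error")
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      stop_ec("failed to read NIfTI '%s': %s", path,
                              conditionMessage(e), class = "ec_io_error"))
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop_ec("NIfTI '%s' has no usable voxel spacing (pixdim)", path,
              class = "ec_metadata_error")
    vox <- array(as.numeric(img), dim = dim(img)[1:3])
    ct_volume(vox, spacing = sp)
  } else {
    read_metaimage(path)
  }
}

#' Write a volumetric CT image
#'
#' Writes a [ct_volume()] as NIfTI or MetaImage, chosen from the file
#' extension unless `format` is given. MetaImage data are stored as
#' double-precision raw (`MET_DOUBLE`) so write/read round trips are exact.
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii`, `.nii.gz`, `.mhd`, `.mha`).
#' @param format optional explicit format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  assert_that(inherits(vol, "ct_volume"), "vol must be a ct_volume")
  format <- format %||% guess_format(path)
  if (format == "nifti") {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (format == "metaimage") {
    write_metaimage(vol, path)
  } else {
    stop_ec("cannot write format '%s'", format, class = "ec_io_error")
  }
  invisible(path)
}

# -- MetaImage (.mhd/.mha): no installed R package reads this format, so a
#    minimal reader/writer for the fields the pipeline needs is implemented
#    here (3D, MET_SHORT/MET_FLOAT/MET_DOUBLE, uncompressed).

write_metaimage <- function(vol, path) {
  local_data <- grepl("\\.mha$", path)
  d <- dim(vol$voxels)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.10g %.10g %.10g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s",
            if (local_data) "LOCAL"
            else basename(sub("\\.mhd$", ".raw", path)))
  )
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  } else {
    writeLines(hdr, path)
    raw_path <- sub("\\.mhd$", ".raw", path)
    con <- file(raw_path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_metaimage <- function(path) {
  if (file.info(path)$size == 0)
    stop_ec("file '%s' is empty", path, class = "ec_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0)
      stop_ec("MetaImage '%s': header ended before ElementDataFile", path,
              class = "ec_io_error")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  for (field in c("DimSize", "ElementSpacing", "ElementType"))
    if (is.null(hdr[[field]]))
      stop_ec("MetaImage '%s': missing header field '%s'", path, field,
              class = "ec_metadata_error")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  n <- prod(d)
  type <- hdr$ElementType
  read_vals <- function(con) switch(
    type,
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(con, "double", n, size = 4, endian = "little"),
    MET_SHORT  = readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little"),
    stop_ec("MetaImage '%s': unsupported ElementType '%s'", path, type,
            class = "ec_io_error"))
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- read_vals(con)
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    assert_that(file.exists(raw_path), "raw file '%s' not found", raw_path,
                class = "ec_io_error")
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- read_vals(rcon)
  }
  assert_that(length(vals) == n, "MetaImage '%s': truncated voxel data", path,
              class = "ec_io_error")
  ct_volume(array(as.numeric(vals), dim = d), spacing = sp, origin = org)
}

#' Resample a CT volume to isotropic voxels
#'
#' CT colonography volumes are acquired with near-isotropic in-plane pixels
#' but a coarser (or finer) slice interval; this interpolates along the
#' axial (`z`) axis so the output spacing is `(p, p, p)` with `p` the
#' in-plane pixel spacing. In-plane grids are untouched; the axial axis is
#' linearly interpolated on the old physical grid, preserving the physical
#' extent to within one voxel. Already-isotropic input is returned
#' unchanged.
#'
#' @param vol a [ct_volume()].
#' @return a [ct_volume()] with isotropic spacing.
#' @export
resample_isotropic <- function(vol) {
  assert_that(inherits(vol, "ct_volume"), "vol must be a ct_volume")
  p <- vol$spacing[1]
  if (abs(vol$spacing[2] - p) > 1e-9 * p)
    warning("in-plane spacings differ; using the x pixel spacing")
  sz <- vol$spacing[3]
  if (abs(sz - p) <= 1e-12) return(vol)
  d <- dim(vol$voxels)
  nz <- d[3]
  extent <- (nz - 1) * sz
  nz_new <- max(1L, as.integer(floor(extent / p + 1e-9)) + 1L)
  out <- array(0, dim = c(d[1], d[2], nz_new))
  flat <- matrix(vol$voxels, nrow = d[1] * d[2], ncol = nz)
  for (j in seq_len(nz_new)) {
    t <- (j - 1) * p / sz            # fractional old slice index (0-based)
    i0 <- min(floor(t), nz - 1)
    w <- t - i0
    lo <- as.integer(i0) + 1L
    hi <- min(lo + 1L, nz)
    out[, , j] <- array((1 - w) * flat[, lo] + w * flat[, hi], dim = d[1:2])
  }
  ct_volume(out, spacing = c(p, p, p), origin = vol$origin)
}

#' Map Hounsfield units to the network value range
#'
#' Clips HU values to `[-1024, 1024]` and scales linearly to `[-1, 1]`
#' (`v_out = clip(v, -1024, 1024) / 1024`), the representation the networks
#' train on. Spacing is preserved.
#'
#' @param vol a [ct_volume()].
#' @param source_id optional identifier carried into extracted VOIs.
#' @return a [normalized_volume()].
#' @export
normalize_hu <- function(vol, source_id = NA_character_) {
  assert_that(inherits(vol, "ct_volume"), "vol must be a ct_volume")
  normalized_volume(clamp(vol$voxels, -1024, 1024) / 1024,
                    spacing = vol$spacing, source_id = source_id)
}

#' Map normalized values back to Hounsfield units
#'
#' Inverse of [normalize_hu()] on the in-range domain: `v_out = 1024 * v_in`.
#' Used before computing PSNR so image-quality numbers are on the HU scale.
#'
#' @param nvol a [normalized_volume()], or a bare numeric array of values in
#'   `[-1, 1]`.
#' @return a [ct_volume()] (or a bare array if the input was one).
#' @export
denormalize <- function(nvol) {
  if (is.array(nvol) || is.numeric(nvol)) return(1024 * nvol)
  assert_that(inherits(nvol, "ec_nvol"), "nvol must be a normalized volume")
  ct_volume(1024 * nvol$values, spacing = nvol$spacing)
}
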