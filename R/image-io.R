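#' Dynamic (4D) PET image container
#'
#' Wraps a 4D activity-concentration array (kBq/mL) together with its voxel
#' geometry and [frame_schedule()]. The 4th array dimension indexes frames
#' and must match the schedule length.
#'
#' @param data 4D numeric array (x, y, z, frame), kBq/mL.
#' @param voxel_size_mm Length-3 numeric, voxel edge lengths in mm.
#' @param schedule A [frame_schedule()].
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `voxel_size_mm`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_size_mm, schedule, affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array", call. = FALSE)
  if (!inherits(schedule, "frame_schedule"))
    stop("`schedule` must be a frame_schedule", call. = FALSE)
  if (dim(data)[4L] != n_frames(schedule))
    stop("4th dimension (", dim(data)[4L], ") does not match schedule length (",
         n_frames(schedule), ")", call. = FALSE)
  if (!all(is.finite(data)))
    stop("activity values must be finite", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive numbers", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 schedule = schedule, affine = affine),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("<dynamic_image> %s voxels x %d frames, voxel %s mm\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4L],
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' 3D integer label mask
#'
#' @param labels 3D array of non-negative integer labels (0 = outside).
#' @param voxel_size_mm Length-3 numeric, mm.
#' @param affine Optional 4x4 matrix, as in [dynamic_image()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, voxel_size_mm, affine = NULL) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive numbers", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(list(labels = array(as.integer(round(labels)), dim(labels)),
                 voxel_size_mm = voxel_size_mm, affine = affine),
            class = "label_mask")
}

#' Volume of one voxel in cm^3
#' @param x A `dynamic_image` or `label_mask`.
#' @return Voxel volume in cm^3 (product of mm edge lengths / 1000).
#' @export
voxel_volume_cm3 <- function(x) prod(x$voxel_size_mm) / 1000

#' Time-activity curve
#'
#' One activity value (kBq/mL) per frame of a [frame_schedule()].
#'
#' @param values Numeric vector, one value per frame.
#' @param schedule A [frame_schedule()].
#' @return An object of class `tac`.
#' @export
tac <- function(values, schedule) {
  if (!inherits(schedule, "frame_schedule"))
    stop("`schedule` must be a frame_schedule", call. = FALSE)
  if (length(values) != n_frames(schedule))
    stop("TAC length (", length(values), ") does not match schedule (",
         n_frames(schedule), " frames)", call. = FALSE)
  structure(list(values = as.numeric(values), schedule = schedule),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, peak %.3g kBq/mL at %.1f min\n",
              n_frames(x$schedule), max(x$values),
              frame_midpoints(x$schedule, "min")[which.max(x$values)]))
  invisible(x)
}

check_same_grid <- function(image, mask) {
  if (!identical(dim(image$data)[1:3], dim(mask$labels)))
    stop("mask grid does not match image grid", call. = FALSE)
  if (max(abs(image$voxel_size_mm - mask$voxel_size_mm)) > 1e-6)
    stop("mask voxel size does not match image", call. = FALSE)
  invisible(TRUE)
}

#' Mean time-activity curve over a labelled region
#'
#' Unweighted mean of all voxel TACs carrying `label` in `mask`.
#'
#' @param image A [dynamic_image()].
#' @param mask A [label_mask()] on the same grid.
#' @param label Integer label to extract (default 1).
#' @return A [tac()].
#' @export
extract_voi_tac <- function(image, mask, label = 1L) {
  check_same_grid(image, mask)
  sel <- mask$labels == label
  if (!any(sel))
    stop("label ", label, " is empty in the mask", call. = FALSE)
  nf <- n_frames(image$schedule)
  mat <- matrix(image$data, ncol = nf)
  tac(colMeans(mat[as.vector(sel), , drop = FALSE]), image$schedule)
}

#' Generate a quasi-spherical VOI of a requested volume
#'
#' Selects the `k` voxels nearest (Euclidean distance in mm) to `center`,
#' where `k` is the voxel count whose total volume is closest to
#' `volume_cm3`. Ties in distance are broken lexicographically on voxel
#' index (x, then y, then z) so the mask is reproducible. If `within` is
#' supplied, only voxels inside that mask are candidates, which keeps the
#' VOI inside an anatomical region.
#'
#' @param center Length-3 voxel-index coordinates (1-based; may be
#'   fractional).
#' @param volume_cm3 Requested volume. If smaller than one voxel, a 1-voxel
#'   mask is returned with a warning.
#' @param grid A `dynamic_image` or `label_mask` supplying dimensions and
#'   voxel size.
#' @param within Optional logical 3D array or `label_mask` restricting the
#'   candidate voxels.
#' @return A [label_mask()] (label 1 inside the VOI) with attributes
#'   `achieved_cm3` and `n_voxels`.
#' @export
make_spherical_voi <- function(center, volume_cm3, grid, within = NULL) {
  dims <- if (inherits(grid, "dynamic_image")) dim(grid$data)[1:3] else dim(grid$labels)
  vox <- grid$voxel_size_mm
  if (length(center) != 3L || any(center < 1) || any(center > dims))
    stop("`center` must lie inside the grid", call. = FALSE)
  vvol <- prod(vox) / 1000
  k <- max(1L, as.integer(round(volume_cm3 / vvol)))
  if (volume_cm3 < vvol) {
    warning("requested volume smaller than one voxel; returning 1-voxel mask")
    k <- 1L
  }
  idx <- arrayInd(seq_len(prod(dims)), dims)
  if (!is.null(within)) {
    w <- if (inherits(within, "label_mask")) within$labels > 0 else within
    keep <- as.vector(w)
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) < k)
      stop("`within` region has fewer voxels than the requested volume",
           call. = FALSE)
  }
  d2 <- ((idx[, 1] - center[1]) * vox[1])^2 +
        ((idx[, 2] - center[2]) * vox[2])^2 +
        ((idx[, 3] - center[3]) * vox[3])^2
  ord <- order(d2, idx[, 1], idx[, 2], idx[, 3])
  chosen <- idx[ord[seq_len(k)], , drop = FALSE]
  lab <- array(0L, dims)
  lab[chosen] <- 1L
  out <- label_mask(lab, vox)
  attr(out, "achieved_cm3") <- k * vvol
  attr(out, "n_voxels") <- k
  out
}

#' Read and write dynamic images as NIfTI-1 plus a schedule sidecar
#'
#' The image is stored as a 4D float64 NIfTI-1 volume so roundtrips are
#' lossless; frame timing goes in a CSV sidecar (see [write_schedule()]).
#'
#' @param image A [dynamic_image()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param schedule_path Sidecar CSV path.
#' @return `read_dynamic` returns a [dynamic_image()]; `write_dynamic`
#'   returns `path` invisibly.
#' @export
write_dynamic <- function(image, path, schedule_path) {
  nii <- RNifti::asNifti(structure(image$data,
                                   pixdim = c(image$voxel_size_mm,
                                              image$schedule$duration_s[1])),
                         datatype = "double")
  RNifti::writeNifti(nii, path)
  write_schedule(image$schedule, schedule_path)
  invisible(path)
}

#' @rdname write_dynamic
#' @export
read_dynamic <- function(path, schedule_path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI file, got ", length(dim(arr)), "D", call. = FALSE)
  schedule <- read_schedule(schedule_path)
  if (dim(arr)[4L] != n_frames(schedule))
    stop("schedule has ", n_frames(schedule), " frames but image has ",
         dim(arr)[4L], call. = FALSE)
  vox <- RNifti::pixdim(nii)[1:3]
  dynamic_image(arr, vox, schedule)
}

#' Read and write label masks as integer NIfTI-1
#'
#' @param mask A [label_mask()].
#' @param path NIfTI file path.
#' @return `read_mask` returns a [label_mask()]; `write_mask` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  nii <- RNifti::asNifti(structure(mask$labels, pixdim = mask$voxel_size_mm),
                         datatype = "int16")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI file", call. = FALSE)
  label_mask(arr, RNifti::pixdim(nii)[1:3])
}

#' Write a TAC as a TSV table
#'
#' Columns: `frame`, `start_s`, `duration_s`, `value_kBq_mL`.
#'
#' @param x A [tac()].
#' @param path Output TSV path.
#' @return `path`, invisibly. `read_tac` returns a [tac()].
#' @export
write_tac <- function(x, path) {
  df <- data.frame(frame = seq_len(n_frames(x$schedule)),
                   start_s = x$schedule$start_s,
                   duration_s = x$schedule$duration_s,
                   value_kBq_mL = x$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  df <- utils::read.delim(path)
  tac(df$value_kBq_mL, frame_schedule(df$start_s, df$duration_s))
}
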