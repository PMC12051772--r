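#' Non-negative class weights for one normalized voxel TAC
#'
#' Solves `min_{w >= 0} || tac - sum_k w_k * class_k ||_2` by non-negative
#' least squares against the four library curves. The solution is
#' deterministic; an all-zero TAC returns all-zero weights with attribute
#' `flag = "all-zero"`.
#'
#' @param values Normalized voxel TAC sampled on the library's time grid.
#' @param library A `class_library` (see [build_class_library()]).
#' @return Named non-negative weight vector (one per class).
#' @export
fit_voxel_weights <- function(values, library) {
  stopifnot(inherits(library, "class_library"))
  if (length(values) != length(library$time_s))
    stop("TAC is not on the library grid (interpolate first)", call. = FALSE)
  if (all(values == 0)) {
    w <- stats::setNames(numeric(ncol(library$curves)), colnames(library$curves))
    attr(w, "flag") <- "all-zero"
    return(w)
  }
  w <- pracma::lsqnonneg(library$curves, values)$x
  stats::setNames(pmax(w, 0), colnames(library$curves))
}

#' Gray-matter ratio of a weight vector
#'
#' The GM class weight relative to the sum of all class weights,
#' `w_GM / sum_k w_k`. Scale-invariant; undefined (returned as `NA` with
#' attribute `flag = "undefined"`) when all weights are zero.
#'
#' @param weights Non-negative weight vector; the GM entry is the one named
#'   `"gm"` (or the first entry if unnamed).
#' @return Ratio in `[0, 1]`, or flagged `NA`.
#' @export
gm_ratio <- function(weights) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (s == 0) {
    out <- NA_real_
    attr(out, "flag") <- "undefined"
    return(out)
  }
  g <- if (!is.null(names(weights)) && "gm" %in% names(weights))
    weights[["gm"]] else weights[[1L]]
  g / s
}

## Linear-interpolation matrix mapping values on `from` times to `to` times
## (constant extrapolation at the ends). Returns a length(to) x length(from)
## matrix W with interpolated = V %*% t(W) for row-per-voxel V.
interp_matrix <- function(from, to) {
  nf <- length(from)
  W <- matrix(0, length(to), nf)
  for (i in seq_along(to)) {
    t0 <- to[i]
    if (t0 <= from[1]) { W[i, 1] <- 1; next }
    if (t0 >= from[nf]) { W[i, nf] <- 1; next }
    j <- findInterval(t0, from)
    a <- (t0 - from[j]) / (from[j + 1] - from[j])
    W[i, j] <- 1 - a
    W[i, j + 1] <- a
  }
  W
}

#' Extract an SVCA pseudoreference region and curve
#'
#' Stage 2 of the supervised clustering algorithm: the scan is framewise
#' normalized ([normalize_dynamic()]), every brain voxel's normalized TAC is
#' decomposed into non-negative class weights against the library
#' ([fit_voxel_weights()]), and voxels whose GM ratio strictly exceeds
#' `threshold` form the pseudoreference region. The pseudoreference curve
#' is the mean TAC of those voxels taken from the ORIGINAL (unnormalized)
#' image, so it is in kBq/mL. TACs are interpolated to the library grid
#' when the scan's schedule differs.
#'
#' @param image A [dynamic_image()].
#' @param brain A [label_mask()]; only voxels inside it are fitted.
#' @param library A `class_library`.
#' @param threshold GM-ratio cutoff in (0, 1); default 0.9.
#' @return An object of class `svca_result`: `weights` (voxel x class
#'   matrix), `voxel_index` (linear indices of fitted voxels), `gm_ratio`
#'   (3D map, `NA` outside the brain), `reference_mask` ([label_mask()]),
#'   `reference_tac` ([tac()]), `n_voxels`, `threshold`.
#' @export
extract_pseudoreference <- function(image, brain, library, threshold = 0.9) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  norm <- normalize_dynamic(image, brain)
  sel <- which(as.vector(brain$labels > 0))
  nf <- n_frames(image$schedule)
  V <- matrix(norm$data, ncol = nf)[sel, , drop = FALSE]

  mid <- frame_midpoints(image$schedule)
  if (length(mid) != length(library$time_s) ||
      max(abs(mid - library$time_s)) > 1e-6) {
    V <- V %*% t(interp_matrix(mid, library$time_s))
  }

  K <- ncol(library$curves)
  Wmat <- matrix(0, nrow(V), K, dimnames = list(NULL, colnames(library$curves)))
  for (i in seq_len(nrow(V)))
    Wmat[i, ] <- fit_voxel_weights(V[i, ], library)

  sums <- rowSums(Wmat)
  ratio <- ifelse(sums > 0, Wmat[, "gm"] / sums, NA_real_)
  ratio_map <- array(NA_real_, dim(brain$labels))
  ratio_map[sel] <- ratio

  keep <- !is.na(ratio) & ratio > threshold
  if (!any(keep))
    stop(sprintf(
      "no voxel exceeds the GM-ratio threshold %.3g (max observed %.3g)",
      threshold, max(ratio, na.rm = TRUE)), call. = FALSE)

  mask_arr <- array(0L, dim(brain$labels))
  mask_arr[sel[keep]] <- 1L
  ref_mask <- label_mask(mask_arr, brain$voxel_size_mm)
  orig <- matrix(image$data, ncol = nf)
  ref_tac <- tac(colMeans(orig[sel[keep], , drop = FALSE]), image$schedule)

  structure(list(weights = Wmat, voxel_index = sel, gm_ratio = ratio_map,
                 reference_mask = ref_mask, reference_tac = ref_tac,
                 n_voxels = sum(keep), threshold = threshold),
            class = "svca_result")
}

#' @export
print.svca_result <- function(x, ...) {
  cat(sprintf("<svca_result> %d pseudoreference voxels (GM ratio > %.2f)\n",
              x$n_voxels, x$threshold))
  invisible(x)
}
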