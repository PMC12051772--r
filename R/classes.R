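#' Framewise normalization of a dynamic scan
#'
#' Standardizes each frame by the mean and SD of its voxel values inside a
#' brain mask: `v' = (v - mean_f) / SD_f`. Statistics are computed over
#' brain voxels only, and the same per-frame transform is applied to every
#' voxel. The result is unitless and invariant to affine rescaling
#' (`a * X + b`) of the raw image, which is what lets kinetic shapes be
#' compared across subjects and scanners.
#'
#' @param image A [dynamic_image()].
#' @param brain A [label_mask()] (any label > 0 counts as brain).
#' @return A `normalized_dynamic_image` (also a `dynamic_image`), with the
#'   brain mask attached as `$brain`.
#' @export
normalize_dynamic <- function(image, brain) {
  check_same_grid(image, brain)
  sel <- as.vector(brain$labels > 0)
  if (!any(sel)) stop("brain mask is empty", call. = FALSE)
  nf <- n_frames(image$schedule)
  mat <- matrix(image$data, ncol = nf)
  bm <- mat[sel, , drop = FALSE]
  mu <- colMeans(bm)
  sdv <- apply(bm, 2, stats::sd)
  if (any(sdv < 1e-12))
    stop("degenerate frame: zero within-mask SD in frame ",
         which(sdv < 1e-12)[1], call. = FALSE)
  norm <- sweep(sweep(mat, 2, mu, "-"), 2, sdv, "/")
  out <- dynamic_image(array(norm, dim(image$data)), image$voxel_size_mm,
                       image$schedule, image$affine)
  out$brain <- brain
  class(out) <- c("normalized_dynamic_image", class(out))
  out
}

#' Image-derived blood curve from a carotid mask
#'
#' Averages the TACs of carotid voxels, standing in for manual artery
#' delineation on an early summed image. As QC, the curve's peak must fall
#' inside `early_window_s` (vascular voxels peak during the bolus passage);
#' a late peak suggests the mask covers tissue and triggers a warning.
#'
#' @param image A [dynamic_image()] (original, unnormalized).
#' @param carotid A [label_mask()] of vascular voxels.
#' @param early_window_s QC window for the peak (s), default 120.
#' @return A [tac()] with attribute `qc` (`"pass"` or `"warn"`).
#' @export
idif_blood_curve <- function(image, carotid, early_window_s = 120) {
  curve <- extract_voi_tac(image, carotid, 1L)
  peak_s <- frame_midpoints(image$schedule)[which.max(curve$values)]
  if (peak_s <= early_window_s) {
    attr(curve, "qc") <- "pass"
  } else {
    warning(sprintf(
      "carotid curve peaks at %.0f s, outside the %.0f-s early window; mask may cover tissue",
      peak_s, early_window_s))
    attr(curve, "qc") <- "warn"
  }
  curve
}

## Per-class mean normalized TAC of one subject: matrix (frames x classes).
subject_class_tacs <- function(norm_image, class_masks) {
  cls <- names(PHANTOM_CLASSES)
  stopifnot(all(cls %in% names(class_masks)))
  vapply(cls, function(cl)
    extract_voi_tac(norm_image, class_masks[[cl]], 1L)$values,
    numeric(n_frames(norm_image$schedule)))
}

#' Build the 4-curve kinetic-class library from a training cohort
#'
#' For each class (low-binding GM, WM, thalamus, blood) and each subject,
#' extracts the within-mask mean normalized TAC, linearly interpolates it
#' onto a common time grid (frame midpoints, default the 32-frame
#' schedule's), and averages across subjects. Subjects scanned on different
#' schedules are thereby harmonized onto one grid.
#'
#' @param subjects List of subjects; each element needs `$image` (a
#'   `normalized_dynamic_image`, see [normalize_dynamic()]) and `$masks`
#'   (named list of binary [label_mask()]s: `gm`, `wm`, `thalamus`,
#'   `blood`).
#' @param target_grid_s Common time grid (s); default the WCM-32 frame
#'   midpoints.
#' @return An object of class `class_library`: `time_s`, `curves` (matrix,
#'   one column per class) and `n_subjects`.
#' @export
build_class_library <- function(subjects,
                                target_grid_s = frame_midpoints(standard_schedule("WCM"))) {
  if (length(subjects) < 1L) stop("need at least one subject", call. = FALSE)
  cls <- names(PHANTOM_CLASSES)
  per_subject <- lapply(subjects, function(s) {
    if (is.null(s$image) || is.null(s$masks))
      stop("each subject needs $image and $masks", call. = FALSE)
    if (!all(cls %in% names(s$masks)))
      stop("subject is missing a class mask (need ",
           paste(cls, collapse = ", "), ")", call. = FALSE)
    tacs <- subject_class_tacs(s$image, s$masks)
    mid <- frame_midpoints(s$image$schedule)
    apply(tacs, 2, function(v)
      stats::approx(mid, v, xout = target_grid_s, rule = 2)$y)
  })
  curves <- Reduce(`+`, per_subject) / length(per_subject)
  colnames(curves) <- cls
  structure(list(time_s = target_grid_s, curves = curves,
                 n_subjects = length(subjects)),
            class = "class_library")
}

#' @export
print.class_library <- function(x, ...) {
  cat(sprintf("<class_library> %d classes on %d time points, N = %d subjects\n",
              ncol(x$curves), length(x$time_s), x$n_subjects))
  invisible(x)
}

#' Compare two kinetic-class libraries
#'
#' Per class: the Pearson correlation between the two curves and a one-way
#' ANOVA p-value treating each library's curve samples as one group's
#' observations. Identical libraries give r = 1 and p = 1.
#'
#' @param A,B `class_library` objects on the same time grid.
#' @return `data.frame` with columns `class`, `r`, `anova_p`.
#' @export
compare_class_libraries <- function(A, B) {
  stopifnot(inherits(A, "class_library"), inherits(B, "class_library"))
  if (length(A$time_s) != length(B$time_s) ||
      max(abs(A$time_s - B$time_s)) > 1e-6)
    stop("libraries are not on the same time grid", call. = FALSE)
  cls <- colnames(A$curves)
  res <- lapply(cls, function(cl) {
    a <- A$curves[, cl]; b <- B$curves[, cl]
    grp <- factor(rep(c("A", "B"), each = length(a)))
    p <- stats::oneway.test(c(a, b) ~ grp, var.equal = TRUE)$p.value
    data.frame(class = cl, r = stats::cor(a, b), anova_p = p)
  })
  do.call(rbind, res)
}

#' Write / read a class library as TSV
#'
#' Columns: `time_s`, then one column per class. The subject count is kept
#' in a `# n_subjects` header comment.
#'
#' @param library A `class_library`.
#' @param path Output TSV path.
#' @return `path` invisibly; `read_class_library` returns a
#'   `class_library`.
#' @export
write_class_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_subjects=%d", library$n_subjects), con)
  df <- data.frame(time_s = library$time_s, library$curves)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_class_library
#' @export
read_class_library <- function(path) {
  hdr <- readLines(path, n = 1L)
  n <- as.integer(sub("# n_subjects=", "", hdr))
  df <- utils::read.delim(path, comment.char = "#")
  structure(list(time_s = df$time_s,
                 curves = as.matrix(df[, setdiff(names(df), "time_s")]),
                 n_subjects = n),
            class = "class_library")
}
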