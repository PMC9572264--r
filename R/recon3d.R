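#' Compound posed 2D frames into a 3D intensity/label volume
#'
#' Nearest-voxel forward compounding: pixel (row r, col c) of frame f maps to
#' the world point `pose_f$rotation %*% c((c-1)*s, (r-1)*s, 0) +
#' pose_f$translation` (s = pixel spacing, right-handed frame, image x along
#' columns, y along rows, z normal to the frame) and is deposited into the
#' nearest voxel of an auto-fitted axis-aligned grid. Voxel intensity is the
#' mean of its deposits; the voxel label is the majority vote of deposited
#' labels with ties resolved to the lowest class code; voxel provenance is
#' the frame contributing most deposits (ties to the lowest frame index).
#'
#' @param frames List of intensity matrices (equal shapes).
#' @param poses List of poses (`rotation` 3x3, `translation` length-3 mm).
#' @param labels Optional list of label matrices (codes 0..5).
#' @param voxel_spacing Isotropic voxel size in mm.
#' @param pixel_spacing Pixel size in mm (defaults to `voxel_spacing`).
#'
#' @return An object of class `us_volume`: list with `intensity`, `labels`,
#'   `provenance` (3D arrays indexed \[x, y, z\]; untouched voxels are `NA`,
#'   label 0), `origin` (mm position of voxel \[1,1,1\]), `voxel_spacing`,
#'   `dims`.
#' @export
#' @examples
#' fr <- list(matrix(100, 4, 3), matrix(200, 4, 3))
#' po <- lapply(1:2, function(f) list(rotation = diag(3),
#'                                    translation = c(0, 0, (f - 1) * 0.1),
#'                                    frame_index = f))
#' vol <- compound_volume(fr, po, voxel_spacing = 0.1)
#' vol$dims
compound_volume <- function(frames, poses, labels = NULL, voxel_spacing,
                            pixel_spacing = voxel_spacing) {
  n <- length(frames)
  if (n == 0L) stop("empty input", call. = FALSE)
  if (length(poses) != n || (!is.null(labels) && length(labels) != n))
    stop("frames, poses and labels must have equal length", call. = FALSE)
  if (voxel_spacing <= 0) stop("voxel_spacing must be > 0", call. = FALSE)
  check_pose <- function(p) {
    err <- max(abs(crossprod(p$rotation) - diag(3)))
    if (err > 1e-6 || det(p$rotation) < 0)
      stop("pose rotation is not a proper orthonormal matrix", call. = FALSE)
  }
  lapply(poses, check_pose)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  s <- pixel_spacing
  grid <- rbind(x = rep((seq_len(W) - 1) * s, each = H),
                y = rep((seq_len(H) - 1) * s, times = W),
                z = 0)
  world <- lapply(seq_len(n), function(f)
    poses[[f]]$rotation %*% grid + poses[[f]]$translation)
  lo <- c(min(vapply(world, function(w) min(w[1, ]), 0)),
          min(vapply(world, function(w) min(w[2, ]), 0)),
          min(vapply(world, function(w) min(w[3, ]), 0)))
  vs <- voxel_spacing
  idx <- lapply(world, function(w)
    matrix(as.integer(floor((w - lo) / vs + 0.5)) + 1L, nrow = 3))
  dims <- c(max(vapply(idx, function(i) max(i[1, ]), 0L)),
            max(vapply(idx, function(i) max(i[2, ]), 0L)),
            max(vapply(idx, function(i) max(i[3, ]), 0L)))
  d12 <- as.double(dims[1]) * dims[2]
  DT <- data.table::rbindlist(lapply(seq_len(n), function(f)
    data.table::data.table(
      v = idx[[f]][1, ] + dims[1] * (idx[[f]][2, ] - 1) +
        d12 * (idx[[f]][3, ] - 1),
      I = as.numeric(frames[[f]]),
      L = if (is.null(labels)) 0L else as.integer(labels[[f]]),
      f = f)))
  v <- I <- L <- N <- NULL  # data.table NSE
  agg_i <- DT[, list(I = mean(I)), by = v]
  intensity <- array(NA_real_, dims)
  intensity[agg_i$v] <- agg_i$I
  lab_arr <- array(0L, dims)
  if (!is.null(labels)) {
    agg_l <- DT[, list(N = .N), by = list(v, L)]
    data.table::setorder(agg_l, v, -N, L)
    agg_l <- agg_l[!duplicated(agg_l$v)]
    lab_arr[agg_l$v] <- agg_l$L
  }
  agg_f <- DT[, list(N = .N), by = list(v, f)]
  data.table::setorder(agg_f, v, -N, f)
  agg_f <- agg_f[!duplicated(agg_f$v)]
  prov <- array(NA_integer_, dims)
  prov[agg_f$v] <- agg_f$f
  structure(list(intensity = intensity, labels = lab_arr, provenance = prov,
                 origin = lo, voxel_spacing = vs, dims = dims),
            class = "us_volume")
}

#' @export
print.us_volume <- function(x, ...) {
  cat(sprintf("us_volume: %d x %d x %d voxels at %.3f mm, origin (%.2f, %.2f, %.2f) mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  filled voxels: %d/%d\n", sum(!is.na(x$provenance)),
              prod(x$dims)))
  invisible(x)
}

#' Extract an axis-aligned cross-section from a volume
#'
#' Nearest-voxel plane extraction at a physical position along `x`, `y` or
#' `z`. The returned images are oriented (row, col) = (y, x) for a z-section,
#' (z, x) for a y-section and (z, y) for an x-section.
#'
#' @param volume A `us_volume`.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param position Position along the axis in mm; must fall inside the
#'   volume (the exact boundary is valid).
#' @return List with `intensity` and `labels` matrices and the voxel `index`
#'   of the extracted plane.
#' @export
cross_section <- function(volume, axis = c("x", "y", "z"), position) {
  stopifnot(inherits(volume, "us_volume"))
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  k <- as.integer(round((position - volume$origin[a]) / volume$voxel_spacing)) + 1L
  if (k < 1L || k > volume$dims[a])
    stop(sprintf("position %.3f mm is outside the volume along %s",
                 position, axis), call. = FALSE)
  pick <- function(arr) switch(axis,
    x = t(arr[k, , , drop = TRUE]),   # (z, y)
    y = t(arr[, k, , drop = TRUE]),   # (z, x)
    z = t(arr[, , k, drop = TRUE]))   # (y, x)
  list(intensity = pick(volume$intensity), labels = pick(volume$labels),
       index = k)
}

#' Source frame dominating a voxel
#'
#' Returns the index of the frame whose deposits dominate the voxel, for
#' frame-by-frame navigation from a 3D finding back to the 2D image to
#' correct. Voxels never touched by any frame return `NA`.
#'
#' @param volume A `us_volume`.
#' @param voxel Length-3 integer voxel index `(i, j, k)`.
#' @return Integer frame index, or `NA_integer_` for a no-data voxel.
#' @export
frame_at <- function(volume, voxel) {
  stopifnot(inherits(volume, "us_volume"))
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > volume$dims))
    stop("voxel index out of bounds", call. = FALSE)
  volume$provenance[voxel[1], voxel[2], voxel[3]]
}

#' Flag frames whose masks are inconsistent with their neighbours in 3D
#'
#' Automates the visual 3D quality check: a mask that does not fit the
#' reconstructed object shows up as a frame whose per-class masks disagree
#' with the masks of nearby frames once those are projected into its image
#' plane. For each frame f and class k the score is the *maximum* Dice
#' overlap between frame f's class-k mask and the pose-projected
#' (nearest-neighbour resampled) class-k mask of each frame within `window`
#' frames of f; taking the maximum means a frame is only penalised when it
#' agrees with none of its neighbours, so an erroneous neighbour cannot drag
#' down a correct frame. A class absent from both frames scores 1 for that
#' neighbour. Frames with any class score below `threshold` are flagged.
#'
#' @param sweep A `us_sweep` (or a list with `labels`, `poses`,
#'   `pixel_spacing`).
#' @param threshold Flagging threshold in \[0, 1\] (default 0.9).
#' @param window Neighbourhood half-width in frames (default 3).
#' @return An object of class `qc_report`: list with `scores` (n x 5 matrix),
#'   `flagged` (integer frame indices), `threshold`, `window`. A single-frame
#'   sweep yields an empty report.
#' @export
flag_inconsistent_frames <- function(sweep, threshold = 0.9, window = 3L) {
  labels <- sweep$labels; poses <- sweep$poses
  s <- sweep$pixel_spacing
  if (is.null(labels) || is.null(poses) || is.null(s))
    stop("sweep must carry labels, poses and pixel_spacing", call. = FALSE)
  threshold <- check_prob(threshold, "threshold")
  window <- check_count(window, "window", 1L)
  n <- length(labels)
  cls <- periseg_classes()
  if (n < 2L)
    return(structure(list(scores = matrix(numeric(0), 0, 5,
                                          dimnames = list(NULL, cls)),
                          flagged = integer(0), threshold = threshold,
                          window = window), class = "qc_report"))
  H <- nrow(labels[[1]]); W <- ncol(labels[[1]])
  grid <- rbind(rep((seq_len(W) - 1) * s, each = H),
                rep((seq_len(H) - 1) * s, times = W),
                0)
  project_neighbour <- function(f, g) {
    world <- poses[[f]]$rotation %*% grid + poses[[f]]$translation
    local <- crossprod(poses[[g]]$rotation, world - poses[[g]]$translation)
    cc <- as.integer(round(local[1, ] / s)) + 1L
    rr <- as.integer(round(local[2, ] / s)) + 1L
    ok <- cc >= 1L & cc <= W & rr >= 1L & rr <= H
    out <- integer(H * W)
    out[ok] <- labels[[g]][cbind(rr[ok], cc[ok])]
    matrix(out, H, W)
  }
  dice <- function(A, B) {
    sa <- sum(A); sb <- sum(B)
    if (sa + sb == 0) 1 else 2 * sum(A & B) / (sa + sb)
  }
  scores <- matrix(NA_real_, n, 5L, dimnames = list(NULL, cls))
  for (f in seq_len(n)) {
    nb <- setdiff(max(1L, f - window):min(n, f + window), f)
    best <- rep(0, 5L)
    for (g in nb) {
      proj <- project_neighbour(f, g)
      for (k in 1:5)
        best[k] <- max(best[k], dice(labels[[f]] == k, proj == k))
    }
    scores[f, ] <- best
  }
  flagged <- which(apply(scores < threshold, 1L, any))
  structure(list(scores = scores, flagged = flagged, threshold = threshold,
                 window = window), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d frames scored, threshold %.2f (window +/-%d)\n",
              nrow(x$scores), x$threshold, x$window))
  if (length(x$flagged))
    cat("  flagged frames:", paste(x$flagged, collapse = ", "), "\n")
  else cat("  no frames flagged\n")
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  df <- as.data.frame(x$scores)
  df$frame_index <- seq_len(nrow(df))
  df$flagged <- df$frame_index %in% x$flagged
  df[, c("frame_index", periseg_classes(), "flagged")]
}

#' Write a QC report as CSV and JSON
#'
#' @param report A `qc_report`.
#' @param prefix Output path prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return `prefix`, invisibly.
#' @export
write_qc_report <- function(report, prefix) {
  df <- as.data.frame(report)
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(threshold = report$threshold,
                            window = report$window,
                            flagged = report$flagged,
                            scores = df),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Correct one frame's labels and recompound the volume
#'
#' Replaces the label matrix of a single frame, appends an entry to the
#' sweep's audit log, and recompounds the 3D volume so the correction can be
#' re-evaluated in 3D — the correction loop of the annotation workflow.
#'
#' @param sweep A `us_sweep` (with `labels`, `poses`, `frames`).
#' @param frame_index Frame to correct.
#' @param corrected Corrected label matrix (same shape, codes 0..5).
#' @param voxel_spacing Voxel size for the recompounded volume (defaults to
#'   the sweep pixel spacing).
#' @return List with `sweep` (updated, audit log in `$audit`) and `volume`
#'   (recompounded `us_volume`).
#' @export
apply_correction <- function(sweep, frame_index, corrected,
                             voxel_spacing = sweep$pixel_spacing) {
  labels <- sweep$labels
  frame_index <- check_count(frame_index, "frame_index", 1L)
  if (frame_index > length(labels))
    stop("frame_index out of range", call. = FALSE)
  check_label_matrix(corrected, dim(labels[[frame_index]]))
  changed <- sum(labels[[frame_index]] != corrected)
  sweep$labels[[frame_index]] <- corrected
  entry <- data.frame(seq = if (is.null(sweep$audit)) 1L
                            else nrow(sweep$audit) + 1L,
                      time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      frame_index = frame_index, pixels_changed = changed)
  sweep$audit <- rbind(sweep$audit, entry)
  volume <- compound_volume(sweep$frames, sweep$poses, sweep$labels,
                            voxel_spacing = voxel_spacing,
                            pixel_spacing = sweep$pixel_spacing)
  list(sweep = sweep, volume = volume)
}

#' Export a volume's intensity and label channels as NIfTI files
#'
#' @param volume A `us_volume`.
#' @param prefix Output path prefix; `<prefix>_intensity.nii.gz` and
#'   `<prefix>_labels.nii.gz` are written, with the voxel spacing in the
#'   header. Untouched intensity voxels are written as 0.
#' @return Character vector of the two paths, invisibly.
#' @export
write_volume_nifti <- function(volume, prefix) {
  stopifnot(inherits(volume, "us_volume"))
  vi <- volume$intensity
  vi[is.na(vi)] <- 0
  pi_ <- paste0(prefix, "_intensity.nii.gz")
  pl <- paste0(prefix, "_labels.nii.gz")
  ni <- RNifti::asNifti(vi)
  RNifti::pixdim(ni) <- rep(volume$voxel_spacing, 3)
  RNifti::writeNifti(ni, pi_)
  nl <- RNifti::asNifti(volume$labels * 1)
  RNifti::pixdim(nl) <- rep(volume$voxel_spacing, 3)
  RNifti::writeNifti(nl, pl)
  invisible(c(pi_, pl))
}
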