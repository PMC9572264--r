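#' Configuration for the synthetic periodontal sweep phantom
#'
#' The phantom emulates the statistical structure of freehand periodontal
#' ultrasound sweeps: tall 375x735 grayscale frames whose anatomy occupies the
#' upper half; gingiva and cortical bone present in every frame; crown and
#' root present only on "dental" frames (a little over half of the sweep, the
#' remainder being inter-dental gaps); a thin periodontal pocket on about 10%
#' of all frames; multiplicative speckle noise with a Gaussian post-blur; and
#' probe poses advancing by a fixed step along the sweep axis with small
#' smooth perturbations.
#'
#' Frame-to-frame anatomy is organised in contiguous runs ("segments"):
#' a sweep alternates dental segments (tooth visible, 6-12 frames) and
#' inter-dental segments, whose mean length is chosen so that the long-run
#' fraction of inter-dental frames equals `interdental_fraction`. Geometry is
#' constant within a segment and redrawn between segments, as in a slow
#' physical sweep across an arch. Each dental segment may carry a pocket on a
#' short sub-run of frames; the per-segment pocket probability is calibrated
#' so that the marginal per-frame pocket probability equals
#' `pocket_prevalence`.
#'
#' @param frame_width,frame_height Frame size in pixels (>= 64 each).
#' @param n_frames Number of frames in the sweep.
#' @param interdental_fraction Long-run fraction of frames without crown/root.
#' @param pocket_prevalence Marginal probability that a frame contains a
#'   pocket; must not exceed `1 - interdental_fraction` (pockets only occur on
#'   dental frames).
#' @param class_intensity_means Named mean intensities (0-255) for
#'   `background` plus the five classes of [periseg_classes()].
#' @param noise_amplitude Multiplicative speckle amplitude: a pixel with clean
#'   intensity I is drawn as I*(1 + noise_amplitude*eta), eta ~ N(0,1).
#' @param blur_sigma Gaussian post-blur standard deviation in pixels.
#' @param pixel_spacing Isotropic pixel size in mm.
#' @param pose_step Probe advance per frame along the sweep axis, in mm.
#' @param rng_seed Integer seed; the whole sweep is deterministic given it.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @export
#' @examples
#' cfg <- phantom_config(n_frames = 5, frame_width = 96, frame_height = 192)
phantom_config <- function(frame_width = 375L, frame_height = 735L,
                           n_frames = 20L,
                           interdental_fraction = 0.45,
                           pocket_prevalence = 0.10,
                           class_intensity_means = c(background = 30, bone = 200,
                                                     crown = 220, gingiva = 90,
                                                     pocket = 45, root = 160),
                           noise_amplitude = 0.35, blur_sigma = 1.5,
                           pixel_spacing = 0.05, pose_step = 0.2,
                           rng_seed = 1L) {
  frame_width <- check_count(frame_width, "frame_width", 64L)
  frame_height <- check_count(frame_height, "frame_height", 64L)
  n_frames <- check_count(n_frames, "n_frames", 1L)
  interdental_fraction <- check_prob(interdental_fraction, "interdental_fraction")
  pocket_prevalence <- check_prob(pocket_prevalence, "pocket_prevalence")
  if (interdental_fraction < 1 && pocket_prevalence > 1 - interdental_fraction)
    stop("pocket_prevalence cannot exceed 1 - interdental_fraction ",
         "(pockets occur only on dental frames)", call. = FALSE)
  need <- c("background", periseg_classes())
  if (!all(need %in% names(class_intensity_means)))
    stop("class_intensity_means must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  class_intensity_means <- class_intensity_means[need]
  if (any(class_intensity_means < 0 | class_intensity_means > 255))
    stop("class_intensity_means must lie in [0, 255]", call. = FALSE)
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0", call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (pixel_spacing <= 0 || pose_step <= 0)
    stop("pixel_spacing and pose_step must be positive", call. = FALSE)
  rng_seed <- check_count(rng_seed, "rng_seed", 0L)
  if (noise_amplitude > 0) {
    mm <- sort(unname(class_intensity_means))
    gaps <- diff(mm)
    # speckle sd on the dimmer class of each adjacent pair, in intensity units
    if (any(gaps <= 2 * noise_amplitude * mm[-length(mm)]))
      warning("some class intensity means are separated by less than twice ",
              "the speckle amplitude; classes may be hard to distinguish")
  }
  structure(list(frame_width = frame_width, frame_height = frame_height,
                 n_frames = n_frames,
                 interdental_fraction = interdental_fraction,
                 pocket_prevalence = pocket_prevalence,
                 class_intensity_means = class_intensity_means,
                 noise_amplitude = noise_amplitude, blur_sigma = blur_sigma,
                 pixel_spacing = pixel_spacing, pose_step = pose_step,
                 rng_seed = rng_seed),
            class = "phantom_config")
}

# ---- segment plan -----------------------------------------------------------

# Dental segments are 6-12 frames; inter-dental gap lengths are drawn around
# g* = 9 * f / (1 - f) so the long-run inter-dental fraction is f. Pockets
# cover a sub-run of L frames in a dental segment with probability q, with
# L and q calibrated so the marginal per-frame pocket probability is p:
# expected pocket frames per dental segment m = p * 9 / (1 - f), L = ceil(m)
# (at least 2 frames so a pocket is never an isolated one-frame event),
# q = m / L.
plan_segments <- function(cfg) {
  n <- cfg$n_frames
  f <- cfg$interdental_fraction
  p <- cfg$pocket_prevalence
  dental_len <- function() sample(6:12, 1L)
  gap_len <- if (f <= 0) function() 0L else if (f >= 1) function() n else {
    gstar <- max(2, round(9 * f / (1 - f)))
    function() sample(max(2L, gstar - 2L):(gstar + 2L), 1L)
  }
  if (f < 1 && p > 0) {
    m <- p * 9 / (1 - f)
    pocket_len <- max(2L, as.integer(ceiling(m)))
    pocket_q <- m / pocket_len
  } else {
    pocket_len <- 0L; pocket_q <- 0
  }
  segs <- list()
  pos <- 1L
  dental <- if (f <= 0) TRUE else if (f >= 1) FALSE else runif(1) >= f
  while (pos <= n) {
    len <- if (dental) dental_len() else gap_len()
    if (len < 1L) { dental <- !dental; next }
    len <- min(len, n - pos + 1L)
    pocket_from <- NA_integer_; pocket_to <- NA_integer_
    if (dental && pocket_len > 0L && len >= pocket_len && runif(1) < pocket_q) {
      start <- sample(seq_len(len - pocket_len + 1L), 1L)
      pocket_from <- pos + start - 1L
      pocket_to <- pocket_from + pocket_len - 1L
    }
    segs[[length(segs) + 1L]] <- data.frame(
      start = pos, end = pos + len - 1L, dental = dental,
      pocket_from = pocket_from, pocket_to = pocket_to)
    pos <- pos + len
    if (f > 0 && f < 1) dental <- !dental
  }
  do.call(rbind, segs)
}

# ---- geometry ---------------------------------------------------------------

# Per-segment anatomy parameters, drawn once per segment. All structures stay
# in the upper half of the frame (rows <= H/2). Layout (fractions of the
# upper-half height H2 and the width W): crown = bright ellipse near the top,
# root = tapered region beneath it, gingiva = soft-tissue band across the
# frame, cortical bone = thin bright band under the gingiva, pocket = a
# <=5 px sliver hugging the root's left edge inside the gingival band.
draw_segment_geometry <- function(cfg, dental) {
  H2 <- floor(cfg$frame_height / 2)
  W <- cfg$frame_width
  g <- list(dental = dental,
            ging_top = round(H2 * 0.30 * runif(1, 0.95, 1.05)),
            ging_bot = round(H2 * 0.62 * runif(1, 0.95, 1.05)),
            bone_top = round(H2 * 0.64),
            bone_bot = round(H2 * 0.68))
  g$bone_top <- max(g$bone_top, g$ging_bot + 1L)
  g$bone_bot <- max(g$bone_bot, g$bone_top + max(2L, round(H2 * 0.02)))
  if (dental) {
    g$cx <- round(W * runif(1, 0.42, 0.58))
    g$crown_r <- round(H2 * 0.16 * runif(1, 0.9, 1.1))
    g$crown_ar <- round(H2 * 0.10 * runif(1, 0.85, 1.15))
    g$crown_ac <- round(W * 0.20 * runif(1, 0.85, 1.15))
    g$root_top <- round(H2 * 0.28 * runif(1, 0.9, 1.1))
    g$root_bot <- round(H2 * 0.85 * runif(1, 0.95, 1.0))
    g$root_hw_top <- round(W * 0.12 * runif(1, 0.85, 1.15))
    g$root_hw_bot <- max(3L, round(W * 0.03))
    g$pocket_top <- max(g$root_top + 2L, g$ging_top + 2L)
    g$pocket_bot <- min(g$ging_bot - 2L, round(H2 * 0.58))
    g$pocket_w <- max(2L, round(W * 0.013))
  }
  g
}

# Render the label matrix for one segment geometry. Painting order implements
# the class priority crown > root > pocket > bone > gingiva.
render_labels <- function(cfg, g, with_pocket) {
  H <- cfg$frame_height; W <- cfg$frame_width
  lab <- matrix(0L, H, W)
  R <- row(lab); C <- col(lab)
  lab[R >= g$ging_top & R <= g$ging_bot] <- 3L
  lab[R >= g$bone_top & R <= g$bone_bot] <- 1L
  if (g$dental) {
    # tapered root: half-width interpolates linearly from top to bottom
    frac <- (R - g$root_top) / max(1L, g$root_bot - g$root_top)
    hw <- g$root_hw_top + frac * (g$root_hw_bot - g$root_hw_top)
    in_root <- R >= g$root_top & R <= g$root_bot & abs(C - g$cx) <= hw
    if (with_pocket) {
      left_edge <- g$cx - hw
      in_pocket <- R >= g$pocket_top & R <= g$pocket_bot &
        C < left_edge & C >= left_edge - g$pocket_w
      lab[in_pocket] <- 4L
    }
    lab[in_root] <- 5L
    in_crown <- ((R - g$crown_r) / g$crown_ar)^2 +
      ((C - g$cx) / g$crown_ac)^2 <= 1
    lab[in_crown] <- 2L
  }
  lab
}

render_intensity <- function(cfg, lab) {
  means <- cfg$class_intensity_means
  img <- matrix(means[lab + 1L], nrow(lab), ncol(lab))
  if (cfg$noise_amplitude > 0)
    img <- img * (1 + cfg$noise_amplitude * matrix(rnorm(length(img)),
                                                   nrow(lab), ncol(lab)))
  if (cfg$blur_sigma > 0) img <- cpp_gauss_blur(img, cfg$blur_sigma)
  img[img < 0] <- 0; img[img > 255] <- 255
  img
}

# Exact small rotation about the three axes; smooth sinusoidal perturbations
# keep in-plane shifts sub-pixel so consecutive frames stay aligned.
make_poses <- function(cfg) {
  n <- cfg$n_frames
  s <- cfg$pixel_spacing
  per <- runif(3, 15, 30); ph <- runif(3, 0, 2 * pi)
  per_r <- runif(3, 15, 30); ph_r <- runif(3, 0, 2 * pi)
  amp_xy <- 0.15 * s
  amp_z <- 0.05 * cfg$pose_step
  amp_rot <- 0.003
  rot1 <- function(ax, a) {
    ca <- cos(a); sa <- sin(a)
    switch(ax,
           x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
           y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
           z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3))
  }
  lapply(seq_len(n), function(f) {
    tr <- c(amp_xy * sin(2 * pi * f / per[1] + ph[1]),
            amp_xy * sin(2 * pi * f / per[2] + ph[2]),
            (f - 1) * cfg$pose_step + amp_z * sin(2 * pi * f / per[3] + ph[3]))
    ang <- amp_rot * sin(2 * pi * f / per_r + ph_r)
    Rm <- rot1("z", ang[3]) %*% rot1("y", ang[2]) %*% rot1("x", ang[1])
    list(rotation = Rm, translation = tr, frame_index = f)
  })
}

# ---- sweep generation -------------------------------------------------------

#' Generate a synthetic periodontal ultrasound sweep
#'
#' Produces `n_frames` aligned triples of intensity frame, per-pixel label
#' matrix (codes 0..5) and rigid probe pose, with the segment/run structure
#' described in [phantom_config()]. The sweep is bit-reproducible given the
#' configured seed.
#'
#' @param config A [phantom_config()].
#' @param content `"full"` returns frames, labels and poses; `"labels"` skips
#'   the intensity rendering; `"presence"` additionally drops the label
#'   matrices, keeping only the per-frame class presence table (memory-light
#'   for long sweeps).
#'
#' @return An object of class `us_sweep`: a list with elements `frames` (list
#'   of numeric matrices, 0-255), `labels` (list of integer matrices),
#'   `poses` (list of `rotation`/`translation`/`frame_index`), `presence`
#'   (n x 5 logical matrix, one column per class), `dental` (logical),
#'   `segments` (data frame), `pixel_spacing`, `source_id` and `config`.
#'   Elements not requested are `NULL`.
#' @export
#' @examples
#' sw <- generate_sweep(phantom_config(n_frames = 4, frame_width = 96,
#'                                     frame_height = 192, rng_seed = 7))
#' dim(sw$frames[[1]])
#' colSums(sw$presence)
generate_sweep <- function(config, content = c("full", "labels", "presence")) {
  if (!inherits(config, "phantom_config"))
    stop("'config' must be a phantom_config object", call. = FALSE)
  content <- match.arg(content)
  with_seed(config$rng_seed, {
    segs <- plan_segments(config)
    poses <- make_poses(config)
    n <- config$n_frames
    labels <- vector("list", n)
    frames <- if (content == "full") vector("list", n) else NULL
    presence <- matrix(FALSE, n, 5L, dimnames = list(NULL, periseg_classes()))
    dental <- logical(n)
    for (si in seq_len(nrow(segs))) {
      seg <- segs[si, ]
      geom <- draw_segment_geometry(config, seg$dental)
      lab_plain <- render_labels(config, geom, with_pocket = FALSE)
      lab_pocket <- if (!is.na(seg$pocket_from))
        render_labels(config, geom, with_pocket = TRUE) else NULL
      for (f in seg$start:seg$end) {
        has_pocket <- !is.na(seg$pocket_from) &&
          f >= seg$pocket_from && f <= seg$pocket_to
        lab <- if (has_pocket) lab_pocket else lab_plain
        dental[f] <- seg$dental
        presence[f, ] <- tabulate(lab[lab > 0L], 5L) > 0L
        if (content == "full") frames[[f]] <- render_intensity(config, lab)
        if (content != "presence") labels[[f]] <- lab
      }
    }
    structure(list(frames = frames,
                   labels = if (content != "presence") labels else NULL,
                   poses = poses, presence = presence, dental = dental,
                   segments = segs, pixel_spacing = config$pixel_spacing,
                   source_id = sprintf("phantom-seed%d", config$rng_seed),
                   config = config),
              class = "us_sweep")
  })
}

#' @export
print.us_sweep <- function(x, ...) {
  cat(sprintf("us_sweep: %d frames of %dx%d px (%.3f mm/px), source '%s'\n",
              x$config$n_frames, x$config$frame_height, x$config$frame_width,
              x$pixel_spacing, x$source_id))
  cat(sprintf("  dental frames: %d/%d; class presence: %s\n",
              sum(x$dental), length(x$dental),
              paste(sprintf("%s %d", colnames(x$presence),
                            colSums(x$presence)), collapse = ", ")))
  invisible(x)
}

#' Corrupt ground-truth label matrices to emulate annotation errors
#'
#' Emulates the mistakes of a low-experience annotator that the 3D quality
#' check is designed to catch: on a randomly chosen fraction of frames, one
#' present class mask is either dilated, eroded (disc structuring element) or
#' rigidly shifted by `severity` pixels. Dilated/shifted pixels overwrite
#' other classes, as an erroneous hand mask would. A corrupted mask is always
#' changed but never removed outright: if the drawn operation would empty the
#' mask (eroding a structure thinner than `severity`) or leave it identical,
#' the corruption falls back to a shift and then to a dilation, so every
#' corrupted frame still carries a (mis-traced) annotation of that class.
#' Untouched frames are returned bit-identical.
#'
#' @param labels List of integer label matrices (codes 0..5), or a `us_sweep`.
#' @param error_rate Fraction of frames to corrupt (rounded to a count).
#' @param severity Corruption magnitude in pixels (>= 1).
#' @param rng_seed Integer seed for frame/class/operation draws.
#'
#' @return A list with `labels` (corrupted list, same length/order) and
#'   `corrupted` (sorted indices of altered frames).
#' @export
#' @examples
#' sw <- generate_sweep(phantom_config(n_frames = 5, frame_width = 96,
#'                                     frame_height = 192, rng_seed = 3),
#'                      content = "labels")
#' out <- corrupt_labels(sw$labels, error_rate = 0.4, severity = 5, rng_seed = 9)
#' out$corrupted
corrupt_labels <- function(labels, error_rate, severity, rng_seed) {
  if (inherits(labels, "us_sweep")) labels <- labels$labels
  if (!is.list(labels) || length(labels) == 0L)
    stop("'labels' must be a nonempty list of label matrices", call. = FALSE)
  error_rate <- check_prob(error_rate, "error_rate")
  severity <- check_count(severity, "severity", 1L)
  rng_seed <- check_count(rng_seed, "rng_seed", 0L)
  n <- length(labels)
  k <- round(error_rate * n)
  if (k == 0L) return(list(labels = labels, corrupted = integer(0)))
  with_seed(rng_seed, {
    idx <- sort(sample.int(n, k))
    brush <- EBImage::makeBrush(2L * severity + 1L, shape = "disc")
    out <- labels
    for (f in idx) {
      lab <- out[[f]]
      present <- which(tabulate(lab[lab > 0L], 5L) > 0L)
      if (length(present) == 0L) {
        # degenerate all-background frame: spurious blob annotation
        lab[disc_mask(nrow(lab), ncol(lab),
                      nrow(lab) %/% 4L, ncol(lab) %/% 2L, severity)] <- 3L
        out[[f]] <- lab
        next
      }
      cls <- if (length(present) == 1L) present else sample(present, 1L)
      op <- sample(c("dilate", "erode", "shift"), 1L)
      m <- lab == cls
      apply_op <- function(op) switch(op,
        dilate = EBImage::dilate(m * 1, brush) > 0,
        erode = EBImage::erode(m * 1, brush) > 0,
        shift = {
          dir <- sample(1:8, 1L)
          dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)[dir] * severity
          dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)[dir] * severity
          shift_mask(m, dr, dc)
        })
      newm <- apply_op(op)
      # never delete the annotation outright, and always change it
      for (fallback in c("shift", "dilate")) {
        if (any(newm) && !identical(newm, m)) break
        newm <- apply_op(fallback)
      }
      lab[m] <- 0L
      lab[newm] <- cls
      out[[f]] <- lab
    }
    list(labels = out, corrupted = idx)
  })
}

shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  src_r <- seq_len(H) - dr; src_c <- seq_len(W) - dc
  ok_r <- src_r >= 1L & src_r <= H; ok_c <- src_c >= 1L & src_c <= W
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# ---- sweep IO ---------------------------------------------------------------

#' Write a sweep to disk as PNG frames, per-class mask PNGs, poses and manifest
#'
#' Frames become 8-bit grayscale `frames/f####.png`; each present class k gets
#' a binary mask `masks/f####_<class>.png` (0/255); poses go to `poses.csv`
#' with columns `frame_index,r11..r33,tx,ty,tz` (rotation in row-major order);
#' the configuration is recorded in `manifest.yaml`.
#'
#' @param sweep A `us_sweep` from [generate_sweep()] (content `"full"`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "us_sweep"))
  if (is.null(sweep$frames)) stop("sweep has no rendered frames", call. = FALSE)
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  cls <- periseg_classes()
  n <- length(sweep$frames)
  for (f in seq_len(n)) {
    png::writePNG(round(sweep$frames[[f]]) / 255,
                  file.path(dir, "frames", sprintf("f%04d.png", f)))
    lab <- sweep$labels[[f]]
    for (k in which(sweep$presence[f, ]))
      png::writePNG((lab == k) * 1,
                    file.path(dir, "masks", sprintf("f%04d_%s.png", f, cls[k])))
  }
  po <- t(vapply(sweep$poses, function(p)
    c(p$frame_index, as.vector(t(p$rotation)), p$translation), numeric(13)))
  colnames(po) <- c("frame_index", "r11", "r12", "r13", "r21", "r22", "r23",
                    "r31", "r32", "r33", "tx", "ty", "tz")
  write.csv(as.data.frame(po), file.path(dir, "poses.csv"), row.names = FALSE)
  cfg <- sweep$config
  yaml::write_yaml(list(source_id = sweep$source_id,
                        n_frames = n,
                        pixel_spacing = sweep$pixel_spacing,
                        dental = as.logical(sweep$dental),
                        config = lapply(unclass(cfg), function(v)
                          if (is.numeric(v)) as.list(as.numeric(v)) else v)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a sweep directory written by [write_sweep()]
#'
#' @param dir Directory containing `frames/`, `masks/`, `poses.csv`.
#' @return A list with `frames` (0-255 matrices), `labels` (codes 0..5,
#'   reassembled from the mask PNGs), `poses` and `pixel_spacing`.
#' @export
read_sweep <- function(dir) {
  ffiles <- sort(list.files(file.path(dir, "frames"), "\\.png$",
                            full.names = TRUE))
  if (length(ffiles) == 0L) stop("no frames found in ", dir, call. = FALSE)
  frames <- lapply(ffiles, function(p) png::readPNG(p) * 255)
  cls <- periseg_classes()
  labels <- lapply(seq_along(ffiles), function(f) {
    stem <- sub("\\.png$", "", basename(ffiles[f]))
    lab <- matrix(0L, nrow(frames[[f]]), ncol(frames[[f]]))
    for (k in seq_along(cls)) {
      mp <- file.path(dir, "masks", sprintf("%s_%s.png", stem, cls[k]))
      if (file.exists(mp)) lab[png::readPNG(mp) > 0.5] <- k
    }
    lab
  })
  po <- read.csv(file.path(dir, "poses.csv"))
  poses <- lapply(seq_len(nrow(po)), function(i)
    list(rotation = matrix(as.numeric(po[i, 2:10]), 3, 3, byrow = TRUE),
         translation = as.numeric(po[i, 11:13]),
         frame_index = as.integer(po[i, 1])))
  spacing <- tryCatch(
    yaml::read_yaml(file.path(dir, "manifest.yaml"))$pixel_spacing,
    error = function(e) NULL)
  list(frames = frames, labels = labels, poses = poses,
       pixel_spacing = if (is.null(spacing)) NA_real_ else as.numeric(spacing))
}
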