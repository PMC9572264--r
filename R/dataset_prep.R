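#' Extract frames from a grayscale DICOM file to 8-bit PNGs
#'
#' Each stored frame becomes one 8-bit grayscale PNG, in acquisition order.
#' 8-bit input is written pixel-identically; deeper input is rescaled
#' affinely from the file's stored intensity range to 0..255.
#'
#' @param dicom_path Path to an uncompressed grayscale DICOM file.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written PNG paths (frame order preserved).
#' @export
extract_frames <- function(dicom_path, out_dir) {
  dc <- read_dicom(dicom_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- tools::file_path_sans_ext(basename(dicom_path))
  rng <- range(unlist(lapply(dc$frames, range)))
  paths <- character(dc$n_frames)
  for (f in seq_len(dc$n_frames)) {
    m <- dc$frames[[f]]
    if (dc$bits > 8L) {
      m <- if (rng[2] > rng[1])
        round((m - rng[1]) / (rng[2] - rng[1]) * 255) else m * 0
    }
    paths[f] <- file.path(out_dir, sprintf("%s_f%03d.png", stem, f - 1L))
    png::writePNG(m / 255, paths[f])
  }
  paths
}

#' Validate and repair a directory of frame and mask PNGs
#'
#' A directory is expected to contain frame images `<stem>.png` and per-class
#' masks `<stem>_<class>.png` (classes from [periseg_classes()]). Uppercase
#' `.PNG` extensions and uppercase class suffixes are repaired by renaming;
#' unreadable files, masks whose shape differs from their frame, masks
#' without a frame, and frames without any valid mask are rejected with a
#' reason. Report-only apart from the renames: nothing is deleted.
#'
#' @param directory Directory to scan.
#' @return An object of class `pairing_report`: list with `valid` (frame
#'   stems that passed, with their valid masks), `repaired` (data frame
#'   `from`/`to`), `rejected` (data frame `file`/`reason`).
#' @export
validate_pairing <- function(directory) {
  files <- list.files(directory)
  cls <- periseg_classes()
  repaired <- data.frame(from = character(), to = character())
  # repair extension/suffix case
  for (f in files) {
    fixed <- f
    if (grepl("\\.png$", fixed, ignore.case = TRUE) &&
        !grepl("\\.png$", fixed))
      fixed <- sub("\\.[Pp][Nn][Gg]$", ".png", fixed)
    stem <- sub("\\.png$", "", fixed)
    m <- regmatches(stem, regexec(paste0("_(", paste(cls, collapse = "|"),
                                         ")$"), tolower(stem)))[[1]]
    if (length(m) == 2L) {
      base <- substr(stem, 1L, nchar(stem) - nchar(m[2]) - 1L)
      fixed <- paste0(base, "_", m[2], ".png")
    }
    if (!identical(fixed, f)) {
      file.rename(file.path(directory, f), file.path(directory, fixed))
      repaired <- rbind(repaired, data.frame(from = f, to = fixed))
    }
  }
  files <- list.files(directory, pattern = "\\.png$")
  is_mask <- grepl(paste0("_(", paste(cls, collapse = "|"), ")\\.png$"), files)
  frame_files <- files[!is_mask]
  mask_files <- files[is_mask]
  rejected <- data.frame(file = character(), reason = character())
  reject <- function(f, why)
    rejected <<- rbind(rejected, data.frame(file = f, reason = why))
  read_try <- function(f) tryCatch(png::readPNG(file.path(directory, f)),
                                   error = function(e) NULL)
  valid <- list()
  for (ff in frame_files) {
    img <- read_try(ff)
    if (is.null(img)) { reject(ff, "unreadable"); next }
    stem <- sub("\\.png$", "", ff)
    mine <- mask_files[startsWith(mask_files, paste0(stem, "_"))]
    good <- character()
    for (mf in mine) {
      mk <- read_try(mf)
      if (is.null(mk)) { reject(mf, "unreadable"); next }
      if (!identical(dim(mk)[1:2], dim(img)[1:2])) {
        reject(mf, "shape mismatch"); next
      }
      good <- c(good, mf)
    }
    if (length(good) == 0L) reject(ff, "no valid masks")
    else valid[[stem]] <- good
  }
  frame_stems <- sub("\\.png$", "", frame_files)
  for (mf in mask_files) {
    stem <- sub(paste0("_(", paste(cls, collapse = "|"), ")\\.png$"), "", mf)
    if (!stem %in% frame_stems) reject(mf, "orphan mask")
  }
  structure(list(valid = valid, repaired = repaired, rejected = rejected),
            class = "pairing_report")
}

#' @export
print.pairing_report <- function(x, ...) {
  cat(sprintf("pairing_report: %d valid frames, %d repaired names, %d rejects\n",
              length(x$valid), nrow(x$repaired), nrow(x$rejected)))
  if (nrow(x$rejected)) print(x$rejected)
  invisible(x)
}

#' Crop/pad a frame or mask to the square training size
#'
#' Ultrasound frames are tall (width 375 x height 735) with all anatomy in
#' the upper half, so the vertical direction is cropped (top-anchored: rows
#' 1..384 are kept) and the horizontal direction is extended by zero-padding
#' on the right to reach 384 x 384.
#'
#' @param x Numeric/integer/logical matrix with at least `size` rows.
#' @param size Output side length (default 384).
#' @return A `size` x `size` matrix of the same storage mode.
#' @export
#' @examples
#' dim(crop_pad(matrix(0, 735, 375)))
crop_pad <- function(x, size = 384L) {
  if (!is.matrix(x)) stop("'x' must be a matrix", call. = FALSE)
  size <- check_count(size, "size", 1L)
  if (nrow(x) < size)
    stop(sprintf("input has %d rows; at least %d required", nrow(x), size),
         call. = FALSE)
  out <- x[seq_len(size), seq_len(min(ncol(x), size)), drop = FALSE]
  if (ncol(out) < size) {
    pad <- matrix(vector(typeof(out), 1L), size, size - ncol(out))
    out <- cbind(out, pad)
  }
  out
}

#' Assemble per-class masks into the 384x384x5 training stack
#'
#' Channels follow the fixed order bone, crown, gingiva, pocket, root;
#' classes without a mask are left all-zero.
#'
#' @param masks Named list of binary `size` x `size` matrices; names must be
#'   a subset of [periseg_classes()]. `NULL` or an empty list gives an
#'   all-zero stack.
#' @param source_frame Optional identifier of the originating frame.
#' @param size Spatial side length (default 384).
#' @return A `mask_stack`: numeric `size` x `size` x 5 array of 0/1 with the
#'   class order as `dimnames` and attribute `source_frame`.
#' @export
build_mask_stack <- function(masks = NULL, source_frame = "", size = 384L) {
  cls <- periseg_classes()
  size <- check_count(size, "size", 1L)
  stack <- array(0, dim = c(size, size, 5L), dimnames = list(NULL, NULL, cls))
  if (!is.null(masks) && length(masks)) {
    if (is.null(names(masks)) || !all(names(masks) %in% cls))
      stop("masks must be named by class: ", paste(cls, collapse = ", "),
           call. = FALSE)
    for (nm in names(masks)) {
      m <- masks[[nm]]
      if (!is.matrix(m) || !identical(dim(m), c(size, size)))
        stop(sprintf("mask '%s' is not %dx%d", nm, size, size), call. = FALSE)
      if (!all(m %in% c(0, 1)))
        stop(sprintf("mask '%s' is not binary", nm), call. = FALSE)
      stack[, , nm] <- m * 1
    }
  }
  structure(stack, class = c("mask_stack", "array"), source_frame = source_frame)
}

#' Write/read a mask stack as a raw binary file with a JSON sidecar
#'
#' The `.bin` file holds the 0/1 voxels as unsigned bytes in column-major
#' order; the `.json` sidecar records the dimensions, the class order and the
#' source frame, making the container self-describing. The round trip is
#' bit-exact.
#'
#' @param stack A `mask_stack` from [build_mask_stack()].
#' @param path Path without extension; `<path>.bin` and `<path>.json` are
#'   written.
#' @return `path`, invisibly (writer); the `mask_stack` (reader).
#' @export
write_mask_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mask_stack"))
  writeBin(as.raw(as.integer(stack)), paste0(path, ".bin"))
  jsonlite::write_json(list(dims = dim(stack),
                            class_order = periseg_classes(),
                            source_frame = attr(stack, "source_frame")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  v <- as.integer(readBin(paste0(path, ".bin"), "raw", n))
  if (length(v) != n) stop("truncated mask stack file", call. = FALSE)
  if (!identical(as.character(meta$class_order), periseg_classes()))
    stop("unexpected class order in sidecar", call. = FALSE)
  stack <- array(as.numeric(v), dim = meta$dims,
                 dimnames = list(NULL, NULL, periseg_classes()))
  structure(stack, class = c("mask_stack", "array"),
            source_frame = meta$source_frame)
}

#' Reproducible train/validation/test split
#'
#' After a deterministic shuffle under `rng_seed`, the first
#' `floor(ratios[1] * N)` files form the training set, the next
#' `floor(ratios[2] * N)` the validation set, and the remainder the test set.
#' With the canonical 0.8/0.1/0.1 ratios this floor/floor/remainder rule
#' reproduces the published dataset sizes (2135 -> 1708/213/214,
#' 3417 -> 2733/341/343).
#'
#' @param files Nonempty character vector.
#' @param ratios Length-3 nonnegative ratios summing to at most 1.
#' @param rng_seed Integer seed for the shuffle.
#' @return An object of class `dataset_split`: list with `train`,
#'   `validation`, `test`, `ratios`, `rng_seed`.
#' @export
#' @examples
#' sp <- split_dataset(sprintf("f%04d.png", 1:2135), rng_seed = 1)
#' lengths(sp[c("train", "validation", "test")])
split_dataset <- function(files, ratios = c(0.8, 0.1, 0.1), rng_seed = 1L) {
  if (length(files) == 0L) stop("'files' is empty", call. = FALSE)
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) > 1 + 1e-9)
    stop("'ratios' must be 3 nonnegative numbers summing to <= 1",
         call. = FALSE)
  rng_seed <- check_count(rng_seed, "rng_seed", 0L)
  n <- length(files)
  shuffled <- with_seed(rng_seed, files[sample.int(n)])
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  structure(list(train = shuffled[seq_len(n_train)],
                 validation = shuffled[n_train + seq_len(n_val)],
                 test = shuffled[-seq_len(n_train + n_val)],
                 ratios = ratios, rng_seed = rng_seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split (seed %d): train %d / validation %d / test %d\n",
              x$rng_seed, length(x$train), length(x$validation),
              length(x$test)))
  invisible(x)
}

#' Write/read split manifests as plain-text file lists
#'
#' One file per subset: `train.txt`, `validation.txt`, `test.txt`.
#'
#' @param split A `dataset_split`.
#' @param dir Output directory.
#' @return `dir` invisibly (writer); a `dataset_split` (reader, with the
#'   ratios/seed it was written from unavailable, set to `NA`).
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "dataset_split"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in c("train", "validation", "test"))
    writeLines(split[[s]], file.path(dir, paste0(s, ".txt")))
  invisible(dir)
}

#' @rdname write_split
#' @export
read_split <- function(dir) {
  out <- lapply(c(train = "train", validation = "validation", test = "test"),
                function(s) readLines(file.path(dir, paste0(s, ".txt"))))
  structure(c(out, list(ratios = NA, rng_seed = NA)), class = "dataset_split")
}
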