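# Minimal DICOM support: uncompressed little-endian grayscale files (explicit
# or implicit VR), single- or multi-frame. This is deliberately a small
# parser for the handful of tags frame extraction needs, not a general DICOM
# implementation.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

#' Read an uncompressed grayscale DICOM file
#'
#' Supports explicit and implicit VR little endian transfer syntaxes with
#' 8- or 16-bit unsigned grayscale pixel data, single- or multi-frame.
#' Compressed or otherwise unsupported files raise a format error.
#'
#' @param path Path to the DICOM file.
#' @return A list with `frames` (list of integer matrices, stored values),
#'   `bits` (8 or 16), `n_frames`, and `transfer_syntax`.
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("format error: not a DICOM part-10 file", call. = FALSE)
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pos <- 133L
  ts <- TS_EXPLICIT_LE
  explicit <- TRUE
  in_meta <- TRUE
  keep <- new.env()
  while (pos + 7L <= length(raw) + 1L) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (in_meta && group != 2L) {
      in_meta <- FALSE
      explicit <- identical(ts, TS_EXPLICIT_LE)
      if (!explicit && !identical(ts, TS_IMPLICIT_LE))
        stop("format error: unsupported transfer syntax ", ts, call. = FALSE)
    }
    if (in_meta || explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); dstart <- pos + 12L
      } else {
        len <- u16(pos + 6L); dstart <- pos + 8L
      }
    } else {
      len <- u32(pos + 4L); dstart <- pos + 8L
    }
    if (len < 0 || len == 4294967295)
      stop("format error: undefined-length element (compressed pixel data?)",
           call. = FALSE)
    key <- sprintf("%04x%04x", group, elem)
    if (key %in% c("00020010", "00280002", "00280008", "00280010", "00280011",
                   "00280100", "00280103", "7fe00010")) {
      assign(key, if (len > 0) raw[dstart:(dstart + len - 1L)] else raw(0),
             envir = keep)
      if (key == "00020010") {
        v <- get(key, envir = keep)
        ts <- trimws(rawToChar(v[v != as.raw(0)]))
      }
    }
    pos <- dstart + len
  }
  val_u16 <- function(key, default = NULL) {
    if (!exists(key, envir = keep)) return(default)
    v <- get(key, envir = keep)
    as.integer(v[1]) + 256L * as.integer(v[2])
  }
  rows <- val_u16("00280010"); cols <- val_u16("00280011")
  bits <- val_u16("00280100", 8L)
  pixrep <- val_u16("00280103", 0L)
  spp <- val_u16("00280002", 1L)
  nfr <- if (exists("00280008", envir = keep))
    as.integer(trimws(rawToChar(get("00280008", envir = keep)))) else 1L
  if (is.null(rows) || is.null(cols) || !exists("7fe00010", envir = keep))
    stop("format error: missing Rows/Columns/PixelData", call. = FALSE)
  if (!bits %in% c(8L, 16L) || pixrep != 0L || spp != 1L)
    stop("format error: only 8/16-bit unsigned grayscale supported",
         call. = FALSE)
  pd <- get("7fe00010", envir = keep)
  npx <- rows * cols * nfr
  vals <- if (bits == 8L) as.integer(pd[seq_len(npx)])
          else readBin(pd, "integer", n = npx, size = 2L, signed = FALSE,
                       endian = "little")
  frames <- lapply(seq_len(nfr), function(f) {
    off <- (f - 1L) * rows * cols
    # DICOM pixel data is row-major (columns vary fastest)
    matrix(vals[(off + 1L):(off + rows * cols)], nrow = rows, byrow = TRUE)
  })
  list(frames = frames, bits = bits, n_frames = nfr, transfer_syntax = ts)
}

#' Write a minimal grayscale DICOM file (testing/fixture helper)
#'
#' Writes an explicit VR little endian part-10 file with just the tags
#' [read_dicom()] consumes. Intended for building synthetic fixtures in tests
#' and examples, not for clinical interchange.
#'
#' @param frames List of integer matrices (equal shapes, nonnegative).
#' @param path Output path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_dicom_gray <- function(frames, path, bits = 8L) {
  stopifnot(is.list(frames), length(frames) >= 1L, bits %in% c(8L, 16L))
  rows <- nrow(frames[[1]]); cols <- ncol(frames[[1]])
  u16r <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  u32r <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  elem_short <- function(g, e, vr, value) {
    c(u16r(g), u16r(e), charToRaw(vr), u16r(length(value)), value)
  }
  elem_long <- function(g, e, vr, value) {
    c(u16r(g), u16r(e), charToRaw(vr), as.raw(c(0, 0)), u32r(length(value)),
      value)
  }
  pad_even <- function(v, pad = as.raw(0)) if (length(v) %% 2) c(v, pad) else v
  ts <- pad_even(charToRaw(TS_EXPLICIT_LE))
  nfr_raw <- pad_even(charToRaw(as.character(length(frames))),
                      charToRaw(" "))
  px <- unlist(lapply(frames, function(m) as.integer(t(m))))
  pd <- if (bits == 8L) as.raw(px)
        else writeBin(as.integer(px), raw(), size = 2L, endian = "little")
  out <- c(raw(128), charToRaw("DICM"),
           elem_short(0x0002L, 0x0010L, "UI", ts),
           elem_short(0x0028L, 0x0002L, "US", u16r(1L)),
           elem_short(0x0028L, 0x0008L, "IS", nfr_raw),
           elem_short(0x0028L, 0x0010L, "US", u16r(rows)),
           elem_short(0x0028L, 0x0011L, "US", u16r(cols)),
           elem_short(0x0028L, 0x0100L, "US", u16r(bits)),
           elem_short(0x0028L, 0x0101L, "US", u16r(bits)),
           elem_short(0x0028L, 0x0103L, "US", u16r(0L)),
           elem_long(0x7fe0L, 0x0010L, if (bits == 8L) "OB" else "OW",
                     pad_even(pd)))
  writeBin(out, path)
  invisible(path)
}
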