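test_that("crop_pad keeps the top 384 rows and zero-pads width to 384", {
  x <- matrix(0, 735, 375)
  expect_identical(dim(crop_pad(x)), c(384L, 384L))

  x[1, 1] <- 7; x[400, 200] <- 9
  out <- crop_pad(x)
  expect_identical(out[1, 1], 7)
  expect_false(any(out == 9))          # row 400 is cropped away
  expect_true(all(out[, 376:384] == 0))

  set.seed(3)
  x <- matrix(runif(735 * 375), 735, 375)
  expect_equal(sum(crop_pad(x)), sum(x[1:384, ]))   # slicing oracle

  expect_error(crop_pad(matrix(0, 100, 375)), "rows")
})

test_that("crop_pad is shape-total and idempotent on the retained region", {
  for (w in c(200, 384, 500)) {
    out <- crop_pad(matrix(1, 400, w))
    expect_identical(dim(out), c(384L, 384L))
    expect_identical(crop_pad(out), out)
  }
  m <- crop_pad(matrix(TRUE, 400, 300))
  expect_true(all(m %in% c(TRUE, FALSE)))
})

test_that("mask stacks have fixed class order, zero-filled absences, and exact IO round trip", {
  empty <- build_mask_stack(NULL)
  expect_identical(dim(empty), c(384L, 384L, 5L))
  expect_true(all(empty == 0))
  expect_identical(dimnames(empty)[[3]], periseg_classes())

  set.seed(5)
  masks <- lapply(periseg_classes(), function(k)
    matrix(as.numeric(runif(384 * 384) < 0.1), 384, 384))
  names(masks) <- periseg_classes()
  st <- build_mask_stack(masks, source_frame = "f0001")
  expect_true(all(apply(st, 3, sum) > 0))
  partial <- build_mask_stack(masks["pocket"], source_frame = "f0002")
  expect_identical(which(apply(partial, 3, sum) > 0), c(pocket = 4L))

  d <- withr::local_tempdir()
  write_mask_stack(st, file.path(d, "s1"))
  back <- read_mask_stack(file.path(d, "s1"))
  expect_identical(unclass(back)[, , ], unclass(st)[, , ])
  expect_identical(attr(back, "source_frame"), "f0001")

  expect_error(build_mask_stack(list(bone = matrix(2, 384, 384))), "binary")
  expect_error(build_mask_stack(list(bone = matrix(0, 10, 10))), "384x384")
  expect_error(build_mask_stack(list(matrix(0, 384, 384))), "named")
})

test_that("the floor/floor/remainder split reproduces the published dataset sizes", {
  sp <- split_dataset(sprintf("f%04d", 1:2135), rng_seed = 1)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 1708L, validation = 213L, test = 214L))
  sp <- split_dataset(sprintf("f%04d", 1:3417), rng_seed = 1)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 2733L, validation = 341L, test = 343L))
  sp <- split_dataset(sprintf("f%02d", 1:10), rng_seed = 1)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 8L, validation = 1L, test = 1L))
})

test_that("splits partition the input and are reproducible under the seed", {
  files <- sprintf("f%03d", 1:57)
  a <- split_dataset(files, rng_seed = 12)
  b <- split_dataset(files, rng_seed = 12)
  c <- split_dataset(files, rng_seed = 13)
  expect_identical(a, b)
  expect_false(identical(a$train, c$train))
  all_a <- c(a$train, a$validation, a$test)
  expect_setequal(all_a, files)
  expect_identical(anyDuplicated(all_a), 0L)
  expect_error(split_dataset(character(0)), "empty")

  d <- withr::local_tempdir()
  write_split(a, d)
  back <- read_split(d)
  expect_identical(back$train, a$train)
  expect_identical(back$test, a$test)
})

test_that("validate_pairing passes clean output, repairs case, and rejects with reasons", {
  d <- withr::local_tempdir()
  img <- matrix(runif(48 * 32), 48, 32)
  png::writePNG(img, file.path(d, "a.png"))
  png::writePNG((img > 0.5) * 1, file.path(d, "a_bone.png"))
  png::writePNG((img > 0.7) * 1, file.path(d, "a_gingiva.png"))
  rep <- validate_pairing(d)
  expect_identical(names(rep$valid), "a")
  expect_identical(nrow(rep$rejected), 0L)

  # uppercase extension is repaired and the pair still counts as valid
  png::writePNG(img, file.path(d, "b.png"))
  file.rename(file.path(d, "a_bone.png"), file.path(d, "b_bone.PNG"))
  rep <- validate_pairing(d)
  expect_true("b" %in% names(rep$valid))
  expect_true("b_bone.PNG" %in% rep$repaired$from)
  expect_true(file.exists(file.path(d, "b_bone.png")))

  # shape-mismatched mask is rejected with the reason
  png::writePNG(matrix(0, 10, 10), file.path(d, "b_root.png"))
  rep <- validate_pairing(d)
  expect_true(any(rep$rejected$file == "b_root.png" &
                  rep$rejected$reason == "shape mismatch"))

  # orphan mask and frame without masks are rejected
  png::writePNG(matrix(0, 48, 32), file.path(d, "zz_crown.png"))
  png::writePNG(img, file.path(d, "lonely.png"))
  rep <- validate_pairing(d)
  expect_true(any(rep$rejected$file == "zz_crown.png" &
                  rep$rejected$reason == "orphan mask"))
  expect_true(any(rep$rejected$file == "lonely.png" &
                  rep$rejected$reason == "no valid masks"))
})

test_that("extract_frames writes one PNG per frame in order, 8-bit pixel-identically", {
  d <- withr::local_tempdir()
  fr <- list(matrix(sample(0:255, 30 * 20, TRUE), 30, 20),
             matrix(sample(0:255, 30 * 20, TRUE), 30, 20),
             matrix(sample(0:255, 30 * 20, TRUE), 30, 20))
  dcm <- file.path(d, "probe.dcm")
  write_dicom_gray(fr, dcm, bits = 8L)
  out <- extract_frames(dcm, file.path(d, "png"))
  expect_length(out, 3)
  expect_identical(basename(out),
                   sprintf("probe_f%03d.png", 0:2))
  for (i in 1:3)
    expect_equal(round(png::readPNG(out[i]) * 255), fr[[i]],
                 ignore_attr = TRUE)
})

test_that("16-bit frames are rescaled affinely from the stored range", {
  d <- withr::local_tempdir()
  m <- matrix(as.integer(seq(100, 4000, length.out = 24 * 16)), 24, 16)
  dcm <- file.path(d, "deep.dcm")
  write_dicom_gray(list(m), dcm, bits = 16L)
  out <- extract_frames(dcm, d)
  got <- round(png::readPNG(out[1]) * 255)
  expected <- round((m - min(m)) / (max(m) - min(m)) * 255)
  expect_equal(got, expected, ignore_attr = TRUE)
})

test_that("the DICOM reader agrees with pydicom-written files and rejects junk", {
  d <- withr::local_tempdir()
  py <- sprintf("
import pydicom, numpy as np
from pydicom.dataset import FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, SecondaryCaptureImageStorage, generate_uid
ds = FileDataset('x', {}, file_meta=FileMetaDataset(), preamble=b'\\x00'*128)
ds.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds.file_meta.MediaStorageSOPClassUID = SecondaryCaptureImageStorage
ds.file_meta.MediaStorageSOPInstanceUID = generate_uid()
ds.Rows, ds.Columns, ds.NumberOfFrames = 6, 5, 2
ds.SamplesPerPixel = 1; ds.PhotometricInterpretation = 'MONOCHROME2'
ds.BitsAllocated = ds.BitsStored = 8; ds.HighBit = 7; ds.PixelRepresentation = 0
arr = np.arange(60, dtype=np.uint8).reshape(2, 6, 5)
ds.PixelData = arr.tobytes()
ds.save_as('%s', write_like_original=False)
", file.path(d, "py.dcm"))
  status <- system2("python", "-", input = py, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  dc <- read_dicom(file.path(d, "py.dcm"))
  expect_identical(dc$n_frames, 2L)
  expect_identical(dc$frames[[1]][1, ], 0:4)
  expect_identical(dc$frames[[2]][6, ], 55:59)

  junk <- file.path(d, "junk.dcm")
  writeBin(as.raw(1:200), junk)
  expect_error(read_dicom(junk), "format error")
})
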