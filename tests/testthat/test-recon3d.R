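test_that("identity poses stepped by the voxel spacing reproduce the frame stack exactly", {
  sw <- small_sweep(5, seed = 4)
  s <- sw$config$pixel_spacing
  vol <- compound_volume(sw$frames, identity_poses(5, s), sw$labels,
                         voxel_spacing = s, pixel_spacing = s)
  expect_identical(vol$dims, c(96L, 192L, 5L))
  for (f in 1:5) {
    sl <- cross_section(vol, "z", (f - 1) * s)
    expect_identical(sl$index, f)
    expect_identical(sl$intensity, sw$frames[[f]])
    expect_equal(sl$labels, sw$labels[[f]], ignore_attr = TRUE)
  }
})

test_that("voxel intensity is the mean of deposits; majority labels break ties low", {
  fr <- list(matrix(100, 4, 3), matrix(200, 4, 3))
  po <- identity_poses(2, 0)        # both frames land on the same voxels
  la <- list(matrix(2L, 4, 3), matrix(5L, 4, 3))
  vol <- compound_volume(fr, po, la, voxel_spacing = 0.1, pixel_spacing = 0.1)
  expect_true(all(vol$intensity == 150))
  expect_true(all(vol$labels == 2L))  # 1-1 tie resolved to the lower code

  # identical frames: mean of equal values is unchanged
  vol2 <- compound_volume(list(fr[[1]], fr[[1]]), po,
                          voxel_spacing = 0.1, pixel_spacing = 0.1)
  expect_true(all(vol2$intensity == 100))
})

test_that("majority vote wins over a single dissenting deposit", {
  fr <- list(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  po <- identity_poses(3, 0)
  la <- list(matrix(3L, 2, 2), matrix(3L, 2, 2), matrix(5L, 2, 2))
  vol <- compound_volume(fr, po, la, voxel_spacing = 1, pixel_spacing = 1)
  expect_true(all(vol$labels == 3L))
  expect_true(all(vol$provenance == 1L))  # 1-1-1 frame tie resolves lowest
})

test_that("a global rigid translation by whole voxels leaves the content unchanged", {
  sw <- small_sweep(4, seed = 6)
  s <- sw$config$pixel_spacing
  po <- identity_poses(4, s)
  po_shift <- lapply(po, function(p) {
    p$translation <- p$translation + c(7 * s, -3 * s, 2 * s)
    p
  })
  v1 <- compound_volume(sw$frames, po, sw$labels, s, s)
  v2 <- compound_volume(sw$frames, po_shift, sw$labels, s, s)
  expect_identical(v1$intensity, v2$intensity)
  expect_identical(v1$labels, v2$labels)
  expect_equal(v2$origin - v1$origin, c(7 * s, -3 * s, 2 * s),
               tolerance = 1e-9)
})

test_that("cross_section honours bounds, including the exact boundary", {
  sw <- small_sweep(3, seed = 4)
  s <- sw$config$pixel_spacing
  vol <- compound_volume(sw$frames, identity_poses(3, s), sw$labels, s, s)
  edge <- cross_section(vol, "z", 2 * s)    # last slab, no error
  expect_identical(edge$index, 3L)
  expect_error(cross_section(vol, "z", 5 * s), "outside")
  xsec <- cross_section(vol, "x", 0)
  expect_identical(dim(xsec$intensity), c(3L, 192L))  # (z, y) orientation
})

test_that("frame_at returns the dominating source frame and flags no-data voxels", {
  fr <- list(matrix(1, 4, 4), matrix(1, 4, 4))
  po <- identity_poses(2, 1)
  vol <- compound_volume(fr, po, voxel_spacing = 1, pixel_spacing = 1)
  expect_identical(frame_at(vol, c(2, 2, 1)), 1L)
  expect_identical(frame_at(vol, c(2, 2, 2)), 2L)
  expect_error(frame_at(vol, c(99, 1, 1)), "bounds")
})

test_that("frames and poses are validated before compounding", {
  fr <- list(matrix(1, 4, 4))
  expect_error(compound_volume(list(), list(), voxel_spacing = 1), "empty")
  expect_error(compound_volume(fr, identity_poses(2, 1), voxel_spacing = 1),
               "equal length")
  bad <- list(list(rotation = matrix(1, 3, 3), translation = c(0, 0, 0),
                   frame_index = 1))
  expect_error(compound_volume(fr, bad, voxel_spacing = 1), "orthonormal")
})

test_that("QC scores clean sweeps at 1 and flags exactly a dilated frame", {
  clean <- flag_inconsistent_frames(
    small_sweep(7, seed = 7, width = 128, height = 256), threshold = 0.9)
  expect_length(clean$flagged, 0)
  expect_true(all(clean$scores >= 0.9))

  # hand-checkable fixture: one anatomical segment, so every clean frame has
  # identical clean company inside the comparison window
  sw <- small_sweep(6, seed = 7, width = 128, height = 256,
                    interdental_fraction = 0, pocket_prevalence = 0)
  m <- sw$labels[[4]] == 3L           # gingiva, present in every frame
  big <- EBImage::dilate(m * 1, EBImage::makeBrush(21, "disc")) > 0
  lab4 <- sw$labels[[4]]; lab4[m] <- 0L; lab4[big] <- 3L
  sw$labels[[4]] <- lab4
  rep <- flag_inconsistent_frames(sw, threshold = 0.9)
  expect_identical(rep$flagged, 4L)
})

test_that("single-frame input yields an empty QC report", {
  sw <- small_sweep(1, seed = 2)
  rep <- flag_inconsistent_frames(sw)
  expect_identical(nrow(rep$scores), 0L)
  expect_length(rep$flagged, 0)
})

test_that("apply_correction changes only the named frame, logs, and clears the flag", {
  sw <- small_sweep(6, seed = 8, width = 128, height = 256)
  original <- sw$labels

  # correcting with the identical mask leaves the volume bit-identical
  s <- sw$config$pixel_spacing
  v0 <- compound_volume(sw$frames, sw$poses, sw$labels, s, s)
  out <- apply_correction(sw, 3L, sw$labels[[3]], voxel_spacing = s)
  expect_identical(out$volume$intensity, v0$intensity)
  expect_identical(out$volume$labels, v0$labels)
  expect_identical(nrow(out$sweep$audit), 1L)

  # corrupt frame 2, confirm flagged, correct it back, confirm clean
  broken <- corrupt_labels(sw$labels[2], error_rate = 1, severity = 12,
                           rng_seed = 5)
  sw$labels[[2]] <- broken$labels[[1]]
  expect_true(2L %in% flag_inconsistent_frames(sw)$flagged)
  fixed <- apply_correction(sw, 2L, original[[2]], voxel_spacing = s)
  expect_false(2L %in% flag_inconsistent_frames(fixed$sweep)$flagged)
  for (f in setdiff(1:6, 2L))
    expect_identical(fixed$sweep$labels[[f]], sw$labels[[f]])

  # two sequential corrections produce two ordered audit entries
  again <- apply_correction(fixed$sweep, 5L, original[[5]], voxel_spacing = s)
  expect_identical(again$sweep$audit$seq, 1:2)
  expect_identical(again$sweep$audit$frame_index[2], 5L)
  expect_error(apply_correction(sw, 99L, original[[2]]), "range")
})

test_that("volumes export to NIfTI with the voxel spacing in the header", {
  sw <- small_sweep(3, seed = 4)
  s <- sw$config$pixel_spacing
  vol <- compound_volume(sw$frames, identity_poses(3, s), sw$labels, s, s)
  d <- withr::local_tempdir()
  paths <- write_volume_nifti(vol, file.path(d, "vol"))
  expect_true(all(file.exists(paths)))
  img <- RNifti::readNifti(paths[1])
  expect_identical(dim(img), vol$dims)
  expect_equal(RNifti::pixdim(img), rep(s, 3), tolerance = 1e-6)
  lab <- RNifti::readNifti(paths[2])
  expect_identical(sort(unique(as.vector(lab))), sort(unique(as.vector(vol$labels))) * 1)
})
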