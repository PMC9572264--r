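# Shared fixture builders. Small frames keep the suite fast; geometry scales
# with the configured frame size.

small_sweep <- function(n, seed, noise = 0, blur = 0, width = 96L,
                        height = 192L, ...) {
  suppressWarnings(generate_sweep(phantom_config(
    n_frames = n, frame_width = width, frame_height = height,
    noise_amplitude = noise, blur_sigma = blur, rng_seed = seed, ...)))
}

# Build the H x W x 5 training stack for one label matrix, cropped/padded to
# `size`.
stack_from_labels <- function(lab, size = 96L) {
  ms <- labels_to_masks(crop_pad(lab, size))
  present <- vapply(ms, any, TRUE)
  build_mask_stack(lapply(ms, function(m) m * 1)[present], size = size)
}

# Exhaustive fixpoint flood fill: scan repeatedly until no pixel changes.
# Deliberately independent of the BFS implementation under test.
oracle_grow <- function(img, seed, T, excl) {
  H <- nrow(img); W <- ncol(img)
  ok <- abs(img - img[seed[1], seed[2]]) <= T & !excl
  reg <- matrix(FALSE, H, W)
  reg[seed[1], seed[2]] <- TRUE
  repeat {
    new <- reg
    new[-1, ] <- new[-1, ] | reg[-H, ]
    new[-H, ] <- new[-H, ] | reg[-1, ]
    new[, -1] <- new[, -1] | reg[, -W]
    new[, -W] <- new[, -W] | reg[, -1]
    new <- new & ok
    new[seed[1], seed[2]] <- TRUE
    if (identical(new, reg)) return(reg)
    reg <- new
  }
}

identity_poses <- function(n, step) {
  lapply(seq_len(n), function(f)
    list(rotation = diag(3), translation = c(0, 0, (f - 1) * step),
         frame_index = f))
}
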