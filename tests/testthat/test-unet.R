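test_that("the parameter count matches a hand-computed layer-by-layer sum", {
  # depth 2, base width 1 (middle width 2), 1 input channel:
  #   enc1: 3x3x1x1+1 = 10, 3x3x1x1+1 = 10
  #   enc2: 3x3x1x2+2 = 20, 3x3x2x2+2 = 38
  #   dec1: up 2x2x2x1+1 = 9, 3x3x2x1+1 = 19, 3x3x1x1+1 = 10
  #   head: 1x1x1x5+5 = 10           -> total 126
  cfg <- unet_config(middle_width = 2, depth = 2)
  expect_identical(unet_param_count(cfg), 126)
  expect_identical(build_unet(cfg)$n_params, 126L)
})

test_that("the built model's tensors sum to the closed-form count at several sizes", {
  for (cfg in list(unet_config(middle_width = 8, depth = 2),
                   unet_config(middle_width = 16, depth = 3),
                   unet_config(middle_width = 64, depth = 4,
                               input_channels = 3))) {
    net <- build_unet(cfg)
    expect_identical(net$n_params,
                     as.integer(unet_param_count(cfg)))
    expect_identical(sum(vapply(net$params, length, 0L)), net$n_params)
  }
})

test_that("doubling every width roughly quadruples the parameter count", {
  c1 <- unet_param_count(unet_config(middle_width = 64, depth = 4))
  c2 <- unet_param_count(unet_config(middle_width = 128, depth = 4))
  expect_gt(c2 / c1, 3.7)
  expect_lt(c2 / c1, 4.0)
})

test_that("dropout placement changes behaviour under training but never the parameter count", {
  counts <- vapply(c("none", "all", "contracting_only"), function(m)
    build_unet(unet_config(middle_width = 8, depth = 2, dropout_mode = m,
                           dropout_rate = 0.5))$n_params, 0L)
  expect_identical(unname(counts), rep(counts[[1]], 3))

  x <- array(runif(16 * 16), c(16, 16, 1))
  net <- build_unet(unet_config(middle_width = 8, depth = 2,
                                dropout_mode = "all", dropout_rate = 0.5,
                                rng_seed = 2))
  set.seed(1); a <- periseg:::unet_forward(net, x, train = TRUE)$logits
  set.seed(2); b <- periseg:::unet_forward(net, x, train = TRUE)$logits
  expect_false(identical(a, b))       # dropout active during training
  c1 <- periseg:::unet_forward(net, x, train = FALSE)$logits
  c2 <- periseg:::unet_forward(net, x, train = FALSE)$logits
  expect_identical(c1, c2)            # inference is deterministic
})

test_that("backpropagated gradients match central finite differences", {
  net <- build_unet(unet_config(middle_width = 8, depth = 3, rng_seed = 3))
  set.seed(4)
  # nudge biases off zero-activation plateaus so no ReLU sits exactly on its kink
  for (nm in grep("b$", names(net$params), value = TRUE))
    net$params[[nm]] <- rnorm(length(net$params[[nm]]), 0.05, 0.05)
  x <- array(runif(8 * 8), c(8, 8, 1))
  y <- array(rbinom(8 * 8 * 5, 1, 0.3), c(8, 8, 5))
  fw <- periseg:::unet_forward(net, x, train = TRUE)
  g <- periseg:::unet_backward(net, fw$cache,
                               periseg:::bce_loss_grad(fw$logits, y)$grad)
  loss_at <- function(n) periseg:::bce_loss_grad(
    periseg:::unet_forward(n, x, FALSE)$logits, y)$loss
  eps <- 1e-6
  for (nm in names(net$params)) {
    for (q in sample(length(net$params[[nm]]), min(3, length(net$params[[nm]])))) {
      up <- net; up$params[[nm]][q] <- up$params[[nm]][q] + eps
      dn <- net; dn$params[[nm]][q] <- dn$params[[nm]][q] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][q]),
                1e-4 * max(1, abs(num)))
    }
  }
})

test_that("a zero learning rate leaves the parameters unchanged", {
  sw <- small_sweep(1, seed = 5, noise = 0.1, blur = 1)
  item <- list(image = crop_pad(sw$frames[[1]], 96L),
               mask = unclass(stack_from_labels(sw$labels[[1]])))
  net <- build_unet(unet_config(middle_width = 8, depth = 2,
                                learning_rate = 0, epochs = 1))
  trained <- train_unet(net, list(item))
  expect_identical(trained$params, net$params)
})

test_that("training overfits a single phantom frame to high IoU with decreasing loss", {
  sw <- small_sweep(1, seed = 5, noise = 0.1, blur = 1)
  item <- list(image = crop_pad(sw$frames[[1]], 96L),
               mask = unclass(stack_from_labels(sw$labels[[1]])))
  cfg <- unet_config(middle_width = 16, depth = 3, learning_rate = 1e-2,
                     epochs = 150, rng_seed = 1)
  net <- train_unet(build_unet(cfg), list(item))
  expect_lt(mean(tail(net$history$loss, 10)), mean(head(net$history$loss, 10)))
  pred <- predict(net, item$image)
  expect_gt(mean_present_iou(pred, item$mask), 0.9)
})

test_that("training is reproducible under the configured seed", {
  sw <- small_sweep(2, seed = 6, noise = 0.1, blur = 1)
  items <- lapply(1:2, function(f)
    list(image = crop_pad(sw$frames[[f]], 96L),
         mask = unclass(stack_from_labels(sw$labels[[f]]))))
  cfg <- unet_config(middle_width = 8, depth = 2, learning_rate = 5e-3,
                     epochs = 3, rng_seed = 11)
  a <- train_unet(build_unet(cfg), items)
  b <- train_unet(build_unet(cfg), items)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("predictions are 5-channel, binary, and never overlap across channels", {
  net <- build_unet(unet_config(middle_width = 8, depth = 2, rng_seed = 1))
  img <- matrix(runif(32 * 32), 32, 32)
  pred <- predict(net, img)
  expect_identical(dim(pred), c(32L, 32L, 5L))
  expect_true(all(pred %in% c(0, 1)))
  expect_true(all(apply(pred, c(1, 2), sum) <= 1))

  # force all sigmoids below 0.5: every pixel must be background
  net$params[["head.w"]][] <- 0
  net$params[["head.b"]][] <- -5
  expect_true(all(predict(net, img) == 0))
  expect_error(predict(net, matrix(0, 33, 33)), "divisible")
})

test_that("checkpoints round-trip to identical predictions", {
  sw <- small_sweep(1, seed = 5, noise = 0.1, blur = 1)
  item <- list(image = crop_pad(sw$frames[[1]], 96L),
               mask = unclass(stack_from_labels(sw$labels[[1]])))
  cfg <- unet_config(middle_width = 8, depth = 2, learning_rate = 5e-3,
                     epochs = 2, rng_seed = 3)
  net <- train_unet(build_unet(cfg), list(item))
  p <- withr::local_tempfile(fileext = ".rds")
  save_unet(net, p)
  expect_true(file.exists(paste0(p, ".yaml")))
  back <- load_unet(p)
  expect_identical(predict(back, item$image), predict(net, item$image))
})

test_that("configuration invariants are enforced", {
  expect_error(unet_config(middle_width = 50, depth = 5), "base width")
  expect_error(unet_config(learning_rate = -1), "learning_rate")
  cfg <- unet_config(middle_width = 256)
  expect_identical(periseg:::unet_widths(cfg), c(16, 32, 64, 128, 256))
  expect_identical(cfg$output_channels, 5L)
})
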