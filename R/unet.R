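#' U-Net configuration
#'
#' Describes the encoder-decoder used for 384x384 multi-class mask
#' prediction: `depth` resolution levels, two same-padded 3x3 biased
#' convolutions + ReLU per level, 2x2 max-pool downsampling, 2x2
#' transposed-convolution upsampling, skip concatenation, and a 1x1
#' five-channel sigmoid head. Channel width doubles per level, so the
#' bottleneck ("middle layer") width is `base_width * 2^(depth-1)`; the two
#' published sizes are middle widths 256 and 512 at depth 5 with a
#' single-channel input, giving 1,940,885 and 7,759,653 trainable
#' parameters.
#'
#' Dropout placement follows the three published variants: `"all"` puts a
#' dropout layer after every double-convolution block, `"contracting_only"`
#' only after encoder blocks, `"none"` nowhere. Dropout has no trainable
#' parameters, so the parameter count is identical across modes.
#'
#' @param middle_width Bottleneck channel width; must be
#'   `base_width * 2^(depth-1)` for an integer base width.
#' @param depth Number of resolution levels (default 5).
#' @param input_channels Input image channels (default 1, grayscale).
#' @param dropout_mode `"none"`, `"all"` or `"contracting_only"`.
#' @param dropout_rate Dropout probability while training.
#' @param batch_size Images per optimiser step.
#' @param learning_rate Adam step size (> 0).
#' @param epochs Default training epochs.
#' @param rng_seed Seed for weight initialisation, shuffling and dropout.
#' @return An object of class `unet_config`.
#' @export
#' @examples
#' unet_param_count(unet_config(middle_width = 256))
unet_config <- function(middle_width = 256L, depth = 5L, input_channels = 1L,
                        dropout_mode = c("none", "all", "contracting_only"),
                        dropout_rate = 0.5, batch_size = 1L,
                        learning_rate = 1e-3, epochs = 20L, rng_seed = 1L) {
  depth <- check_count(depth, "depth", 1L)
  middle_width <- check_count(middle_width, "middle_width", 1L)
  input_channels <- check_count(input_channels, "input_channels", 1L)
  base <- middle_width / 2^(depth - 1L)
  if (base < 1 || base != as.integer(base))
    stop("middle_width must equal base_width * 2^(depth-1) for an integer ",
         "base width", call. = FALSE)
  dropout_mode <- match.arg(dropout_mode)
  dropout_rate <- check_prob(dropout_rate, "dropout_rate")
  if (dropout_rate >= 1) stop("dropout_rate must be < 1", call. = FALSE)
  batch_size <- check_count(batch_size, "batch_size", 1L)
  if (length(learning_rate) != 1L || learning_rate < 0)
    stop("learning_rate must be a single nonnegative number", call. = FALSE)
  epochs <- check_count(epochs, "epochs", 0L)
  rng_seed <- check_count(rng_seed, "rng_seed", 0L)
  structure(list(middle_width = middle_width, depth = depth,
                 base_width = as.integer(base),
                 input_channels = input_channels, output_channels = 5L,
                 dropout_mode = dropout_mode, dropout_rate = dropout_rate,
                 batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, rng_seed = rng_seed),
            class = "unet_config")
}

unet_widths <- function(config) config$base_width * 2^(seq_len(config$depth) - 1L)

#' Closed-form trainable parameter count of a U-Net configuration
#'
#' Sums weights and biases layer by layer: per encoder level two 3x3
#' convolutions; per decoder level one 2x2 transposed convolution, a 3x3
#' convolution over the concatenated (doubled) channels and a second 3x3
#' convolution; finally the 1x1 five-channel head. Computed without
#' allocating the model.
#'
#' @param config A [unet_config()].
#' @return Integer parameter count.
#' @export
unet_param_count <- function(config) {
  w <- unet_widths(config)
  d <- config$depth
  nconv <- function(kh, kw, cin, cout) kh * kw * cin * cout + cout
  total <- nconv(3, 3, config$input_channels, w[1]) + nconv(3, 3, w[1], w[1])
  for (l in seq_len(d - 1L) + 1L)
    total <- total + nconv(3, 3, w[l - 1L], w[l]) + nconv(3, 3, w[l], w[l])
  for (l in rev(seq_len(d - 1L)))
    total <- total + nconv(2, 2, w[l + 1L], w[l]) +
      nconv(3, 3, 2L * w[l], w[l]) + nconv(3, 3, w[l], w[l])
  total + nconv(1, 1, w[1], config$output_channels)
}

#' Build (initialise) a U-Net model
#'
#' Allocates all trainable tensors with He-scaled Gaussian initialisation,
#' deterministically under the configured seed. Hidden-layer biases start at
#' a small positive value (0.05) rather than zero: with strongly
#' background-dominated masks, the early optimisation pressure pushes
#' activations negative, and zero-initialised ReLU blocks can die wholesale
#' before any structure is learned; a positive bias keeps units initially
#' active. The output-head bias starts at zero.
#'
#' @param config A [unet_config()].
#' @return An object of class `unet`: list with `config`, `params` (named
#'   flat list of weight/bias arrays), `n_params`, `trained_epochs`,
#'   `history`.
#' @export
#' @examples
#' net <- build_unet(unet_config(middle_width = 4, depth = 2))
#' net$n_params
build_unet <- function(config) {
  if (!inherits(config, "unet_config"))
    stop("'config' must be a unet_config", call. = FALSE)
  w <- unet_widths(config)
  d <- config$depth
  p <- list()
  b0 <- 0.05  # keeps freshly initialised ReLU units active (see docs)
  he <- function(kh, kw, cin, cout)
    array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
          dim = c(kh, kw, cin, cout))
  with_seed(config$rng_seed, {
    for (l in seq_len(d)) {
      cin <- if (l == 1L) config$input_channels else w[l - 1L]
      p[[paste0("enc", l, ".c1w")]] <- he(3, 3, cin, w[l])
      p[[paste0("enc", l, ".c1b")]] <- rep(b0, w[l])
      p[[paste0("enc", l, ".c2w")]] <- he(3, 3, w[l], w[l])
      p[[paste0("enc", l, ".c2b")]] <- rep(b0, w[l])
    }
    for (l in rev(seq_len(d - 1L))) {
      p[[paste0("dec", l, ".upw")]] <- he(2, 2, w[l + 1L], w[l])
      p[[paste0("dec", l, ".upb")]] <- rep(b0, w[l])
      p[[paste0("dec", l, ".c1w")]] <- he(3, 3, 2L * w[l], w[l])
      p[[paste0("dec", l, ".c1b")]] <- rep(b0, w[l])
      p[[paste0("dec", l, ".c2w")]] <- he(3, 3, w[l], w[l])
      p[[paste0("dec", l, ".c2b")]] <- rep(b0, w[l])
    }
    p[["head.w"]] <- he(1, 1, w[1], config$output_channels)
    p[["head.b"]] <- numeric(config$output_channels)
  })
  n_params <- sum(vapply(p, length, 0L))
  structure(list(config = config, params = p, n_params = n_params,
                 trained_epochs = 0L, history = NULL), class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("unet: depth %d, widths %s, input channels %d, dropout %s\n",
              cfg$depth, paste(unet_widths(cfg), collapse = "-"),
              cfg$input_channels, cfg$dropout_mode))
  cat(sprintf("  %s trainable parameters; trained epochs: %d\n",
              format(x$n_params, big.mark = ","), x$trained_epochs))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

relu <- function(z) { z[z < 0] <- 0; z }

conv_block_fw <- function(a, p, nm, drop_rate, use_drop, cache) {
  cache[[paste0(nm, ".in")]] <- a
  a1 <- relu(cpp_conv2d_fw(a, p[[paste0(nm, ".c1w")]], p[[paste0(nm, ".c1b")]]))
  cache[[paste0(nm, ".a1")]] <- a1
  r2 <- relu(cpp_conv2d_fw(a1, p[[paste0(nm, ".c2w")]], p[[paste0(nm, ".c2b")]]))
  cache[[paste0(nm, ".r2")]] <- r2
  if (use_drop) {
    mask <- array((runif(length(r2)) >= drop_rate) / (1 - drop_rate),
                  dim = dim(r2))
    cache[[paste0(nm, ".mask")]] <- mask
    r2 <- r2 * mask
  }
  list(out = r2, cache = cache)
}

conv_block_bw <- function(gout, p, nm, cache, grads) {
  mask <- cache[[paste0(nm, ".mask")]]
  if (!is.null(mask)) gout <- gout * mask
  gz2 <- gout * (cache[[paste0(nm, ".r2")]] > 0)
  r <- cpp_conv2d_bw(cache[[paste0(nm, ".a1")]], p[[paste0(nm, ".c2w")]], gz2)
  grads[[paste0(nm, ".c2w")]] <- r$gw
  grads[[paste0(nm, ".c2b")]] <- r$gb
  gz1 <- r$gx * (cache[[paste0(nm, ".a1")]] > 0)
  r <- cpp_conv2d_bw(cache[[paste0(nm, ".in")]], p[[paste0(nm, ".c1w")]], gz1)
  grads[[paste0(nm, ".c1w")]] <- r$gw
  grads[[paste0(nm, ".c1b")]] <- r$gb
  list(gin = r$gx, grads = grads)
}

# Forward pass over one H x W x Cin array; H and W must be divisible by
# 2^(depth-1). Returns logits (H x W x 5) and, when requested, the cache for
# backpropagation.
unet_forward <- function(net, x, train = FALSE) {
  cfg <- net$config; p <- net$params; d <- cfg$depth
  drop_enc <- train && cfg$dropout_mode %in% c("all", "contracting_only") &&
    cfg$dropout_rate > 0
  drop_dec <- train && cfg$dropout_mode == "all" && cfg$dropout_rate > 0
  cache <- list()
  skips <- vector("list", d)
  a <- x
  for (l in seq_len(d)) {
    if (l > 1L) {
      cache[[paste0("pool", l, ".H")]] <- dim(a)[1]
      cache[[paste0("pool", l, ".W")]] <- dim(a)[2]
      mp <- cpp_maxpool_fw(a)
      cache[[paste0("pool", l, ".idx")]] <- mp$idx
      a <- mp$y
    }
    cb <- conv_block_fw(a, p, paste0("enc", l), cfg$dropout_rate, drop_enc,
                        cache)
    a <- cb$out; cache <- cb$cache
    skips[[l]] <- a
  }
  for (l in rev(seq_len(d - 1L))) {
    nm <- paste0("dec", l)
    cache[[paste0(nm, ".upin")]] <- a
    u <- cpp_upconv_fw(a, p[[paste0(nm, ".upw")]], p[[paste0(nm, ".upb")]])
    cc <- array(c(skips[[l]], u),
                dim = c(dim(u)[1], dim(u)[2], dim(skips[[l]])[3] + dim(u)[3]))
    cb <- conv_block_fw(cc, p, nm, cfg$dropout_rate, drop_dec, cache)
    a <- cb$out; cache <- cb$cache
  }
  cache[["head.in"]] <- a
  logits <- cpp_conv2d_fw(a, p[["head.w"]], p[["head.b"]])
  list(logits = logits, cache = if (train) cache else NULL)
}

# Backpropagate the loss gradient wrt logits; returns grads named like params.
unet_backward <- function(net, cache, glogits) {
  cfg <- net$config; p <- net$params; d <- cfg$depth
  grads <- list()
  r <- cpp_conv2d_bw(cache[["head.in"]], p[["head.w"]], glogits)
  grads[["head.w"]] <- r$gw; grads[["head.b"]] <- r$gb
  ga <- r$gx
  gskip <- vector("list", d)
  for (l in seq_len(d - 1L)) {
    nm <- paste0("dec", l)
    bb <- conv_block_bw(ga, p, nm, cache, grads)
    grads <- bb$grads
    cs <- dim(bb$gin)[3] / 2L
    gskip[[l]] <- bb$gin[, , seq_len(cs), drop = FALSE]
    gup <- bb$gin[, , cs + seq_len(cs), drop = FALSE]
    r <- cpp_upconv_bw(cache[[paste0(nm, ".upin")]], p[[paste0(nm, ".upw")]],
                       gup)
    grads[[paste0(nm, ".upw")]] <- r$gw
    grads[[paste0(nm, ".upb")]] <- r$gb
    ga <- r$gx
  }
  for (l in rev(seq_len(d))) {
    gout <- if (l == d) ga else gskip[[l]]
    bb <- conv_block_bw(gout, p, paste0("enc", l), cache, grads)
    grads <- bb$grads
    if (l > 1L) {
      ga <- cpp_maxpool_bw(bb$gin, cache[[paste0("pool", l, ".idx")]],
                           cache[[paste0("pool", l, ".H")]],
                           cache[[paste0("pool", l, ".W")]])
      gskip[[l - 1L]] <- gskip[[l - 1L]] + ga
    }
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Mean per-pixel binary cross-entropy over the five channels and its exact
# gradient wrt the logits.
bce_loss_grad <- function(logits, y) {
  p <- sigmoid(logits)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  list(loss = -mean(y * log(pc) + (1 - y) * log(1 - pc)),
       grad = (p - y) / length(p))
}

# ---- training ---------------------------------------------------------------

as_input_array <- function(image, input_channels) {
  if (is.matrix(image)) {
    x <- image
    if (max(x) > 1.5) x <- x / 255
    if (input_channels == 1L) return(array(x, dim = c(dim(x), 1L)))
    return(array(rep(x, input_channels), dim = c(dim(x), input_channels)))
  }
  if (length(dim(image)) == 3L) {
    x <- image
    if (max(x) > 1.5) x <- x / 255
    if (dim(x)[3] == input_channels) return(x)
    # RGB input with a grayscale model: average the channels
    if (input_channels == 1L)
      return(array(apply(x, c(1, 2), mean), dim = c(dim(x)[1:2], 1L)))
  }
  stop("image must be a matrix or an H x W x C array", call. = FALSE)
}

check_train_item <- function(item, cfg) {
  if (!all(c("image", "mask") %in% names(item)))
    stop("each training item needs $image and $mask", call. = FALSE)
  dm <- dim(item$mask)
  dx <- dim(item$image)[1:2]
  if (!identical(as.integer(dm[1:2]), as.integer(dx)) || dm[3] != 5L)
    stop("mask must be H x W x 5 and match its image", call. = FALSE)
  div <- 2^(cfg$depth - 1L)
  if (any(dx %% div != 0))
    stop(sprintf("image sides must be divisible by %d for depth %d",
                 div, cfg$depth), call. = FALSE)
  invisible(item)
}

#' Train a U-Net on (image, mask stack) pairs
#'
#' Minimises the mean per-pixel binary cross-entropy over the five sigmoid
#' output channels with Adam, shuffling each epoch and stepping every
#' `batch_size` images (gradients averaged). Images are single-channel
#' arrays scaled to \[0, 1\] (0-255 input is rescaled automatically); RGB
#' input is converted by channel averaging. Deterministic given the
#' configured seed, up to floating-point non-associativity.
#'
#' @param net A [build_unet()] model.
#' @param train_set List of `list(image = , mask = )` pairs; masks are
#'   `mask_stack`-style H x W x 5 binary arrays.
#' @param val_set Optional list in the same format; when present, mean IoU
#'   over its ground-truth-present classes is recorded per epoch.
#' @param epochs Number of epochs (default from the config).
#' @param verbose Print per-epoch loss.
#' @return The trained `unet`, with `$history` (data frame: epoch, loss,
#'   and `val_iou` if a validation set was given) and `$trained_epochs`
#'   updated.
#' @export
train_unet <- function(net, train_set, val_set = NULL, epochs = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(net, "unet"))
  cfg <- net$config
  if (length(train_set) == 0L) stop("empty training set", call. = FALSE)
  lapply(train_set, check_train_item, cfg = cfg)
  if (is.null(epochs)) epochs <- cfg$epochs
  xs <- lapply(train_set, function(it) as_input_array(it$image,
                                                      cfg$input_channels))
  ys <- lapply(train_set, function(it) {
    y <- it$mask; attributes(y) <- list(dim = dim(y)); y
  })
  st <- list(t = 0,
             m = lapply(net$params, function(a) a * 0),
             v = lapply(net$params, function(a) a * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist_rows <- vector("list", epochs)
  with_seed(cfg$rng_seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(xs))
      losses <- numeric(0)
      acc <- NULL; acc_n <- 0L
      for (i in ord) {
        fw <- unet_forward(net, xs[[i]], train = TRUE)
        lg <- bce_loss_grad(fw$logits, ys[[i]])
        losses <- c(losses, lg$loss)
        g <- unet_backward(net, fw$cache, lg$grad)
        acc <- if (is.null(acc)) g
               else mapply(function(a, b) a + b, acc, g, SIMPLIFY = FALSE)
        acc_n <- acc_n + 1L
        if (acc_n == cfg$batch_size || i == ord[length(ord)]) {
          st$t <- st$t + 1
          for (nm in names(acc)) {
            gv <- acc[[nm]] / acc_n
            st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * gv
            st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * gv^2
            mhat <- st$m[[nm]] / (1 - b1^st$t)
            vhat <- st$v[[nm]] / (1 - b2^st$t)
            net$params[[nm]] <- net$params[[nm]] -
              cfg$learning_rate * mhat / (sqrt(vhat) + eps)
          }
          acc <- NULL; acc_n <- 0L
        }
      }
      row <- data.frame(epoch = net$trained_epochs + ep,
                        loss = mean(losses))
      if (!is.null(val_set)) {
        ious <- vapply(val_set, function(it)
          mean_present_iou(predict(net, it$image), it$mask), 0)
        row$val_iou <- mean(ious, na.rm = TRUE)
      }
      hist_rows[[ep]] <- row
      if (verbose)
        cat(sprintf("epoch %d: loss %.5f%s\n", row$epoch, row$loss,
                    if (!is.null(row$val_iou))
                      sprintf(", val IoU %.3f", row$val_iou) else ""))
    }
  })
  net$trained_epochs <- net$trained_epochs + epochs
  net$history <- rbind(net$history, do.call(rbind, hist_rows))
  net
}

#' Predict a 5-channel mask stack for one image
#'
#' Runs the forward pass and binarises the sigmoid outputs so that predicted
#' masks can never overlap: per pixel, only the arg-max channel may be set,
#' and only if its sigmoid probability reaches 0.5; otherwise the pixel is
#' background in all channels.
#'
#' @param object A trained `unet`.
#' @param image H x W matrix (grayscale, 0-1 or 0-255) or H x W x C array;
#'   sides must be divisible by `2^(depth-1)` (384 for the published
#'   configuration).
#' @param ... Unused.
#' @return A `mask_stack`-classed H x W x 5 binary array.
#' @export
predict.unet <- function(object, image, ...) {
  cfg <- object$config
  x <- as_input_array(image, cfg$input_channels)
  div <- 2^(cfg$depth - 1L)
  if (any(dim(x)[1:2] %% div != 0))
    stop(sprintf("image sides must be divisible by %d for depth %d",
                 div, cfg$depth), call. = FALSE)
  pr <- sigmoid(unet_forward(object, x, train = FALSE)$logits)
  H <- dim(pr)[1]; W <- dim(pr)[2]
  P <- matrix(pr, H * W, 5L)
  am <- max.col(P, ties.method = "first")
  keep <- P[cbind(seq_len(H * W), am)] >= 0.5
  out <- matrix(0, H * W, 5L)
  out[cbind(which(keep), am[keep])] <- 1
  structure(array(out, dim = c(H, W, 5L),
                  dimnames = list(NULL, NULL, periseg_classes())),
            class = c("mask_stack", "array"), source_frame = "")
}

#' Mean IoU over the classes present in a ground-truth stack
#'
#' Averages [pixel_iou()] over the channels whose ground-truth mask is
#' nonempty; `NA` if no class is present.
#'
#' @param pred,gt H x W x 5 binary arrays.
#' @return Mean IoU, or `NA`.
#' @export
mean_present_iou <- function(pred, gt) {
  present <- which(apply(gt, 3L, sum) > 0)
  if (length(present) == 0L) return(NA_real_)
  mean(vapply(present, function(k) pixel_iou(pred[, , k], gt[, , k]), 0))
}

#' Save/load a U-Net checkpoint
#'
#' The model (weights, optimiser-free) is serialised to `path`; a YAML
#' sidecar `<path>.yaml` records the configuration and training state for
#' inspection. Loading restores a model whose predictions are identical to
#' the saved one's.
#'
#' @param net A `unet`.
#' @param path Checkpoint path.
#' @return `path` invisibly (save); the `unet` (load).
#' @export
save_unet <- function(net, path) {
  stopifnot(inherits(net, "unet"))
  saveRDS(net, path)
  yaml::write_yaml(c(unclass(net$config),
                     list(n_params = net$n_params,
                          trained_epochs = net$trained_epochs)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "unet")) stop("not a unet checkpoint", call. = FALSE)
  net
}
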