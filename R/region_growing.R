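#' Seeded region growing from a single seed pixel
#'
#' Grows a 4-connected region from `seed` by breadth-first traversal with a
#' FIFO queue, admitting pixels `p` with `|I(p) - I(seed)| <= T` that are not
#' excluded. Already-labeled pixels are the typical exclusion set, so regions
#' of different classes can never overlap.
#'
#' @param image Numeric intensity matrix.
#' @param seed Length-2 integer vector `(row, col)`, 1-based.
#' @param T Intensity similarity threshold (>= 0), anchored at the seed.
#' @param excluded Optional logical matrix of pixels the growth may not enter.
#'
#' @return Logical matrix: the grown region (contains the seed).
#' @export
#' @examples
#' img <- matrix(c(10, 10, 50, 10), 2, 2)
#' grow_region(img, c(1, 1), T = 5)
grow_region <- function(image, seed, T, excluded = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix", call. = FALSE)
  if (length(seed) != 2L || any(seed < 1L) ||
      seed[1] > nrow(image) || seed[2] > ncol(image))
    stop("seed out of bounds", call. = FALSE)
  if (length(T) != 1L || !is.finite(T) || T < 0)
    stop("'T' must be a single nonnegative number", call. = FALSE)
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(image), ncol(image))
  if (!identical(dim(excluded), dim(image)))
    stop("'excluded' must match the image shape", call. = FALSE)
  if (excluded[seed[1], seed[2]])
    stop("seed pixel is excluded (already labeled)", call. = FALSE)
  cpp_grow_region(image, as.integer(seed[1]), as.integer(seed[2]),
                  as.numeric(T), excluded)
}

#' Start an annotation session over one image
#'
#' A session holds the image, the global label matrix (all committed classes,
#' pairwise disjoint by construction), and the transient state of the
#' interactive grow/adjust/commit loop: the pending region, its seed, the
#' current threshold, and the `grow_in_progress` flag.
#'
#' @param image Numeric intensity matrix.
#' @param labels Optional starting label matrix (codes 0..5); defaults to all
#'   unlabeled.
#' @param active_class Class code 1..5 written by commit/draw (default 1).
#' @return An object of class `growth_session`.
#' @export
growth_session <- function(image, labels = NULL, active_class = 1L) {
  if (!is.matrix(image)) stop("'image' must be a matrix", call. = FALSE)
  if (is.null(labels)) labels <- matrix(0L, nrow(image), ncol(image))
  check_label_matrix(labels, dim(image))
  active_class <- check_count(active_class, "active_class", 1L)
  if (active_class > 5L) stop("active_class must be 1..5", call. = FALSE)
  structure(list(image = image, labels = labels, pending = NULL,
                 seed = NULL, threshold = 0, grow_in_progress = FALSE,
                 active_class = active_class),
            class = "growth_session")
}

check_label_matrix <- function(labels, dims = NULL) {
  if (!is.matrix(labels) || !all(labels %in% 0:5))
    stop("label matrix must contain only codes 0..5", call. = FALSE)
  if (!is.null(dims) && !identical(dim(labels), dims))
    stop("label matrix shape does not match the image", call. = FALSE)
  invisible(labels)
}

#' Advance an annotation session by one command
#'
#' Commands mirror the interactive tool: `seed` starts a pending growth from
#' a point (left click), `threshold` re-grows the pending region under a new
#' `T` (track-bar; it only stores the value when no growth is pending),
#' `commit` writes the pending region into the global labels under the active
#' class (right click), `cancel` discards it (middle click), `class` selects
#' the active class, and `erase`/`draw` edit the committed labels inside a
#' disc brush. Editing is refused while a growth is pending, so the pending
#' region can never overlap labeled pixels. All transitions are deterministic.
#'
#' @param session A [growth_session()].
#' @param command A list such as `list(op = "seed", row = 5, col = 9)`,
#'   `list(op = "threshold", value = 12)`, `list(op = "commit")`,
#'   `list(op = "cancel")`, `list(op = "class", value = 3)`,
#'   `list(op = "erase", row = , col = , radius = )` or the same for `"draw"`;
#'   alternatively a script line string, e.g. `"seed 5 9"` (see
#'   [parse_session_command()]).
#'
#' @return The updated `growth_session`.
#' @export
session_step <- function(session, command) {
  stopifnot(inherits(session, "growth_session"))
  if (is.character(command)) command <- parse_session_command(command)
  op <- command$op
  H <- nrow(session$image); W <- ncol(session$image)
  in_bounds <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W
  if (op %in% c("seed", "erase", "draw") &&
      !in_bounds(command$row, command$col))
    stop("point out of bounds", call. = FALSE)
  switch(op,
    seed = {
      p <- c(command$row, command$col)
      if (session$labels[p[1], p[2]] != 0L)
        stop("seed pixel is already labeled", call. = FALSE)
      session$pending <- grow_region(session$image, p, session$threshold,
                                     excluded = session$labels > 0L)
      session$seed <- p
      session$grow_in_progress <- TRUE
    },
    threshold = {
      if (command$value < 0) stop("threshold must be >= 0", call. = FALSE)
      session$threshold <- command$value
      if (session$grow_in_progress)
        session$pending <- grow_region(session$image, session$seed,
                                       session$threshold,
                                       excluded = session$labels > 0L)
    },
    commit = {
      if (!session$grow_in_progress)
        stop("no growth in progress to commit", call. = FALSE)
      session$labels[session$pending] <- session$active_class
      session$pending <- NULL; session$seed <- NULL
      session$grow_in_progress <- FALSE
    },
    cancel = {
      if (!session$grow_in_progress)
        stop("no growth in progress to cancel", call. = FALSE)
      session$pending <- NULL; session$seed <- NULL
      session$grow_in_progress <- FALSE
    },
    class = {
      v <- check_count(command$value, "class", 1L)
      if (v > 5L) stop("class must be 1..5", call. = FALSE)
      session$active_class <- v
    },
    erase = ,
    draw = {
      if (session$grow_in_progress)
        stop("finish or cancel the pending growth before editing",
             call. = FALSE)
      if (command$radius < 0) stop("radius must be >= 0", call. = FALSE)
      d <- disc_mask(H, W, command$row, command$col, command$radius)
      session$labels[d] <- if (op == "erase") 0L else session$active_class
    },
    stop("unknown session command: ", op, call. = FALSE))
  session
}

#' Parse one session-script line
#'
#' Grammar (whitespace-separated): `seed r c`, `threshold T`, `commit`,
#' `cancel`, `class k`, `erase r c radius`, `draw r c radius`. Blank lines
#' and lines starting with `#` yield `NULL`.
#'
#' @param line A single script line.
#' @return A command list for [session_step()], or `NULL`.
#' @export
parse_session_command <- function(line) {
  line <- trimws(line)
  if (line == "" || startsWith(line, "#")) return(NULL)
  tok <- strsplit(line, "\\s+")[[1]]
  op <- tok[1]
  need <- function(k) if (length(tok) != k + 1L)
    stop("malformed session command: ", line, call. = FALSE)
  switch(op,
    seed = { need(2); list(op = "seed", row = as.integer(tok[2]),
                           col = as.integer(tok[3])) },
    threshold = { need(1); list(op = "threshold", value = as.numeric(tok[2])) },
    commit = { need(0); list(op = "commit") },
    cancel = { need(0); list(op = "cancel") },
    class = { need(1); list(op = "class", value = as.integer(tok[2])) },
    erase = ,
    draw = { need(3); list(op = op, row = as.integer(tok[2]),
                           col = as.integer(tok[3]),
                           radius = as.numeric(tok[4])) },
    stop("unknown session command: ", line, call. = FALSE))
}

#' Replay a session script headlessly
#'
#' Runs a plain-text command script (one command per line) against an image,
#' replacing the interactive mouse/keyboard/track-bar loop of the annotation
#' tool. Replaying the same script on the same image always yields the same
#' label matrix.
#'
#' @param image Numeric intensity matrix.
#' @param script Character vector of command lines, or the path of a script
#'   file.
#' @param labels Optional starting label matrix.
#' @return The final `growth_session`.
#' @export
#' @examples
#' img <- matrix(rep(c(10, 200), each = 8), 4, 4)
#' s <- run_session_script(img, c("class 3", "seed 1 1", "threshold 5",
#'                                "commit"))
#' table(s$labels)
run_session_script <- function(image, script, labels = NULL) {
  if (length(script) == 1L && file.exists(script))
    script <- readLines(script, warn = FALSE)
  session <- growth_session(image, labels)
  for (line in script) {
    cmd <- parse_session_command(line)
    if (!is.null(cmd)) session <- session_step(session, cmd)
  }
  session
}

#' Split a label matrix into the five per-class binary masks
#'
#' Mask k is `labels == k`, in the canonical class order of
#' [periseg_classes()]. The masks are pairwise disjoint and their union is
#' the labeled region.
#'
#' @param labels Integer label matrix (codes 0..5).
#' @return Named list of 5 logical matrices.
#' @export
labels_to_masks <- function(labels) {
  check_label_matrix(labels)
  masks <- lapply(1:5, function(k) labels == k)
  names(masks) <- periseg_classes()
  masks
}

#' Reassemble a label matrix from per-class binary masks
#'
#' Inverse of [labels_to_masks()]; overlapping masks are an error.
#'
#' @param masks Named list of 5 logical/binary matrices in class order.
#' @return Integer label matrix.
#' @export
masks_to_labels <- function(masks) {
  if (length(masks) != 5L) stop("expected 5 masks", call. = FALSE)
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  seen <- matrix(FALSE, nrow(lab), ncol(lab))
  for (k in 1:5) {
    m <- masks[[k]] > 0
    if (any(m & seen)) stop("masks overlap", call. = FALSE)
    seen <- seen | m
    lab[m] <- k
  }
  lab
}

#' @export
print.growth_session <- function(x, ...) {
  cat(sprintf("growth_session: %dx%d image, active class %d (%s), T = %g\n",
              nrow(x$image), ncol(x$image), x$active_class,
              periseg_classes()[x$active_class], x$threshold))
  cat(sprintf("  labeled pixels: %d; growth in progress: %s%s\n",
              sum(x$labels > 0L), x$grow_in_progress,
              if (x$grow_in_progress)
                sprintf(" (pending %d px from seed %d,%d)",
                        sum(x$pending), x$seed[1], x$seed[2]) else ""))
  invisible(x)
}
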