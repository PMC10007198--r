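#' Scene configuration for the synthetic kernel generator
#'
#' Describes a synthetic dark-box imaging scene: elliptical maize kernels
#' of three classes (`mCherry-1` bright red-magenta, `DsRed-2` dim red,
#' `Non-3` near-background) scattered on a near-black background with
#' additive Gaussian noise. Defaults emulate the imaging setup the
#' toolkit targets: 640x640 frames, a near-black background (mean 0.02),
#' channel noise sd 0.01, and per-class emission triples chosen so the
#' mean R-channel emission is strictly ordered
#' mCherry-1 > DsRed-2 > Non-3.
#'
#' @param width_px,height_px Frame size in pixels (default 640x640).
#' @param n_kernels Number of kernels to place (non-negative).
#' @param class_mix Proportions over classes
#'   `c("mCherry-1", "DsRed-2", "Non-3")`; must sum to 1.
#' @param kernel_axis_px Range (length 2) for the ellipse major semi-axis
#'   in pixels; the minor semi-axis is drawn as 0.75-1 of the major so
#'   kernels stay maize-like (aspect ratio at most ~1.35).
#' @param min_gap_px Minimum Euclidean pixel distance between kernel
#'   masks; 0 permits touching (but never overlapping) kernels.
#' @param brightness Named list of per-class mean RGB emission triples in
#'   `[0, 1]`.
#' @param background_mean Background level added to every pixel.
#' @param noise_sd Standard deviation of additive Gaussian channel noise.
#' @param seed Integer RNG seed; scenes are a pure function of
#'   (config, seed).
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(width_px = 640L, height_px = 640L,
                         n_kernels = 12L,
                         class_mix = c("mCherry-1" = 1 / 3,
                                       "DsRed-2" = 1 / 3,
                                       "Non-3" = 1 / 3),
                         kernel_axis_px = c(16, 26),
                         min_gap_px = 5L,
                         brightness = list(
                           "mCherry-1" = c(0.85, 0.12, 0.40),
                           "DsRed-2"   = c(0.50, 0.10, 0.14),
                           "Non-3"     = c(0.24, 0.22, 0.20)),
                         background_mean = 0.02,
                         noise_sd = 0.01,
                         seed = 1L) {
  cfg <- list(width_px = as.integer(width_px),
              height_px = as.integer(height_px),
              n_kernels = as.integer(n_kernels),
              class_mix = class_mix,
              kernel_axis_px = as.numeric(kernel_axis_px),
              min_gap_px = as.numeric(min_gap_px),
              brightness = brightness,
              background_mean = background_mean,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

kernel_classes <- function() c("mCherry-1", "DsRed-2", "Non-3")

#' @rdname scene_config
#' @param cfg A `scene_config`.
#' @export
validate_scene_config <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  if (cfg$width_px < 1L || cfg$height_px < 1L)
    stop("frame dimensions must be positive")
  if (cfg$n_kernels < 0L) stop("n_kernels must be non-negative")
  mix <- cfg$class_mix
  if (length(mix) != 3L || any(mix < 0))
    stop("class_mix must be three non-negative proportions")
  if (abs(sum(mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  ax <- cfg$kernel_axis_px
  if (length(ax) != 2L || ax[1] <= 0 || ax[2] < ax[1])
    stop("kernel_axis_px must be an increasing positive range")
  if (2 * ax[2] + 2 > min(cfg$width_px, cfg$height_px))
    stop("largest kernel does not fit inside the frame")
  if (cfg$min_gap_px < 0) stop("min_gap_px must be >= 0")
  if (!all(kernel_classes() %in% names(cfg$brightness)))
    stop("brightness must name all three classes")
  if (any(unlist(cfg$brightness) < 0) || any(unlist(cfg$brightness) > 1))
    stop("brightness triples must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(cfg)
}

#' Validate an RGB image array
#'
#' Images are `H x W x 3` numeric arrays with values in `[0, 1]`
#' (row = image y, column = image x).
#'
#' @param img Candidate array.
#' @return The image, invisibly; errors if invalid.
#' @export
validate_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("RGB image must be an H x W x 3 array")
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop("RGB image values must lie in [0, 1]")
  invisible(img)
}

# deterministic class counts from proportions (largest remainder),
# shuffled with the scene stream
assign_classes <- function(n, mix) {
  if (n == 0L) return(character(0))
  raw <- mix * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(kernel_classes(), times = counts))
}

# render one ellipse; returns NULL on frame overflow
ellipse_mask <- function(cy, cx, a, b, theta, H, W) {
  half <- ceiling(max(a, b)) + 1L
  r0 <- floor(cy - half); r1 <- ceiling(cy + half)
  c0 <- floor(cx - half); c1 <- ceiling(cx + half)
  if (r0 < 1L || c0 < 1L || r1 > H || c1 > W) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  ys <- rows - 0.5 - cy           # pixel centres, 0-based continuous
  xs <- cols - 0.5 - cx
  X <- matrix(xs, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  Y <- matrix(ys, nrow = length(rows), ncol = length(cols))
  u <- (X * cos(theta) + Y * sin(theta)) / a
  v <- (-X * sin(theta) + Y * cos(theta)) / b
  d2 <- u^2 + v^2
  if (!any(d2 <= 1)) return(NULL)
  list(rows = rows, cols = cols, inside = d2 <= 1, d2 = d2)
}

#' Generate a synthetic fluorescent-kernel scene with ground truth
#'
#' Places `n_kernels` elliptical kernels by rejection sampling (at most
#' 1000 attempts each), honouring `min_gap_px` via an exact Euclidean
#' distance transform of the already-occupied raster. Each kernel is
#' rendered with a radial brightness falloff (edge at 65% of centre
#' emission), then background level and Gaussian noise are added and the
#' result is clipped to `[0, 1]`.
#'
#' The generator is deterministic: identical `(config, seed)` give
#' bit-identical pixels. Each kernel draws from its own seeded substream
#' so placements do not shift when unrelated parameters change.
#'
#' @param config A [scene_config()].
#' @return A list with `image` (H x W x 3 array in `[0, 1]`) and
#'   `truths`, a list of per-kernel ground-truth records of class
#'   `"kernel_truth"` with fields `mask` (logical H x W), `bbox` (tight
#'   [bbox()] of the mask), `class_label`, `centroid` (row, col,
#'   0-based continuous) and `mean_emission` (pre-noise mean RGB inside
#'   the mask).
#' @examples
#' sc <- generate_scene(scene_config(n_kernels = 3, seed = 7))
#' length(sc$truths)
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  H <- config$height_px; W <- config$width_px
  n <- config$n_kernels
  ax <- config$kernel_axis_px
  gap <- max(config$min_gap_px, 1)       # >= 1 forbids overlap, permits touch
  emission <- array(0, dim = c(H, W, 3))
  occupied <- matrix(FALSE, H, W)
  occ_d2 <- NULL                         # squared EDT to occupied pixels
  classes <- with_seed(mix_seed(config$seed, 0), {
    assign_classes(n, config$class_mix[kernel_classes()])
  })
  truths <- vector("list", n)
  for (k in seq_len(n)) {
    placed <- with_seed(mix_seed(config$seed, k), {
      res <- NULL
      for (attempt in seq_len(1000L)) {
        a <- runif(1, ax[1], ax[2])
        b <- a * runif(1, 0.75, 1)
        theta <- runif(1, 0, pi)
        cy <- runif(1, max(a, b) + 1, H - max(a, b) - 1)
        cx <- runif(1, max(a, b) + 1, W - max(a, b) - 1)
        em <- ellipse_mask(cy, cx, a, b, theta, H, W)
        if (is.null(em)) next
        if (!is.null(occ_d2)) {
          d2win <- occ_d2[em$rows, em$cols, drop = FALSE]
          if (min(d2win[em$inside]) < gap^2) next
        }
        res <- list(em = em, cy = cy, cx = cx)
        break
      }
      res
    })
    if (is.null(placed))
      stop(sprintf(
        "could not place kernel %d after 1000 attempts (min_gap_px = %g)",
        k, config$min_gap_px))
    em <- placed$em
    mask <- matrix(FALSE, H, W)
    mask[em$rows, em$cols][em$inside] <- TRUE
    falloff <- 1 - 0.35 * em$d2[em$inside]
    bright <- config$brightness[[classes[k]]]
    for (ch in 1:3) {
      win <- emission[em$rows, em$cols, ch]
      win[em$inside] <- bright[ch] * falloff
      emission[em$rows, em$cols, ch] <- win
    }
    occupied <- occupied | mask
    occ_d2 <- edt_sq_cpp(occupied)
    rr <- range(which(rowSums(mask) > 0))
    cc <- range(which(colSums(mask) > 0))
    idx <- which(mask, arr.ind = TRUE)
    truths[[k]] <- structure(list(
      mask = mask,
      bbox = bbox(cc[1] - 1, rr[1] - 1, cc[2], rr[2]),
      class_label = classes[k],
      centroid = c(row = mean(idx[, 1]) - 0.5, col = mean(idx[, 2]) - 0.5),
      mean_emission = c(
        R = mean(emission[, , 1][mask]),
        G = mean(emission[, , 2][mask]),
        B = mean(emission[, , 3][mask]))),
      class = "kernel_truth")
  }
  img <- with_seed(mix_seed(config$seed, n + 1L), {
    noise <- array(rnorm(H * W * 3, 0, config$noise_sd), dim = c(H, W, 3))
    clip01(emission + config$background_mean + noise)
  })
  list(image = img, truths = truths)
}

#' Convert ground-truth kernels to label records
#'
#' Produces one label record per truth in either YOLO-txt geometry
#' (class index plus centre/size normalized to `[0, 1]`) or Pascal-VOC
#' geometry (class name plus pixel corners). Class indices follow the
#' fixed order `mCherry-1` = 0, `DsRed-2` = 1, `Non-3` = 2.
#'
#' @param truths List of `kernel_truth` records (or any objects with a
#'   `bbox` and `class_label` field).
#' @param width_px,height_px Frame size the boxes live in.
#' @param format `"yolo-txt"` or `"voc-xml"`.
#' @return A `label_set`: a data frame of records with attributes
#'   `format`, `width_px`, `height_px`. Writable with [write_labels()].
#' @export
scene_to_labels <- function(truths, width_px, height_px,
                            format = c("yolo-txt", "voc-xml")) {
  format <- match.arg(format)
  boxes <- lapply(truths, `[[`, "bbox")
  labels <- vapply(truths, `[[`, character(1), "class_label")
  idx <- match(labels, kernel_classes()) - 1L
  if (anyNA(idx)) stop("unknown class label in truths")
  if (format == "yolo-txt") {
    df <- data.frame(
      class_index = idx,
      x_center = vapply(boxes, function(b) (b[[1]] + b[[3]]) / 2, 0) / width_px,
      y_center = vapply(boxes, function(b) (b[[2]] + b[[4]]) / 2, 0) / height_px,
      width = vapply(boxes, function(b) b[[3]] - b[[1]], 0) / width_px,
      height = vapply(boxes, function(b) b[[4]] - b[[2]], 0) / height_px)
  } else {
    df <- data.frame(
      class_index = idx,
      class_name = labels,
      x_min = vapply(boxes, `[[`, 0, 1L),
      y_min = vapply(boxes, `[[`, 0, 2L),
      x_max = vapply(boxes, `[[`, 0, 3L),
      y_max = vapply(boxes, `[[`, 0, 4L))
  }
  label_set(df, format, width_px, height_px)
}
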