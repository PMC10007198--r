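#' Gamma transform parameters
#'
#' The gamma transform `s = c * r^gamma` applies a nonlinear map to
#' `[0, 1]`-normalized intensities: `gamma < 1` stretches the histogram
#' towards high values (brightens, lifting dim DsRed kernels off a dark
#' background), `gamma > 1` compresses it (darkens). With `c = 1` the
#' endpoints 0 and 1 are fixed.
#'
#' @param c Positive multiplicative constant (default 1).
#' @param gamma Positive exponent. 0.7 is the default working point for
#'   enhancing dim fluorescent kernels against a dark background.
#' @return A list of class `"gamma_params"`.
#' @export
gamma_params <- function(c = 1, gamma = 0.7) {
  if (!is.finite(c) || c <= 0) stop("c must be positive")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive")
  structure(list(c = c, gamma = gamma), class = "gamma_params")
}

#' Gamma transform of an image
#'
#' Applies `s = c * r^gamma` per pixel (per channel for RGB input),
#' clipping to `[0, 1]`. Monotone non-decreasing in `r`; with `c = 1`,
#' composing two transforms multiplies their exponents.
#'
#' @param img Gray matrix or RGB array, values in `[0, 1]`.
#' @param p A [gamma_params()].
#' @param on_v If `TRUE` and `img` is RGB, apply the transform to the
#'   HSV value channel only (grey-level contrast reading); default
#'   applies per channel.
#' @return Same type and shape as `img`.
#' @examples
#' gamma_transform(matrix(0.25), gamma_params(gamma = 0.7))  # ~0.3789
#' @export
gamma_transform <- function(img, p = gamma_params(), on_v = FALSE) {
  stopifnot(inherits(p, "gamma_params"))
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop("input values must lie in [0, 1]")
  if (on_v && is.array(img) && length(dim(img)) == 3L) {
    hsv <- rgb_to_hsv(img)
    hsv[, , 3] <- clip01(p$c * hsv[, , 3]^p$gamma)
    return(hsv_to_rgb(hsv))
  }
  out <- clip01(p$c * img^p$gamma)
  dim(out) <- dim(img)
  out
}

#' HSV jitter parameters
#'
#' Per-image random colour jitter gains in the style of detection
#' training pipelines. Defaults are the hue/saturation/value gains used
#' alongside gamma 0.7 in the target pipeline's hyperparameter set.
#'
#' @param h_gain,s_gain,v_gain Non-negative gains.
#' @return A list of class `"jitter_params"`.
#' @export
jitter_params <- function(h_gain = 0.0138, s_gain = 0.664, v_gain = 0.464) {
  if (any(c(h_gain, s_gain, v_gain) < 0)) stop("gains must be >= 0")
  structure(list(h_gain = h_gain, s_gain = s_gain, v_gain = v_gain),
            class = "jitter_params")
}

#' Random HSV jitter
#'
#' Draws one uniform `u ~ U(-1, 1)` per channel, then shifts hue by
#' `u * h_gain` (mod 1) and multiplies saturation and value by
#' `1 + u * gain` (clipped to `[0, 1]`). Deterministic given `seed`;
#' all-zero gains are the identity.
#'
#' @param img RGB image.
#' @param p A [jitter_params()].
#' @param seed Integer seed.
#' @return Jittered RGB image.
#' @export
hsv_jitter <- function(img, p = jitter_params(), seed = 1L) {
  validate_rgb_image(img)
  stopifnot(inherits(p, "jitter_params"))
  u <- with_seed(seed, runif(3, -1, 1))
  hsv <- rgb_to_hsv(img)
  hsv[, , 1] <- (hsv[, , 1] + u[1] * p$h_gain) %% 1
  hsv[, , 2] <- clip01(hsv[, , 2] * (1 + u[2] * p$s_gain))
  hsv[, , 3] <- clip01(hsv[, , 3] * (1 + u[3] * p$v_gain))
  hsv_to_rgb(hsv)
}

# clip a box data.frame to a rectangle; returns boxes with clipped
# area >= min_keep * original area
clip_boxes <- function(boxes, x0, y0, x1, y1, min_keep) {
  if (nrow(boxes) == 0L) return(boxes)
  orig <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
  boxes$x_min <- pmax(boxes$x_min, x0); boxes$x_max <- pmin(boxes$x_max, x1)
  boxes$y_min <- pmax(boxes$y_min, y0); boxes$y_max <- pmin(boxes$y_max, y1)
  w <- pmax(boxes$x_max - boxes$x_min, 0)
  h <- pmax(boxes$y_max - boxes$y_min, 0)
  boxes[w * h >= min_keep * orig & w > 0 & h > 0, , drop = FALSE]
}

#' Mosaic composition of four labelled images
#'
#' Composes four images onto one `out_size x out_size` canvas split into
#' four quadrants by a random centre point (drawn uniformly in the
#' middle half of the canvas). Each image is placed at native scale,
#' anchored at the centre point and cropped to its quadrant; boxes are
#' shifted with their image, clipped to the visible region, and dropped
#' when less than `min_keep` (default 20%) of their original area
#' survives.
#'
#' @param imgs List of exactly four RGB images.
#' @param labels List of four data frames with columns
#'   `x_min, y_min, x_max, y_max` (extra columns such as `class_index`
#'   are carried through).
#' @param out_size Canvas side in pixels.
#' @param seed Integer seed for the centre point.
#' @param min_keep Minimum surviving area fraction for a box to be kept.
#' @param center Optional explicit centre `c(x, y)` overriding the
#'   random draw (used for reproducible geometry checks).
#' @return A list with `image` (the canvas) and `boxes` (combined,
#'   transformed data frame with a `tile` column).
#' @export
mosaic <- function(imgs, labels, out_size = 640L, seed = 1L,
                   min_keep = 0.2, center = NULL) {
  if (length(imgs) != 4L || length(labels) != 4L)
    stop("mosaic needs exactly 4 images and 4 label sets")
  lapply(imgs, validate_rgb_image)
  S <- as.integer(out_size)
  if (is.null(center)) {
    center <- with_seed(seed, round(runif(2, 0.25, 0.75) * S))
  }
  cx <- center[1]; cy <- center[2]
  canvas <- array(0, dim = c(S, S, 3))
  out_boxes <- list()
  for (i in 1:4) {
    im <- imgs[[i]]
    h <- dim(im)[1]; w <- dim(im)[2]
    # destination rectangles [x0, x1) x [y0, y1) per quadrant;
    # images anchored at the centre point
    reg <- switch(i,
      c(max(cx - w, 0), max(cy - h, 0), cx, cy),            # top-left
      c(cx, max(cy - h, 0), min(cx + w, S), cy),            # top-right
      c(max(cx - w, 0), cy, cx, min(cy + h, S)),            # bottom-left
      c(cx, cy, min(cx + w, S), min(cy + h, S)))            # bottom-right
    dx <- switch(i, cx - w, cx, cx - w, cx)
    dy <- switch(i, cy - h, cy - h, cy, cy)
    if (reg[3] > reg[1] && reg[4] > reg[2]) {
      sr <- (reg[2] - dy + 1):(reg[4] - dy)   # source rows
      sc <- (reg[1] - dx + 1):(reg[3] - dx)   # source cols
      canvas[(reg[2] + 1):reg[4], (reg[1] + 1):reg[3], ] <- im[sr, sc, ]
      bx <- labels[[i]]
      if (nrow(bx) > 0L) {
        bx$x_min <- bx$x_min + dx; bx$x_max <- bx$x_max + dx
        bx$y_min <- bx$y_min + dy; bx$y_max <- bx$y_max + dy
        bx <- clip_boxes(bx, reg[1], reg[2], reg[3], reg[4], min_keep)
        if (nrow(bx) > 0L) {
          bx$tile <- i
          out_boxes[[length(out_boxes) + 1L]] <- bx
        }
      }
    }
  }
  boxes <- if (length(out_boxes)) do.call(rbind, out_boxes) else
    data.frame(x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0), tile = integer(0))
  rownames(boxes) <- NULL
  list(image = canvas, boxes = boxes)
}
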