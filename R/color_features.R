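#' RGB to HSV conversion
#'
#' Standard hexcone conversion; hue is scaled to `[0, 1)` (fraction of
#' the colour circle), saturation and value to `[0, 1]`. Gray pixels get
#' hue 0 by convention.
#'
#' @param img RGB image (`H x W x 3` array in `[0, 1]`).
#' @return An `H x W x 3` array with channels H, S, V.
#' @export
rgb_to_hsv <- function(img) {
  validate_rgb_image(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  out <- array(0, dim = d)
  out[, , 1] <- hsv[1, ] %% 1
  out[, , 2] <- hsv[2, ]
  out[, , 3] <- hsv[3, ]
  out
}

#' HSV to RGB conversion (vectorized inverse of [rgb_to_hsv()])
#'
#' @param hsv `H x W x 3` array with H in `[0, 1)` (values wrap), S and
#'   V in `[0, 1]`.
#' @return An RGB `H x W x 3` array in `[0, 1]`.
#' @export
hsv_to_rgb <- function(hsv) {
  d <- dim(hsv)
  h6 <- (as.vector(hsv[, , 1]) %% 1) * 6
  s <- as.vector(hsv[, , 2]); v <- as.vector(hsv[, , 3])
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim = d)
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  clip01(out)
}

moment_channel_names <- function() {
  as.vector(t(outer(c("R", "G", "B", "H", "S", "V"),
                    c("mean", "second", "third"), paste, sep = "_")))
}

#' Colour moments of a masked region
#'
#' Computes the standard colour-moment feature vector over the masked
#' pixels: for each of the six channels (R, G, B and H, S, V) the mean,
#' the second moment (standard deviation, the square root of the second
#' central moment) and the third moment (the signed cube root of the
#' third central moment). 18 values in total. With the cube/square root
#' definitions all three moments share the channel's units, so scaling a
#' channel by `k > 0` scales all three by `k`.
#'
#' @param img RGB image.
#' @param mask Logical `H x W` region mask (non-empty). Defaults to the
#'   whole frame.
#' @param scale_255 If `TRUE`, compute on `[0, 255]`-scaled channels
#'   (for comparability with byte-valued pipelines); default `FALSE`
#'   computes on `[0, 1]`.
#' @return A named numeric vector of 18 moments
#'   (`R_mean`, `R_second`, `R_third`, ..., `V_third`).
#' @export
color_moments <- function(img, mask = NULL, scale_255 = FALSE) {
  validate_rgb_image(img)
  if (is.null(mask)) mask <- matrix(TRUE, dim(img)[1], dim(img)[2])
  if (!is.logical(mask) || !identical(dim(mask), dim(img)[1:2]))
    stop("mask must be a logical matrix matching the image")
  if (!any(mask)) stop("empty mask")
  hsv <- rgb_to_hsv(img)
  chans <- list(R = img[, , 1], G = img[, , 2], B = img[, , 3],
                H = hsv[, , 1], S = hsv[, , 2], V = hsv[, , 3])
  k <- if (scale_255) 255 else 1
  out <- unlist(lapply(chans, function(ch) {
    x <- ch[mask] * k
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    m3 <- mean((x - mu)^3)
    c(mean = mu, second = sqrt(m2), third = sign(m3) * abs(m3)^(1 / 3))
  }))
  names(out) <- moment_channel_names()
  out
}

#' Threshold rule for the moment classifier
#'
#' @param theta_h,theta_v Finite thresholds on the H-mean and V-mean
#'   features.
#' @return A list of class `"threshold_rule"`.
#' @export
threshold_rule <- function(theta_h, theta_v) {
  if (!is.finite(theta_h) || !is.finite(theta_v))
    stop("thresholds must be finite")
  structure(list(theta_h = theta_h, theta_v = theta_v),
            class = "threshold_rule")
}

#' Classify a kernel as fluorescent from its colour moments
#'
#' Fluorescent kernels separate from non-fluorescent ones most strongly
#' in the H and V channels, so the rule is deliberately minimal:
#' fluorescent iff `H_mean > theta_h` **or** `V_mean > theta_v` (strict;
#' a vector exactly at threshold is non-fluorescent). The other 16
#' moments are carried for analysis, not used by the rule.
#'
#' @param v An 18-moment vector from [color_moments()].
#' @param rule A [threshold_rule()].
#' @return `"fluorescent"` or `"non-fluorescent"`.
#' @export
moment_classify <- function(v, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (!all(c("H_mean", "V_mean") %in% names(v)))
    stop("v must contain H_mean and V_mean")
  if (v[["H_mean"]] > rule$theta_h || v[["V_mean"]] > rule$theta_v)
    "fluorescent" else "non-fluorescent"
}

#' Fit a threshold rule by class-mean midpoints
#'
#' Sets each threshold at the midpoint between the mean feature value of
#' fluorescent and non-fluorescent training kernels.
#'
#' @param moments A matrix or data frame of moment vectors (rows =
#'   kernels, columns named as in [color_moments()]).
#' @param fluorescent Logical vector: is each training kernel
#'   fluorescent? Both classes must be present.
#' @return A [threshold_rule()].
#' @export
fit_threshold_rule <- function(moments, fluorescent) {
  moments <- as.matrix(moments)
  if (nrow(moments) != length(fluorescent))
    stop("moments and fluorescent lengths differ")
  if (!any(fluorescent) || all(fluorescent))
    stop("need both classes to fit thresholds")
  mid <- function(col) {
    (mean(moments[fluorescent, col]) + mean(moments[!fluorescent, col])) / 2
  }
  threshold_rule(mid("H_mean"), mid("V_mean"))
}
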