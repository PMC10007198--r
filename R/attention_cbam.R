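#' CBAM parameters
#'
#' Weights for a forward-pass convolutional block attention module:
#' a shared two-layer channel MLP (`C -> C/r -> C`, ReLU hidden, no
#' biases) and a 2-in/1-out spatial convolution kernel. Weights are
#' drawn from `N(0, 0.1^2)` under the given seed unless supplied
#' explicitly.
#'
#' @param channels Number of input channels `C`.
#' @param reduction_ratio Channel bottleneck ratio `r`; must divide
#'   `C`. Default 16 (the module's conventional default).
#' @param spatial_kernel Odd spatial convolution size (default 7).
#' @param seed Integer seed for random initialization.
#' @param channel_mlp_weights Optional list `list(W1, W2)` with `W1`
#'   of shape `C/r x C` and `W2` of shape `C x C/r`.
#' @param spatial_conv_weights Optional `k x k x 2` array (mean path,
#'   max path).
#' @return A list of class `"cbam_params"`.
#' @export
cbam_params <- function(channels, reduction_ratio = 16L,
                        spatial_kernel = 7L, seed = 1L,
                        channel_mlp_weights = NULL,
                        spatial_conv_weights = NULL) {
  C <- as.integer(channels)
  r <- as.integer(reduction_ratio)
  k <- as.integer(spatial_kernel)
  if (C < 1L || r < 1L || C %% r != 0L)
    stop("channels must be a positive multiple of reduction_ratio")
  if (k < 1L || k %% 2L == 0L) stop("spatial_kernel must be odd")
  hidden <- C %/% r
  if (is.null(channel_mlp_weights) || is.null(spatial_conv_weights)) {
    init <- with_seed(seed, list(
      W1 = matrix(rnorm(hidden * C, 0, 0.1), hidden, C),
      W2 = matrix(rnorm(C * hidden, 0, 0.1), C, hidden),
      Ws = array(rnorm(k * k * 2, 0, 0.1), dim = c(k, k, 2))))
    if (is.null(channel_mlp_weights))
      channel_mlp_weights <- list(W1 = init$W1, W2 = init$W2)
    if (is.null(spatial_conv_weights)) spatial_conv_weights <- init$Ws
  }
  W1 <- channel_mlp_weights[[1]]; W2 <- channel_mlp_weights[[2]]
  if (!identical(dim(W1), c(hidden, C)) || !identical(dim(W2), c(C, hidden)))
    stop("channel MLP weight shapes must be C/r x C and C x C/r")
  if (!identical(dim(spatial_conv_weights), c(k, k, 2L)))
    stop("spatial conv weights must be k x k x 2")
  structure(list(channels = C, reduction_ratio = r, spatial_kernel = k,
                 W1 = W1, W2 = W2, Ws = spatial_conv_weights, seed = seed),
            class = "cbam_params")
}

validate_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be a C x H x W array")
  if (anyNA(x) || any(!is.finite(x))) stop("feature map must be finite")
  invisible(x)
}

#' Channel attention weights
#'
#' Global average- and max-pooled channel descriptors are passed
#' through the shared MLP, summed, and squashed:
#' `w = sigmoid(MLP(avgpool(x)) + MLP(maxpool(x)))`. One weight per
#' channel, each strictly in `(0, 1)`. Max pooling retains the
#' strongest activation per channel, average pooling its extent.
#'
#' @param x A `C x H x W` feature map.
#' @param p A [cbam_params()] with matching channel count.
#' @return Numeric vector of `C` weights in `(0, 1)`.
#' @export
channel_attention <- function(x, p) {
  validate_feature_map(x)
  stopifnot(inherits(p, "cbam_params"))
  if (dim(x)[1] != p$channels) stop("channel count mismatch")
  mlp <- function(v) p$W2 %*% pmax(p$W1 %*% v, 0)
  avg <- apply(x, 1, mean)
  mx <- apply(x, 1, max)
  as.vector(stats::plogis(mlp(avg) + mlp(mx)))
}

#' Spatial attention map
#'
#' The channel-wise mean and max maps are stacked, convolved with the
#' 2-in/1-out kernel (reflect padding, so a spatially constant input
#' gives a spatially constant map), and squashed with the sigmoid.
#'
#' @inheritParams channel_attention
#' @return An `H x W` matrix of weights in `(0, 1)`.
#' @export
spatial_attention <- function(x, p) {
  validate_feature_map(x)
  stopifnot(inherits(p, "cbam_params"))
  mean_map <- apply(x, c(2, 3), mean)
  max_map <- apply(x, c(2, 3), max)
  if (dim(x)[1] == 1L) {           # apply() drops to vector for C = 1
    mean_map <- matrix(mean_map, dim(x)[2], dim(x)[3])
    max_map <- matrix(max_map, dim(x)[2], dim(x)[3])
  }
  s <- conv2d_reflect_cpp(mean_map, p$Ws[, , 1]) +
       conv2d_reflect_cpp(max_map, p$Ws[, , 2])
  stats::plogis(s)
}

#' CBAM forward pass
#'
#' Sequential multiplicative attention: the channel weights scale the
#' input (`intermediate = w_c * x`), then the spatial map, computed on
#' the intermediate feature, scales the result
#' (`out = w_s * intermediate`). Both weight stages lie in `(0, 1)`, so
#' the module strictly attenuates every non-zero activation and
#' preserves shape.
#'
#' @inheritParams channel_attention
#' @return A feature map of the same shape as `x`.
#' @export
cbam_forward <- function(x, p) {
  wc <- channel_attention(x, p)
  inter <- x * wc                      # recycles along the channel dim
  ws <- spatial_attention(inter, p)
  inter * rep(ws, each = dim(x)[1])
}
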