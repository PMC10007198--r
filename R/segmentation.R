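#' Grayscale conversion
#'
#' Applies the ITU-R BT.601 luma weights 0.299/0.587/0.114, the standard
#' first step of the classical kernel-image processing chain (colour is
#' only needed again at feature extraction).
#'
#' @param img An RGB image (`H x W x 3` array in `[0, 1]`).
#' @return An `H x W` matrix in `[0, 1]`.
#' @export
to_gray <- function(img) {
  validate_rgb_image(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  clip01(g)
}

validate_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("gray image must be a numeric matrix")
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop("gray image values must lie in [0, 1]")
  invisible(img)
}

#' Median filter
#'
#' Smooths kernel debris and transmission noise: each pixel becomes the
#' median of its `window x window` neighbourhood (reflect padding at the
#' edges). `window = 1` is the identity.
#'
#' @param img Gray image matrix in `[0, 1]`.
#' @param window Odd positive window width (default 3).
#' @return Filtered matrix, same shape.
#' @export
median_filter <- function(img, window = 3L) {
  validate_gray(img)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  median_filter_cpp(img, window)
}

#' Laplacian sharpening
#'
#' Edge enhancement by subtracting the 4-neighbour Laplacian
#' (`[[0,1,0],[1,-4,1],[0,1,0]]`, reflect padding):
#' `out = clip(img - strength * lap(img), 0, 1)`. `strength = 0` is the
#' identity; a constant image is unchanged for any strength.
#'
#' @param img Gray image matrix in `[0, 1]`.
#' @param strength Non-negative sharpening strength (default 0.5).
#' @return Sharpened matrix, same shape, clipped to `[0, 1]`.
#' @export
laplacian_sharpen <- function(img, strength = 0.5) {
  validate_gray(img)
  if (strength < 0) stop("strength must be >= 0")
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  clip01(img - strength * conv2d_reflect_cpp(img, k))
}

#' Otsu threshold
#'
#' Parameter-free global threshold maximizing between-class variance of
#' the gray histogram.
#'
#' @param img Gray image matrix in `[0, 1]`.
#' @param nbins Number of histogram bins.
#' @return The threshold value (a number strictly inside the value
#'   range).
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  validate_gray(img)
  if (diff(range(img)) == 0) stop("no foreground: image has zero variance")
  breaks <- seq(0, 1, length.out = nbins + 1L)
  counts <- as.numeric(
    tabulate(pmin(findInterval(img, breaks, rightmost.closed = TRUE),
                  nbins), nbins))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(counts)
  w1 <- sum(counts) - w0
  mu0 <- cumsum(counts * mids) / pmax(w0, 1)
  mu1 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w1, 1)
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  breaks[which.max(between) + 1L]
}

# Euclidean-disk binary morphology via the exact distance transform
morph_dilate <- function(fg, radius) {
  if (radius <= 0) return(fg)
  edt_sq_cpp(fg) <= radius^2
}

morph_erode <- function(fg, radius) {
  if (radius <= 0) return(fg)
  fg & edt_sq_cpp(!fg) > radius^2
}

#' Binarization and morphological clean-up
#'
#' Otsu-thresholds a gray image, then applies binary opening (removes
#' speckle smaller than the disk) and closing (fills small gaps) with
#' Euclidean disk structuring elements.
#'
#' @param img Gray image matrix in `[0, 1]`.
#' @param open_radius,close_radius Disk radii in pixels (0 disables the
#'   step). Defaults 2/2 are configuration, not a claim about any
#'   particular imaging rig.
#' @return A logical `H x W` foreground raster.
#' @export
binarize_morph <- function(img, open_radius = 2, close_radius = 2) {
  validate_gray(img)
  if (open_radius < 0 || close_radius < 0) stop("radii must be >= 0")
  thr <- otsu_threshold(img)
  fg <- img > thr
  fg <- morph_dilate(morph_erode(fg, open_radius), open_radius)   # opening
  fg <- morph_erode(morph_dilate(fg, close_radius), close_radius) # closing
  fg
}

#' Marker-controlled watershed instance splitting
#'
#' Separates touching kernels: markers are greedy peaks of the Euclidean
#' distance transform (minimum peak separation `min_sep_px`, one marker
#' guaranteed per connected component), and the watershed floods the
#' negated distance transform from those markers, constrained to the
#' foreground. Labels are renumbered 1..K in raster (row-major) order of
#' first appearance.
#'
#' @param binary Logical foreground raster with at least one `TRUE`.
#' @param min_sep_px Minimum marker separation; set to the smallest
#'   expected kernel radius. Default 20 matches the default generator's
#'   16-26 px semi-axes.
#' @return An integer `H x W` label map; 0 = background.
#' @export
watershed_split <- function(binary, min_sep_px = 20) {
  if (!is.logical(binary) || !is.matrix(binary))
    stop("binary must be a logical matrix")
  if (!any(binary)) stop("empty foreground")
  d <- sqrt(edt_sq_cpp(!binary))
  peaks <- local_peaks_cpp(d, min_sep_px, 1.0)
  comps <- label_components_cpp(binary)
  markers <- matrix(0L, nrow(binary), ncol(binary))
  markers[peaks + 1L] <- seq_along(peaks)
  # every component needs a marker even if peak suppression starved it
  starved <- setdiff(unique(comps[comps > 0]), unique(comps[peaks + 1L]))
  nxt <- length(peaks)
  for (cid in starved) {
    in_comp <- which(comps == cid)
    nxt <- nxt + 1L
    markers[in_comp[which.max(d[in_comp])]] <- nxt
  }
  lab <- watershed_cpp(-d, markers, binary)
  relabel_raster_order(lab)
}

# renumber labels 1..K by first appearance scanning rows left-to-right
relabel_raster_order <- function(lab) {
  nz <- t(lab)[t(lab) > 0]
  ids <- unique(nz)
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

#' Crop per-instance sub-images
#'
#' Cuts one padded crop per label out of the original RGB frame,
#' producing the "multiple single-kernel images" the classical chain
#' feeds to feature extraction.
#'
#' @param img RGB image the labels refer to.
#' @param labels Integer label map from [watershed_split()].
#' @param pad_px Padding in pixels around each tight box (clipped to the
#'   frame).
#' @return A list with one element per label: `image` (the crop),
#'   `bbox` (crop box in frame coordinates, tight box plus padding) and
#'   `mask` (logical crop-sized instance mask).
#' @export
crop_instances <- function(img, labels, pad_px = 0L) {
  validate_rgb_image(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (!identical(dim(labels), c(H, W))) stop("labels/image size mismatch")
  ks <- sort(unique(labels[labels > 0]))
  lapply(ks, function(k) {
    mk <- labels == k
    rr <- range(which(rowSums(mk) > 0))
    cc <- range(which(colSums(mk) > 0))
    r0 <- max(1L, rr[1] - pad_px); r1 <- min(H, rr[2] + pad_px)
    c0 <- max(1L, cc[1] - pad_px); c1 <- min(W, cc[2] + pad_px)
    list(image = img[r0:r1, c0:c1, , drop = FALSE],
         bbox = bbox(c0 - 1, r0 - 1, c1, r1),
         mask = mk[r0:r1, c0:c1, drop = FALSE])
  })
}

#' Full segmentation chain
#'
#' Convenience wrapper running grayscale conversion, median filtering,
#' Laplacian sharpening, Otsu binarization with disk morphology, and
#' marker-controlled watershed.
#'
#' @param img RGB scene image.
#' @param median_window,sharpen_strength,open_radius,close_radius,min_sep_px
#'   Stage parameters; see the individual stages.
#' @return A list with `gray`, `binary` and `labels` (the final label
#'   map).
#' @export
segment_scene <- function(img, median_window = 3L, sharpen_strength = 0.5,
                          open_radius = 2, close_radius = 2,
                          min_sep_px = 20) {
  g <- to_gray(img)
  g <- median_filter(g, median_window)
  g <- laplacian_sharpen(g, sharpen_strength)
  fg <- binarize_morph(g, open_radius, close_radius)
  labels <- watershed_split(fg, min_sep_px)
  list(gray = g, binary = fg, labels = labels)
}
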