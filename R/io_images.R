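#' Read and write raster images
#'
#' PNG via the `png` package, plus plain-text NetPBM (`P2` grayscale
#' PGM / `P3` colour PPM), which keeps test fixtures text-only. Format
#' is chosen by file extension (`.png`, `.pgm`, `.ppm`). Values are
#' scaled to `[0, 1]` on read and quantized to `max_val` levels on
#' write.
#'
#' @param path File path.
#' @param img Gray matrix or RGB array with values in `[0, 1]`.
#' @param max_val Maximum integer level for PNM output (255, or 65535
#'   for 16-bit label maps).
#' @return `read_image`: a gray matrix (PGM) or RGB array; `write_image`
#'   returns `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L && dim(px)[3] >= 3L) return(px[, , 1:3])
    if (length(dim(px)) == 3L) px <- px[, , 1]
    return(px)
  }
  if (ext %in% c("pgm", "ppm")) return(read_pnm(path))
  stop("unsupported image extension: ", ext)
}

#' @rdname read_image
#' @export
write_image <- function(img, path, max_val = 255L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(clip01(img), path)
    return(invisible(path))
  }
  if (ext %in% c("pgm", "ppm")) return(write_pnm(img, path, max_val))
  stop("unsupported image extension: ", ext)
}

# plain-text NetPBM readers/writers ---------------------------------------

read_pnm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  magic <- toks[1]
  if (!magic %in% c("P2", "P3")) stop("unsupported PNM magic: ", magic)
  hdr <- as.numeric(toks[2:4])
  w <- hdr[1]; h <- hdr[2]; mx <- hdr[3]
  vals <- as.numeric(toks[-(1:4)]) / mx
  if (magic == "P2") {
    if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (length(vals) != 3 * w * h) stop("corrupt PPM: wrong pixel count")
    px <- matrix(vals, ncol = 3, byrow = TRUE)   # row-major RGB triples
    out <- array(0, dim = c(h, w, 3))
    for (ch in 1:3)
      out[, , ch] <- matrix(px[, ch], nrow = h, ncol = w, byrow = TRUE)
    out
  }
}

write_pnm <- function(img, path, max_val = 255L) {
  max_val <- as.integer(max_val)
  is_rgb <- is.array(img) && length(dim(img)) == 3L
  q <- function(x) round(clip01(x) * max_val)
  con <- file(path, "w")
  on.exit(close(con))
  if (is_rgb) {
    h <- dim(img)[1]; w <- dim(img)[2]
    writeLines(c("P3", paste(w, h), as.character(max_val)), con)
    px <- cbind(as.vector(t(q(img[, , 1]))), as.vector(t(q(img[, , 2]))),
                as.vector(t(q(img[, , 3]))))
    writeLines(paste(px[, 1], px[, 2], px[, 3]), con)
  } else {
    h <- nrow(img); w <- ncol(img)
    writeLines(c("P2", paste(w, h), as.character(max_val)), con)
    writeLines(apply(t(q(img)), 2, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Write / read an integer label map
#'
#' Label maps are stored as 16-bit plain-text PGM rasters with the
#' label index as the pixel value (the available PNG writer is 8-bit
#' only, which would collide label indices).
#'
#' @param labels Integer matrix (0 = background).
#' @param path Output path (`.pgm`).
#' @return `read_label_map`: an integer matrix.
#' @export
write_label_map <- function(labels, path) {
  mx <- 65535
  if (max(labels) > mx) stop("too many labels for a 16-bit raster")
  write_pnm(labels / mx, path, max_val = mx)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  px <- read_pnm(path)
  lab <- round(px * 65535)
  storage.mode(lab) <- "integer"
  lab
}

#' Bilinear image resize
#'
#' Resizes with pixel-centre alignment (sample positions
#' `(i + 0.5) * scale - 0.5`), the convention under which resizing to
#' the input size is the exact identity. Normalized (YOLO-style) box
#' labels are unchanged by resizing, by definition.
#'
#' @param img Gray matrix or RGB array.
#' @param size Output size: one integer (square) or `c(height, width)`.
#' @return Resized image of the same type.
#' @export
resize_image <- function(img, size) {
  if (length(size) == 1L) size <- c(size, size)
  oh <- as.integer(size[1]); ow <- as.integer(size[2])
  if (oh < 1L || ow < 1L) stop("size must be >= 1")
  is_rgb <- is.array(img) && length(dim(img)) == 3L
  h <- if (is_rgb) dim(img)[1] else nrow(img)
  w <- if (is_rgb) dim(img)[2] else ncol(img)
  map_axis <- function(n_out, n_in) {
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- floor(pos)
    list(lo = as.integer(lo) + 1L,
         hi = as.integer(pmin(lo + 1, n_in - 1)) + 1L,
         frac = pos - lo)
  }
  ry <- map_axis(oh, h); rx <- map_axis(ow, w)
  resize_plane <- function(m) {
    top <- m[ry$lo, rx$lo, drop = FALSE] * (1 - rx$frac[col(matrix(0, oh, ow))]) +
           m[ry$lo, rx$hi, drop = FALSE] * rx$frac[col(matrix(0, oh, ow))]
    bot <- m[ry$hi, rx$lo, drop = FALSE] * (1 - rx$frac[col(matrix(0, oh, ow))]) +
           m[ry$hi, rx$hi, drop = FALSE] * rx$frac[col(matrix(0, oh, ow))]
    top * (1 - ry$frac[row(matrix(0, oh, ow))]) +
      bot * ry$frac[row(matrix(0, oh, ow))]
  }
  if (is_rgb) {
    out <- array(0, dim = c(oh, ow, 3))
    for (ch in 1:3) out[, , ch] <- resize_plane(img[, , ch])
    out
  } else {
    resize_plane(img)
  }
}
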