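label_set <- function(df, format, width_px, height_px) {
  structure(df, format = format,
            width_px = as.numeric(width_px),
            height_px = as.numeric(height_px),
            class = c("label_set", "data.frame"))
}

#' Read object labels
#'
#' Two annotation formats are supported. YOLO-txt: one object per line,
#' five space-separated fields `class_index x_center y_center width
#' height`, all geometry normalized to `[0, 1]`. Pascal-VOC XML: one
#' `<object>` element per box with pixel-corner `<bndbox>` fields.
#' Malformed lines or XML raise errors naming the offending line or
#' node; out-of-range normalized values are rejected.
#'
#' @param path Label file path.
#' @param format `"yolo-txt"` or `"voc-xml"`.
#' @return A `label_set` data frame. YOLO records have columns
#'   `class_index, x_center, y_center, width, height` (normalized);
#'   VOC records have `class_index, class_name, x_min, y_min, x_max,
#'   y_max` (pixels) plus frame size attributes.
#' @export
read_labels <- function(path, format = c("yolo-txt", "voc-xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "yolo-txt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      return(label_set(data.frame(class_index = integer(0),
                                  x_center = numeric(0), y_center = numeric(0),
                                  width = numeric(0), height = numeric(0)),
                       "yolo-txt", NA, NA))
    }
    recs <- lapply(seq_along(lines), function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) != 5L)
        stop(sprintf("%s line %d: expected 5 fields, got %d", path, i, length(f)))
      v <- suppressWarnings(as.numeric(f))
      if (anyNA(v))
        stop(sprintf("%s line %d: non-numeric field", path, i))
      if (any(v[2:5] < 0) || any(v[2:5] > 1))
        stop(sprintf("%s line %d: normalized values outside [0, 1]", path, i))
      data.frame(class_index = as.integer(v[1]), x_center = v[2],
                 y_center = v[3], width = v[4], height = v[5])
    })
    return(label_set(do.call(rbind, recs), "yolo-txt", NA, NA))
  }
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, "./size")
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  objs <- xml2::xml_find_all(doc, "./object")
  num <- function(o, what) {
    x <- as.numeric(xml2::xml_text(xml2::xml_find_first(o, what)))
    if (is.na(x)) stop("malformed VOC object: missing ", what)
    x
  }
  if (length(objs) == 0L) {
    df <- data.frame(class_index = integer(0), class_name = character(0),
                     x_min = numeric(0), y_min = numeric(0),
                     x_max = numeric(0), y_max = numeric(0))
  } else {
    df <- do.call(rbind, lapply(objs, function(o) {
      nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
      data.frame(class_index = match(nm, kernel_classes()) - 1L,
                 class_name = nm,
                 x_min = num(o, "./bndbox/xmin"), y_min = num(o, "./bndbox/ymin"),
                 x_max = num(o, "./bndbox/xmax"), y_max = num(o, "./bndbox/ymax"))
    }))
  }
  label_set(df, "voc-xml", w, h)
}

#' Write object labels
#'
#' Inverse of [read_labels()]; `write` then `read` reproduces the
#' geometry to better than 1e-6 (coordinates are written with 9
#' decimals).
#'
#' @param records A `label_set` (from [read_labels()],
#'   [scene_to_labels()] or built by hand).
#' @param path Output path.
#' @param format Target format; defaults to the set's own format.
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path, format = NULL) {
  if (is.null(format)) format <- attr(records, "format")
  if (is.null(format)) stop("format must be given for plain data frames")
  if (!format %in% c("yolo-txt", "voc-xml")) stop("unknown format: ", format)
  if (format == "yolo-txt") {
    if (nrow(records) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    writeLines(sprintf("%d %.9f %.9f %.9f %.9f",
                       records$class_index, records$x_center,
                       records$y_center, records$width, records$height),
               path)
    return(invisible(path))
  }
  w <- attr(records, "width_px"); h <- attr(records, "height_px")
  doc <- xml2::xml_new_root("annotation")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(w, digits = 12))
  xml2::xml_add_child(size, "height", format(h, digits = 12))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(records))) {
    o <- xml2::xml_add_child(doc, "object")
    nm <- if (!is.null(records$class_name)) records$class_name[i] else
      kernel_classes()[records$class_index[i] + 1L]
    xml2::xml_add_child(o, "name", nm)
    bb <- xml2::xml_add_child(o, "bndbox")
    fmt <- function(x) sprintf("%.6f", x)
    xml2::xml_add_child(bb, "xmin", fmt(records$x_min[i]))
    xml2::xml_add_child(bb, "ymin", fmt(records$y_min[i]))
    xml2::xml_add_child(bb, "xmax", fmt(records$x_max[i]))
    xml2::xml_add_child(bb, "ymax", fmt(records$y_max[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Convert label records between normalized and pixel geometry
#'
#' @param records A `label_set`.
#' @param width_px,height_px Frame size (required for YOLO records,
#'   whose geometry is normalized).
#' @return `labels_to_pixel`: data frame with corner columns
#'   `x_min, y_min, x_max, y_max` (plus class columns);
#'   `labels_to_norm`: data frame in normalized centre format.
#' @export
labels_to_pixel <- function(records, width_px = NULL, height_px = NULL) {
  fmt <- attr(records, "format")
  if (identical(fmt, "voc-xml") || !is.null(records$x_min))
    return(as.data.frame(records))
  if (is.null(width_px) || is.null(height_px))
    stop("frame size required to convert normalized labels")
  data.frame(class_index = records$class_index,
             x_min = (records$x_center - records$width / 2) * width_px,
             y_min = (records$y_center - records$height / 2) * height_px,
             x_max = (records$x_center + records$width / 2) * width_px,
             y_max = (records$y_center + records$height / 2) * height_px)
}

#' @rdname labels_to_pixel
#' @export
labels_to_norm <- function(records, width_px = NULL, height_px = NULL) {
  if (!is.null(records$x_center)) return(as.data.frame(records))
  if (is.null(width_px)) width_px <- attr(records, "width_px")
  if (is.null(height_px)) height_px <- attr(records, "height_px")
  if (is.null(width_px) || is.na(width_px))
    stop("frame size required to normalize pixel labels")
  data.frame(class_index = records$class_index,
             x_center = (records$x_min + records$x_max) / 2 / width_px,
             y_center = (records$y_min + records$y_max) / 2 / height_px,
             width = (records$x_max - records$x_min) / width_px,
             height = (records$y_max - records$y_min) / height_px)
}
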