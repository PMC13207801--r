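#' Labelled bounding box
#'
#' An axis-aligned box in 0-based half-open image coordinates: the box covers
#' pixels with `x_min <= x < x_max`, `y_min <= y < y_max`. Pascal VOC files
#' store 1-based inclusive coordinates; [read_voc_annotation()] converts on
#' ingestion (`xmin - 1 .. xmax`).
#'
#' @param class_name label string, e.g. `"crop"` or `"weed"`.
#' @param x_min,y_min,x_max,y_max integer pixel coordinates.
#' @return An object of class `labeled_box`.
#' @export
labeled_box <- function(class_name, x_min, y_min, x_max, y_max) {
  x_min <- as.integer(x_min); y_min <- as.integer(y_min)
  x_max <- as.integer(x_max); y_max <- as.integer(y_max)
  if (x_min >= x_max || y_min >= y_max)
    stop("degenerate box: requires x_min < x_max and y_min < y_max")
  structure(
    list(class_name = as.character(class_name),
         x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
    class = "labeled_box"
  )
}

#' @export
print.labeled_box <- function(x, ...) {
  cat(sprintf("<labeled_box '%s' [%d,%d) x [%d,%d)>\n",
              x$class_name, x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

box_width <- function(box) box$x_max - box$x_min
box_height <- function(box) box$y_max - box$y_min

#' Intersection-over-union of two boxes
#'
#' Areas follow the half-open convention, so a box's area is
#' `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param a,b `labeled_box` objects.
#' @return IoU as a fraction in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0L, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0L, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- as.numeric(ix) * iy
  union <- box_width(a) * box_height(a) + box_width(b) * box_height(b) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Annotated image: id, dimensions and an ordered box list
#'
#' @param image_id identifier string (usually the file stem).
#' @param width,height image dimensions in pixels.
#' @param boxes list of [labeled_box()] objects.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, width, height, boxes = list()) {
  width <- as.integer(width); height <- as.integer(height)
  if (width <= 0 || height <= 0) stop("image dimensions must be positive")
  for (b in boxes) {
    if (b$x_min < 0 || b$y_min < 0 || b$x_max > width || b$y_max > height)
      stop(sprintf("box [%d,%d)x[%d,%d) outside %dx%d image",
                   b$x_min, b$x_max, b$y_min, b$y_max, width, height))
  }
  structure(list(image_id = image_id, width = width, height = height,
                 boxes = boxes),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image '%s' %dx%d, %d boxes>\n",
              x$image_id, x$width, x$height, length(x$boxes)))
  invisible(x)
}

#' Read a Pascal VOC annotation file
#'
#' Parses `annotation/object` entries, converts VOC's 1-based inclusive pixel
#' coordinates to the package's 0-based half-open convention
#' (`xmin - 1 .. xmax`), and clamps boxes to the image bounds. Image
#' dimensions are taken from the document's `size` element unless
#' `image_dims` overrides them.
#'
#' @param xml_source path to an XML file, or a single XML string.
#' @param image_dims optional `c(width, height)` override.
#' @return An [annotated_image()].
#' @export
read_voc_annotation <- function(xml_source, image_dims = NULL) {
  doc <- tryCatch(
    xml2::read_xml(xml_source),
    error = function(e) stop(sprintf("malformed VOC XML in '%s': %s",
                                     as.character(xml_source)[1],
                                     conditionMessage(e)))
  )
  if (is.null(image_dims)) {
    w <- xml2::xml_double(xml2::xml_find_first(doc, "./size/width"))
    h <- xml2::xml_double(xml2::xml_find_first(doc, "./size/height"))
    if (is.na(w) || is.na(h))
      stop("VOC document has no size element; pass image_dims")
    image_dims <- c(w, h)
  }
  width <- as.integer(image_dims[1]); height <- as.integer(image_dims[2])
  id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  if (is.na(id) || !nzchar(id)) id <- "image"
  id <- sub("\\.[A-Za-z]+$", "", id)

  objs <- xml2::xml_find_all(doc, "./object")
  boxes <- vector("list", length(objs))
  for (i in seq_along(objs)) {
    nm <- xml2::xml_text(xml2::xml_find_first(objs[[i]], "./name"))
    bb <- xml2::xml_find_first(objs[[i]], "./bndbox")
    if (inherits(bb, "xml_missing"))
      stop(sprintf("object %d has no bndbox element", i))
    co <- suppressWarnings(vapply(c("xmin", "ymin", "xmax", "ymax"),
      function(tag) xml2::xml_double(xml2::xml_find_first(bb, paste0("./", tag))),
      numeric(1)))
    if (anyNA(co))
      stop(sprintf("object %d has a missing or non-numeric coordinate", i))
    # 1-based inclusive -> 0-based half-open, then clamp to image bounds
    x0 <- max(0L, as.integer(round(co["xmin"])) - 1L)
    y0 <- max(0L, as.integer(round(co["ymin"])) - 1L)
    x1 <- min(width, as.integer(round(co["xmax"])))
    y1 <- min(height, as.integer(round(co["ymax"])))
    if (x0 >= x1 || y0 >= y1)
      stop(sprintf("object %d has a degenerate bndbox (xmax <= xmin or ymax <= ymin)", i))
    boxes[[i]] <- labeled_box(nm, x0, y0, x1, y1)
  }
  annotated_image(id, width, height, boxes)
}

#' Write a Pascal VOC annotation file
#'
#' Inverse of [read_voc_annotation()]: internal 0-based half-open boxes are
#' emitted as 1-based inclusive VOC coordinates, so read-write-read is an
#' identity.
#'
#' @param ann an [annotated_image()].
#' @param path output file path.
#' @param filename value of the `filename` element (default `image_id`.png).
#' @return `path`, invisibly.
#' @export
write_voc_annotation <- function(ann, path, filename = NULL) {
  if (is.null(filename)) filename <- paste0(ann$image_id, ".png")
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ann$width))
  xml2::xml_add_child(size, "height", as.character(ann$height))
  xml2::xml_add_child(size, "depth", "3")
  for (b in ann$boxes) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$class_name)
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(b$x_min + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(b$y_min + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(b$x_max))
    xml2::xml_add_child(bb, "ymax", as.character(b$y_max))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Remove duplicate and degenerate boxes
#'
#' Field annotations often contain several boxes drawn over the same plant.
#' Among boxes of the same class whose pairwise IoU reaches
#' `duplicate_iou_threshold`, only the first in input order is kept.
#' Degenerate boxes (already rejected by the [labeled_box()] constructor, but
#' tolerated here as raw lists) are dropped. Mislabelled classes are *not*
#' auto-corrected: that requires human judgement and is only surfaced through
#' the counts.
#'
#' @param boxes list of [labeled_box()] objects.
#' @param duplicate_iou_threshold IoU at or above which two same-class boxes
#'   are considered the same object (default 0.9).
#' @return list with elements `boxes` (the kept boxes) and `report`, a
#'   `cleaning_report` with counts `n_input`, `n_removed_duplicates`,
#'   `n_removed_degenerate`, `n_kept` summing to `n_input`.
#' @export
clean_annotations <- function(boxes, duplicate_iou_threshold = 0.9) {
  if (duplicate_iou_threshold <= 0 || duplicate_iou_threshold > 1)
    stop("duplicate_iou_threshold must be in (0, 1]")
  n_input <- length(boxes)
  ok <- vapply(boxes, function(b)
    is.numeric(b$x_min) && b$x_min < b$x_max && b$y_min < b$y_max,
    logical(1))
  n_degenerate <- sum(!ok)
  boxes <- boxes[ok]
  kept <- list()
  n_dup <- 0L
  for (b in boxes) {
    dup <- any(vapply(kept, function(k)
      identical(k$class_name, b$class_name) &&
        box_iou(k, b) >= duplicate_iou_threshold, logical(1)))
    if (dup) n_dup <- n_dup + 1L else kept[[length(kept) + 1L]] <- b
  }
  report <- structure(
    list(n_input = n_input, n_removed_duplicates = n_dup,
         n_removed_degenerate = n_degenerate, n_kept = length(kept)),
    class = "cleaning_report"
  )
  list(boxes = kept, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("cleaning: %d in, %d duplicates removed, %d degenerate removed, %d kept\n",
              x$n_input, x$n_removed_duplicates, x$n_removed_degenerate,
              x$n_kept))
  invisible(x)
}

#' Extract the image region under a box
#'
#' @param image RGB raster.
#' @param box a [labeled_box()] within the image bounds.
#' @return RGB raster of dimensions `(y_max - y_min) x (x_max - x_min) x 3`;
#'   crop pixel `(u, v)` equals image pixel `(x_min + u, y_min + v)`.
#' @export
crop_region <- function(image, box) {
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (box$x_min < 0 || box$y_min < 0 || box$x_max > w || box$y_max > h)
    stop(sprintf("box [%d,%d)x[%d,%d) exceeds %dx%d image extent",
                 box$x_min, box$x_max, box$y_min, box$y_max, w, h))
  image[(box$y_min + 1L):box$y_max, (box$x_min + 1L):box$x_max, , drop = FALSE]
}

#' Class-name to class-id mapping
#'
#' Reads a YAML or JSON file mapping label strings to integer class ids; the
#' default mapping is `crop = 0, weed = 1`.
#'
#' @param path optional path to a YAML/JSON mapping file.
#' @return named integer vector.
#' @export
read_class_map <- function(path = NULL) {
  if (is.null(path)) return(c(crop = 0L, weed = 1L))
  m <- yaml::read_yaml(path)
  out <- vapply(m, as.integer, integer(1))
  names(out) <- names(m)
  out
}
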