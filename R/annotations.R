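#' Construct a bounding-box annotation set for one image
#'
#' The in-memory representation of one image's PASCAL VOC annotations.
#' Coordinates are 0-based, half-open: a box covers pixel columns
#' `[xmin, xmax)` and rows `[ymin, ymax)`, so its area is
#' `(xmax - xmin) * (ymax - ymin)`. This convention makes intersection
#' arithmetic exact; conversion to VOC's 1-based inclusive convention is
#' confined to [read_voc_xml()] and [write_voc_xml()].
#'
#' An empty `objects` table is legal and marks the image as a negative
#' sample (no target-class object present).
#'
#' @param image_id unique image identifier (filename stem by convention).
#' @param width,height image dimensions in pixels.
#' @param objects data frame with columns `class_label`, `xmin`, `ymin`,
#'   `xmax`, `ymax` and optionally `difficult`, `truncated` (0/1 flags,
#'   preserved on round-trip but ignored by evaluation).
#' @param filename image filename stored in the XML; defaults to
#'   `<image_id>.png`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, width, height,
                           objects = empty_objects(),
                           filename = paste0(image_id, ".png")) {
  if (!is.character(image_id) || length(image_id) != 1 || !nzchar(image_id))
    fail("image_id must be a single non-empty string")
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1 || height < 1)
    fail("width and height must be positive integers")
  objects <- as.data.frame(objects)
  need <- c("class_label", "xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(objects)))
    fail("objects must have columns %s", paste(need, collapse = ", "))
  if (is.null(objects$difficult)) objects$difficult <- integer(nrow(objects))
  if (is.null(objects$truncated)) objects$truncated <- integer(nrow(objects))
  objects <- objects[c(need, "difficult", "truncated")]
  for (col in c("xmin", "ymin", "xmax", "ymax", "difficult", "truncated"))
    objects[[col]] <- as.integer(objects[[col]])
  objects$class_label <- as.character(objects$class_label)
  rownames(objects) <- NULL
  ann <- structure(
    list(image_id = image_id, width = width, height = height,
         objects = objects, filename = filename),
    class = "annotation_set")
  validate_annotation_set(ann)
  ann
}

empty_objects <- function() {
  data.frame(class_label = character(), xmin = integer(), ymin = integer(),
             xmax = integer(), ymax = integer(),
             difficult = integer(), truncated = integer())
}

validate_annotation_set <- function(ann) {
  o <- ann$objects
  if (nrow(o) == 0) return(invisible(ann))
  bad <- o$xmax <= o$xmin | o$ymax <= o$ymin
  if (any(bad))
    fail("image '%s': box %d has non-positive area", ann$image_id,
         which(bad)[1])
  out <- o$xmin < 0 | o$ymin < 0 | o$xmax > ann$width | o$ymax > ann$height
  if (any(out))
    fail("image '%s': box %d exceeds image bounds %dx%d", ann$image_id,
         which(out)[1], ann$width, ann$height)
  invisible(ann)
}

#' Is an annotation set a negative sample?
#'
#' A record is negative if and only if it annotates zero objects.
#'
#' @param ann an `annotation_set`.
#' @return logical scalar.
#' @export
is_negative <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  nrow(ann$objects) == 0
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s (%dx%d), %d object(s)%s\n",
              x$image_id, x$width, x$height, nrow(x$objects),
              if (is_negative(x)) " [negative]" else ""))
  if (nrow(x$objects)) print(x$objects)
  invisible(x)
}

#' Read a PASCAL VOC XML annotation file
#'
#' Parses the VOC dialect written by labelImg and kindred annotation tools.
#' VOC stores 1-based inclusive pixel coordinates; these are converted to
#' the package's 0-based half-open convention (`xmin - 1`, `xmax` unchanged,
#' likewise for y), which leaves box areas identical. Boxes extending past
#' the image bounds — common in hand-edited files — are clipped with a
#' warning; a box whose area is non-positive after conversion and clipping
#' is an error.
#'
#' @param path path to the XML file.
#' @return an [annotation_set()].
#' @export
read_voc_xml <- function(path) {
  if (!file.exists(path)) fail("annotation file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) fail("malformed XML in '%s': %s",
                                           path, conditionMessage(e)))
  num <- function(node, xp) {
    v <- xml2::xml_find_first(node, xp)
    if (inherits(v, "xml_missing")) fail("'%s': missing element %s", path, xp)
    as.numeric(xml2::xml_text(v))
  }
  width <- num(doc, "./size/width")
  height <- num(doc, "./size/height")
  fn <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  if (is.na(fn) || !nzchar(fn)) fn <- basename(path)
  image_id <- tools::file_path_sans_ext(fn)

  objs <- xml2::xml_find_all(doc, "./object")
  rows <- lapply(objs, function(node) {
    flag <- function(xp) {
      v <- xml2::xml_find_first(node, xp)
      if (inherits(v, "xml_missing")) 0L else as.integer(xml2::xml_text(v))
    }
    data.frame(
      class_label = xml2::xml_text(xml2::xml_find_first(node, "./name")),
      xmin = num(node, "./bndbox/xmin") - 1,
      ymin = num(node, "./bndbox/ymin") - 1,
      xmax = num(node, "./bndbox/xmax"),
      ymax = num(node, "./bndbox/ymax"),
      difficult = flag("./difficult"),
      truncated = flag("./truncated"))
  })
  objects <- if (length(rows)) do.call(rbind, rows) else empty_objects()

  if (nrow(objects)) {
    clipped <- pmax(objects$xmin, 0) != objects$xmin |
      pmax(objects$ymin, 0) != objects$ymin |
      pmin(objects$xmax, width) != objects$xmax |
      pmin(objects$ymax, height) != objects$ymax
    if (any(clipped))
      warning(sprintf("'%s': clipped %d box(es) to image bounds",
                      path, sum(clipped)), call. = FALSE)
    objects$xmin <- pmax(objects$xmin, 0)
    objects$ymin <- pmax(objects$ymin, 0)
    objects$xmax <- pmin(objects$xmax, width)
    objects$ymax <- pmin(objects$ymax, height)
    if (any(objects$xmax <= objects$xmin | objects$ymax <= objects$ymin))
      fail("'%s': box with non-positive area after coordinate conversion",
           path)
  }
  annotation_set(image_id, width, height, objects, filename = fn)
}

#' Write a PASCAL VOC XML annotation file
#'
#' Inverse of [read_voc_xml()]: internal 0-based half-open coordinates are
#' converted back to VOC's 1-based inclusive convention, so
#' `read_voc_xml(write_voc_xml(ann, f))` reproduces `ann` exactly.
#' A negative sample produces a file with no `<object>` elements.
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @param folder value for the `<folder>` element (cosmetic).
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(ann, path, folder = "images") {
  stopifnot(inherits(ann, "annotation_set"))
  validate_annotation_set(ann)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", folder)
  xml2::xml_add_child(doc, "filename", ann$filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ann$width))
  xml2::xml_add_child(size, "height", as.character(ann$height))
  xml2::xml_add_child(size, "depth", "1")
  o <- ann$objects
  for (i in seq_len(nrow(o))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", o$class_label[i])
    xml2::xml_add_child(obj, "pose", "Unspecified")
    xml2::xml_add_child(obj, "truncated", as.character(o$truncated[i]))
    xml2::xml_add_child(obj, "difficult", as.character(o$difficult[i]))
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(o$xmin[i] + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(o$ymin[i] + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(o$xmax[i]))
    xml2::xml_add_child(bb, "ymax", as.character(o$ymax[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Load a dataset manifest CSV
#'
#' The manifest ties image files to their source and positive/negative
#' status. Required header: `image_id,path,source_tag,is_negative`.
#' Negative status is declared explicitly rather than inferred from
#' directory layout so that split accounting (which counts positives only)
#' is unambiguous.
#'
#' @param path manifest CSV path.
#' @param annotations_dir optional directory of VOC XML files; when given,
#'   every non-negative record must have a `<image_id>.xml` there.
#' @param source_vocabulary optional character vector; when given, every
#'   `source_tag` must be drawn from it.
#' @return data frame of class `dataset_manifest` with columns
#'   `image_id`, `path`, `source_tag`, `is_negative`.
#' @export
load_manifest <- function(path, annotations_dir = NULL,
                          source_vocabulary = NULL) {
  if (!file.exists(path)) fail("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("image_id", "path", "source_tag", "is_negative")
  if (!all(need %in% names(df)))
    fail("manifest must have columns %s", paste(need, collapse = ","))
  df <- df[need]
  df$is_negative <- df$is_negative %in% c("TRUE", "True", "true", "1")
  check_ids(df$image_id)
  if (!is.null(source_vocabulary)) {
    bad <- setdiff(unique(df$source_tag), source_vocabulary)
    if (length(bad))
      fail("unknown source_tag(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(annotations_dir)) {
    pos <- df$image_id[!df$is_negative]
    missing <- pos[!file.exists(file.path(annotations_dir,
                                          paste0(pos, ".xml")))]
    if (length(missing))
      fail("missing annotation XML for non-negative record(s): %s",
           paste(missing, collapse = ", "))
  }
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' Write a dataset manifest CSV
#'
#' @param manifest data frame with columns `image_id`, `path`,
#'   `source_tag`, `is_negative`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("image_id", "path", "source_tag", "is_negative")
  stopifnot(all(need %in% names(manifest)))
  utils::write.csv(as.data.frame(manifest)[need], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a directory of VOC XML annotations into a named collection
#'
#' @param dir directory containing `<image_id>.xml` files.
#' @param ids optional character vector restricting which ids to read.
#' @return named list of [annotation_set()] keyed by `image_id`.
#' @export
read_voc_dir <- function(dir, ids = NULL) {
  files <- if (is.null(ids)) list.files(dir, pattern = "\\.xml$",
                                        full.names = TRUE)
           else file.path(dir, paste0(ids, ".xml"))
  anns <- lapply(sort(files), read_voc_xml)
  stats::setNames(anns, vapply(anns, `[[`, "", "image_id"))
}
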