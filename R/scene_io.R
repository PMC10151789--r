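# File coordinates are (x, y) = (col - 1, row - 1): 0-based, pixel centers
# at integer positions, row 0 at the top. All in-memory coordinates are
# 1-based (row, col).

default_label_map <- c(fruit = "fruit", stem = "stem")

resolve_label_map <- function(label_map) {
  if (is.null(label_map)) return(default_label_map)
  if (is.character(label_map) && is.null(names(label_map)) &&
      length(label_map) == 1 && file.exists(label_map)) {
    lm <- jsonlite::read_json(label_map, simplifyVector = TRUE)
    label_map <- unlist(lm)
  }
  if (!is.character(label_map) || is.null(names(label_map)))
    stop("`label_map` must be a named character vector or a JSON file path",
         call. = FALSE)
  if (!all(label_map %in% c("fruit", "stem")))
    stop("label map values must be 'fruit' or 'stem'", call. = FALSE)
  stats::setNames(unname(label_map), tolower(names(label_map)))
}

poly_file_to_rc <- function(points) {
  # points: n x 2 matrix of (x, y) -> (row, col)
  cbind(row = points[, 2] + 1, col = points[, 1] + 1)
}

poly_rc_to_file <- function(polygon) {
  cbind(polygon[, 2] - 1, polygon[, 1] - 1)
}

#' Load a Labelme annotation file as a scene
#'
#' Reads Labelme-dialect JSON (a `shapes` list of labelled polygons plus
#' `imageHeight` / `imageWidth`). Labels are mapped case-insensitively
#' through `label_map`; shapes with unmapped labels (e.g. whole-pumpkin
#' bounding boxes) are skipped with a warning, and non-polygon shape types
#' are ignored. Instance order in the file is preserved within each class.
#'
#' @param path Path to the JSON file.
#' @param label_map Named character vector mapping file labels to
#'   `"fruit"` / `"stem"`, or a path to a JSON object of the same; default
#'   maps `fruit -> fruit`, `stem -> stem`.
#' @return A [pp_scene()].
#' @export
load_labelme <- function(path, label_map = NULL) {
  label_map <- resolve_label_map(label_map)
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop(sprintf(
                   "malformed Labelme JSON in '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  for (key in c("imageHeight", "imageWidth"))
    if (is.null(js[[key]]))
      stop(sprintf("malformed Labelme JSON: missing key '%s'", key),
           call. = FALSE)
  h <- as.integer(js$imageHeight); w <- as.integer(js$imageWidth)
  fruits <- list(); stems <- list()
  for (shape in js$shapes) {
    if (!is.null(shape$shape_type) && shape$shape_type != "polygon") next
    if (is.null(shape$label))
      stop("malformed Labelme JSON: shape missing key 'label'", call. = FALSE)
    cls <- label_map[tolower(shape$label)]
    if (is.na(cls)) {
      warning(sprintf("skipping shape with unmapped label '%s'", shape$label),
              call. = FALSE)
      next
    }
    pts <- do.call(rbind, lapply(shape$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(pts) < 3)
      stop(sprintf("polygon for label '%s' has fewer than 3 vertices",
                   shape$label), call. = FALSE)
    poly <- poly_file_to_rc(pts)
    m <- instance_mask(rasterize(poly, h, w), cls, polygon = poly)
    if (cls == "fruit") fruits[[length(fruits) + 1L]] <- m
    else stems[[length(stems) + 1L]] <- m
  }
  id <- if (!is.null(js$imagePath)) sub("\\.[^.]*$", "", basename(js$imagePath))
        else sub("\\.[^.]*$", "", basename(path))
  pp_scene(h, w, fruits, stems, image_id = id)
}

# Uncompressed COCO run-length encoding: column-major counts, background first.
rle_encode <- function(raster) {
  v <- as.vector(raster)                 # column-major, matching COCO
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  as.integer(counts)
}

rle_decode <- function(counts, h, w) {
  vals <- rep(c(0L, 1L), length.out = length(counts))
  v <- rep(vals, counts)
  if (length(v) != h * w)
    stop("RLE counts do not cover the canvas", call. = FALSE)
  matrix(v, h, w)
}

#' Load one image's instances from a COCO-style annotation file
#'
#' Supports polygon segmentations (possibly multi-part) and uncompressed
#' run-length (`counts` list) segmentations. Categories are mapped
#' case-insensitively through `label_map`; an annotation whose category is
#' absent from the map is an error. `image_id` is matched against the COCO
#' numeric id (as a string) or the image `file_name`.
#'
#' @param path Path to the COCO instance JSON.
#' @param image_id Which image to load.
#' @inheritParams load_labelme
#' @return A [pp_scene()].
#' @export
load_coco <- function(path, image_id, label_map = NULL) {
  label_map <- resolve_label_map(label_map)
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop(sprintf(
                   "malformed COCO JSON in '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  imgs <- js$images
  hit <- NULL
  for (im in imgs) {
    if (identical(as.character(im$id), as.character(image_id)) ||
        identical(im$file_name, image_id)) { hit <- im; break }
  }
  if (is.null(hit))
    stop(sprintf("image id '%s' not found in '%s'", image_id, path),
         call. = FALSE)
  h <- as.integer(hit$height); w <- as.integer(hit$width)
  cats <- stats::setNames(
    vapply(js$categories, function(ct) tolower(ct$name), character(1)),
    vapply(js$categories, function(ct) as.character(ct$id), character(1)))
  fruits <- list(); stems <- list()
  for (an in js$annotations) {
    if (!identical(as.character(an$image_id), as.character(hit$id)))
      next
    cname <- cats[[as.character(an$category_id)]]
    if (is.null(cname))
      stop(sprintf("annotation category id %s missing from categories",
                   an$category_id), call. = FALSE)
    cls <- label_map[cname]
    if (is.na(cls))
      stop(sprintf("category '%s' absent from the label map", cname),
           call. = FALSE)
    seg <- an$segmentation
    polygon <- NULL
    if (!is.null(seg$counts)) {
      raster <- rle_decode(as.integer(unlist(seg$counts)), h, w)
    } else {
      raster <- matrix(0L, h, w)
      for (part in seg) {
        xy <- as.numeric(unlist(part))
        pts <- cbind(xy[seq(1, length(xy), 2)], xy[seq(2, length(xy), 2)])
        if (nrow(pts) < 3)
          stop("COCO polygon has fewer than 3 vertices", call. = FALSE)
        poly <- poly_file_to_rc(pts)
        raster <- pmax(raster, rasterize(poly, h, w))
        if (is.null(polygon)) polygon <- poly   # keep first part only
      }
      if (length(seg) != 1) polygon <- NULL
    }
    score <- if (!is.null(an$score)) as.numeric(an$score) else NULL
    m <- instance_mask(raster, cls, polygon = polygon, score = score)
    if (cls == "fruit") fruits[[length(fruits) + 1L]] <- m
    else stems[[length(stems) + 1L]] <- m
  }
  pp_scene(h, w, fruits, stems, image_id = as.character(image_id))
}

#' Load a label-map PNG as a scene
#'
#' Auxiliary import path: an 8-bit grayscale PNG where 0 is background,
#' odd pixel values are fruit instance ids and even nonzero values are stem
#' instance ids. Instances are ordered by ascending id within each class.
#'
#' @param path Path to the PNG.
#' @return A [pp_scene()].
#' @export
load_labelmap_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  ids <- round(img * 255)
  vals <- sort(setdiff(unique(as.vector(ids)), 0))
  fruits <- list(); stems <- list()
  for (v in vals) {
    m <- instance_mask(ids == v, if (v %% 2 == 1) "fruit" else "stem")
    if (v %% 2 == 1) fruits[[length(fruits) + 1L]] <- m
    else stems[[length(stems) + 1L]] <- m
  }
  pp_scene(nrow(ids), ncol(ids),
           fruits, stems, image_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Save a scene as Labelme or COCO JSON
#'
#' Round-trip exact: reloading a saved file reproduces every raster bit for
#' bit. The Labelme dialect stores each instance as its source polygon (or,
#' when absent, an exact pixel-edge boundary traced from the raster); the
#' COCO dialect stores uncompressed run-length masks, which also handles
#' masks with holes or multiple components.
#'
#' @param scene A [pp_scene()].
#' @param path Output file path.
#' @param dialect `"labelme"` or `"coco"`.
#' @return `path`, invisibly.
#' @export
save_scene <- function(scene, path, dialect = c("labelme", "coco")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(scene, "pp_scene"))
  all_inst <- c(scene$fruits, scene$stems)
  if (dialect == "labelme") {
    shapes <- lapply(all_inst, function(m) {
      poly <- if (!is.null(m$polygon)) m$polygon else raster_to_polygon(m)
      list(label = m$class_label,
           points = apply(poly_rc_to_file(poly), 1, as.list, simplify = FALSE),
           shape_type = "polygon")
    })
    out <- list(version = "5.0.0", shapes = shapes,
                imagePath = paste0(scene$image_id, ".png"),
                imageHeight = scene$height, imageWidth = scene$width)
  } else {
    anns <- lapply(seq_along(all_inst), function(k) {
      m <- all_inst[[k]]
      ann <- list(id = k, image_id = 1L,
                  category_id = if (m$class_label == "fruit") 1L else 2L,
                  segmentation = list(size = c(scene$height, scene$width),
                                      counts = rle_encode(m$raster)),
                  area = sum(m$raster), iscrowd = 0L)
      if (!is.null(m$score)) ann$score <- m$score
      ann
    })
    out <- list(
      images = list(list(id = 1L, file_name = scene$image_id,
                         height = scene$height, width = scene$width)),
      annotations = anns,
      categories = list(list(id = 1L, name = "fruit"),
                        list(id = 2L, name = "stem")))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
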