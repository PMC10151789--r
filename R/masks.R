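#' Create an instance mask
#'
#' An instance mask is one segmented object: a binary raster plus its class
#' ("fruit" or "stem"), an optional source polygon, and an optional detection
#' confidence score. All coordinates in this package are `(row, col)` with
#' row 1 at the image top and rows increasing downward, matching how R
#' indexes the raster matrix.
#'
#' @param raster Binary matrix (rows x cols); nonzero entries are instance
#'   pixels. Must contain at least one set pixel.
#' @param class_label `"fruit"` or `"stem"`.
#' @param polygon Optional two-column matrix of `(row, col)` vertices (may be
#'   subpixel) from which the raster was produced.
#' @param score Optional confidence in `[0, 1]`.
#' @return An object of class `instance_mask`.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
#' fruit <- instance_mask(m, "fruit")
#' mask_centroid(fruit)
#' @export
instance_mask <- function(raster, class_label = c("fruit", "stem"),
                          polygon = NULL, score = NULL) {
  class_label <- match.arg(class_label)
  if (!is.matrix(raster)) stop("`raster` must be a matrix", call. = FALSE)
  raster <- matrix(as.integer(raster != 0), nrow(raster), ncol(raster))
  if (sum(raster) < 1L) stop("instance mask has no set pixels", call. = FALSE)
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2 || nrow(polygon) < 3)
      stop("`polygon` must be a (>= 3) x 2 matrix of (row, col) vertices",
           call. = FALSE)
    storage.mode(polygon) <- "double"
    colnames(polygon) <- c("row", "col")
  }
  if (!is.null(score)) {
    score <- as.numeric(score)
    if (length(score) != 1 || is.na(score) || score < 0 || score > 1)
      stop("`score` must be a single value in [0, 1]", call. = FALSE)
  }
  structure(
    list(class_label = class_label, raster = raster, polygon = polygon,
         score = score),
    class = "instance_mask"
  )
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask> %s, %d x %d canvas, %d px%s%s\n",
              x$class_label, nrow(x$raster), ncol(x$raster), sum(x$raster),
              if (is.null(x$polygon)) "" else
                sprintf(", polygon[%d]", nrow(x$polygon)),
              if (is.null(x$score)) "" else sprintf(", score %.3f", x$score)))
  invisible(x)
}

#' Assemble a scene
#'
#' A scene is one image's worth of detections: canvas dimensions plus the
#' fruit and stem instance lists. Instance order is preserved exactly as
#' given (and as read from file), so indices are stable identifiers.
#'
#' @param height,width Canvas size in pixels.
#' @param fruits,stems Lists of [instance_mask()] objects whose rasters all
#'   have shape `height` x `width`.
#' @param image_id Opaque identifier string.
#' @return An object of class `pp_scene`.
#' @export
pp_scene <- function(height, width, fruits = list(), stems = list(),
                     image_id = "scene") {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 1, width >= 1)
  chk <- function(lst, lab) {
    for (m in lst) {
      if (!inherits(m, "instance_mask"))
        stop(sprintf("all %s must be instance_mask objects", lab), call. = FALSE)
      if (nrow(m$raster) != height || ncol(m$raster) != width)
        stop(sprintf("%s raster shape %d x %d does not match canvas %d x %d",
                     lab, nrow(m$raster), ncol(m$raster), height, width),
             call. = FALSE)
    }
  }
  chk(fruits, "fruits"); chk(stems, "stems")
  structure(
    list(height = height, width = width, fruits = unname(fruits),
         stems = unname(stems), image_id = as.character(image_id)),
    class = "pp_scene"
  )
}

#' @export
print.pp_scene <- function(x, ...) {
  cat(sprintf("<pp_scene> '%s' %d x %d, %d fruit(s), %d stem(s)\n",
              x$image_id, x$height, x$width, length(x$fruits),
              length(x$stems)))
  invisible(x)
}

#' Center of mass of a binary mask
#'
#' The arithmetic mean of the set-pixel coordinates. It always lies within
#' the mask's bounding box but, for bent or hollow shapes, not necessarily
#' on a set pixel.
#'
#' @param mask An [instance_mask()] or a binary matrix.
#' @return Numeric `(row, col)` of length 2, subpixel.
#' @export
mask_centroid <- function(mask) {
  r <- as_raster(mask)
  idx <- which(r != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask has no set pixels", call. = FALSE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

# Accept either instance_mask or raw binary matrix everywhere masks flow.
as_raster <- function(mask) {
  if (inherits(mask, "instance_mask")) return(mask$raster)
  if (is.matrix(mask)) return(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  stop("expected an instance_mask or a binary matrix", call. = FALSE)
}

#' Boundary pixels of a mask
#'
#' A set pixel is a boundary pixel when at least one of its four edge
#' neighbours is unset or off-canvas.
#'
#' @inheritParams mask_centroid
#' @return Integer matrix with columns `row`, `col`, in row-major order.
#' @export
boundary_pixels <- function(mask) {
  r <- as_raster(mask)
  h <- nrow(r); w <- ncol(r)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- r
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  inner <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  idx <- which(core == 1L & !inner, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("row", "col")
  idx
}
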