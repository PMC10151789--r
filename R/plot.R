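#' Tidy a scene into a per-pixel tibble
#'
#' Long-format view of a scene's set pixels, one row per (instance, pixel),
#' convenient for dplyr summaries and ggplot2.
#'
#' @param x A [pp_scene()].
#' @param ... Unused.
#' @return Tibble with `class`, `index`, `row`, `col`.
#' @method tidy pp_scene
#' @export
tidy.pp_scene <- function(x, ...) {
  one <- function(m, cls, i) {
    idx <- which(m$raster == 1L, arr.ind = TRUE)
    tibble::tibble(class = cls, index = i, row = idx[, 1], col = idx[, 2])
  }
  dplyr::bind_rows(
    purrr::imap(x$fruits, function(m, i) one(m, "fruit", i)),
    purrr::imap(x$stems, function(m, i) one(m, "stem", i)))
}

#' One-row summary of a scene
#'
#' @inheritParams tidy.pp_scene
#' @return Tibble with canvas size and instance counts.
#' @method glance pp_scene
#' @export
glance.pp_scene <- function(x, ...) {
  tibble::tibble(image_id = x$image_id, height = x$height, width = x$width,
                 n_fruits = length(x$fruits), n_stems = length(x$stems))
}

#' Plot a scene with optional matches and keypoints
#'
#' Renders the instance masks (fruits orange, stems green), and overlays the
#' picking annotation in the usual convention: a red cutting point, blue
#' grasping points, and yellow lines tying the three points of one pumpkin
#' together.
#'
#' @param object A [pp_scene()].
#' @param keypoints Optional tibble from [keypoints_for_scene()].
#' @param ... Unused.
#' @return A ggplot object (y axis flipped so row 1 is at the top).
#' @method autoplot pp_scene
#' @export
autoplot.pp_scene <- function(object, keypoints = NULL, ...) {
  px <- tidy(object)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = px,
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$class),
      alpha = 0.85) +
    ggplot2::scale_fill_manual(values = c(fruit = "#e08214", stem = "#1b7837")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(keypoints) && nrow(keypoints) > 0) {
    segs <- dplyr::bind_rows(
      dplyr::transmute(keypoints, x = .data$grasp1_col, y = .data$grasp1_row,
                       xend = .data$cut_col, yend = .data$cut_row),
      dplyr::transmute(keypoints, x = .data$grasp2_col, y = .data$grasp2_row,
                       xend = .data$cut_col, yend = .data$cut_row))
    p <- p +
      ggplot2::geom_segment(
        data = segs,
        ggplot2::aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
        colour = "#ffd700", linewidth = 0.6) +
      ggplot2::geom_point(
        data = keypoints,
        ggplot2::aes(x = .data$cut_col, y = .data$cut_row),
        colour = "red", size = 2.5) +
      ggplot2::geom_point(
        data = dplyr::bind_rows(
          dplyr::transmute(keypoints, col = .data$grasp1_col, row = .data$grasp1_row),
          dplyr::transmute(keypoints, col = .data$grasp2_col, row = .data$grasp2_row)),
        ggplot2::aes(x = .data$col, y = .data$row),
        colour = "blue", size = 2.5)
  }
  p
}

#' @export
plot.pp_scene <- function(x, y, ...) print(autoplot.pp_scene(x, ...))
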