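#' Line through the fruit and stem centroids
#'
#' The centroid line partitions the fruit into the two sides the grasping
#' points are taken from. The line is stored in the image's column/row
#' frame: the `vertical` form `col = c` when the two centroids share a
#' column (within 1e-9 px), otherwise the `sloped` form
#' `row = k * col + b`.
#'
#' @param fruit,stem [instance_mask()] objects or binary matrices.
#' @return A `centroid_line` list with fields `point_f`, `point_s`, `form`,
#'   and either `c` (vertical) or `k`, `b` (sloped).
#' @export
centroid_line <- function(fruit, stem) {
  pf <- mask_centroid(fruit); ps <- mask_centroid(stem)
  if (max(abs(pf - ps)) <= 1e-9)
    stop("coincident centroids: centroid line is undefined; drop the pair",
         call. = FALSE)
  if (abs(pf[["col"]] - ps[["col"]]) <= 1e-9) {
    out <- list(point_f = pf, point_s = ps, form = "vertical",
                c = (pf[["col"]] + ps[["col"]]) / 2)
  } else {
    k <- (ps[["row"]] - pf[["row"]]) / (ps[["col"]] - pf[["col"]])
    b <- pf[["row"]] - k * pf[["col"]]
    out <- list(point_f = pf, point_s = ps, form = "sloped", k = k, b = b)
  }
  structure(out, class = "centroid_line")
}

# Signed offset of points from a centroid line, plus perpendicular distance.
# Sign convention: negative = side 1 (vertical: col < c; sloped: row < k*col+b,
# i.e. the side above the line on screen).
line_eval <- function(line, rows, cols) {
  if (line$form == "vertical") {
    s <- cols - line$c
    list(signed = s, dist = abs(s))
  } else {
    s <- rows - (line$k * cols + line$b)
    list(signed = s, dist = abs(s) / sqrt(1 + line$k^2))
  }
}

#' Grasping points of a fruit
#'
#' On each side of the centroid line, the fruit pixel at maximum
#' perpendicular distance from the line is a grasping point, so a
#' two-finger gripper closes across the fruit's widest extent relative to
#' the fruit-stem axis. In the vertical-line case the distance reduces to
#' `|col - c|`. Pixels lying exactly on the line (perpendicular distance
#' within 1e-9 px) belong to neither side. Ties are broken by smallest row,
#' then smallest column. `grasp_1` is on the negative side of the signed
#' line evaluation (left of a vertical line; above a sloped one on screen).
#'
#' @param fruit [instance_mask()] or binary matrix.
#' @param line A [centroid_line()].
#' @return List with `grasp_1` and `grasp_2`, each a named `(row, col)`
#'   integer pair, plus the per-side distances `dist_1`, `dist_2`.
#' @export
grasp_points <- function(fruit, line) {
  r <- as_raster(fruit)
  idx <- which(r != 0L, arr.ind = TRUE)
  ev <- line_eval(line, idx[, 1], idx[, 2])
  on_line <- ev$dist <= 1e-9
  side1 <- ev$signed < 0 & !on_line
  side2 <- ev$signed > 0 & !on_line
  if (!any(side1)) stop("no fruit pixels on side 1 of the centroid line",
                        call. = FALSE)
  if (!any(side2)) stop("no fruit pixels on side 2 of the centroid line",
                        call. = FALSE)
  pick <- function(sel) {
    rows <- unname(idx[sel, 1]); cols <- unname(idx[sel, 2]); d <- ev$dist[sel]
    best <- which(d == max(d))
    best <- best[order(rows[best], cols[best])][1]
    list(pt = c(row = rows[best], col = cols[best]), dist = d[best])
  }
  g1 <- pick(side1); g2 <- pick(side2)
  list(grasp_1 = g1$pt, grasp_2 = g2$pt, dist_1 = g1$dist, dist_2 = g2$dist)
}

#' Cutting point of a stem
#'
#' The cutting point is the stem mask's center of mass. A bent stem can
#' place its centroid off the mask — an uncuttable location — so by default
#' the point is snapped to the nearest set pixel (ties: smallest row, then
#' column) and the snap distance is reported; pass `snap = FALSE` to get
#' the raw centroid regardless.
#'
#' @param stem [instance_mask()] or binary matrix.
#' @param snap Snap an off-mask centroid to the nearest stem pixel?
#' @return List with `point` (`(row, col)`, subpixel when unsnapped),
#'   `snapped` (logical) and `snap_distance` (pixels, 0 when no snap).
#' @export
cutting_point <- function(stem, snap = TRUE) {
  r <- as_raster(stem)
  ctr <- mask_centroid(r)
  pr <- floor(ctr[[1]] + 0.5); pc <- floor(ctr[[2]] + 0.5)
  if (r[pr, pc] == 1L || !snap)
    return(list(point = ctr, snapped = FALSE, snap_distance = 0))
  idx <- which(r != 0L, arr.ind = TRUE)
  d2 <- (idx[, 1] - ctr[[1]])^2 + (idx[, 2] - ctr[[2]])^2
  best <- which(d2 == min(d2))
  best <- best[order(idx[best, 1], idx[best, 2])][1]
  list(point = c(row = unname(idx[best, 1]), col = unname(idx[best, 2])),
       snapped = TRUE, snap_distance = sqrt(d2[best]))
}

#' Keypoints for every matched pair in a scene
#'
#' Composes [centroid_line()], [grasp_points()] and [cutting_point()] over
#' the pairs returned by [match_scene()]. Pairs with degenerate geometry
#' (coincident centroids, or an empty side of the line) are skipped with a
#' warning; unmatched instances yield no keypoints at all, which is what
#' filters heavily occluded pumpkins out of the picking plan.
#'
#' @param scene A [pp_scene()].
#' @param pairs Tibble from [match_scene()] (or any tibble with
#'   `fruit_index` / `stem_index` columns valid for `scene`).
#' @param snap_cut Passed to [cutting_point()] as `snap`.
#' @return Tibble with one row per successful pair: `image_id`,
#'   `fruit_index`, `stem_index`, `grasp1_row`, `grasp1_col`, `grasp2_row`,
#'   `grasp2_col`, `cut_row`, `cut_col`, `cut_snapped`, `cut_snap_dist`.
#' @export
keypoints_for_scene <- function(scene, pairs, snap_cut = TRUE) {
  stopifnot(inherits(scene, "pp_scene"))
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$fruit_index[k]; j <- pairs$stem_index[k]
    res <- tryCatch({
      ln <- centroid_line(scene$fruits[[i]], scene$stems[[j]])
      gp <- grasp_points(scene$fruits[[i]], ln)
      cp <- cutting_point(scene$stems[[j]], snap = snap_cut)
      tibble::tibble(
        image_id = scene$image_id, fruit_index = i, stem_index = j,
        grasp1_row = gp$grasp_1[["row"]], grasp1_col = gp$grasp_1[["col"]],
        grasp2_row = gp$grasp_2[["row"]], grasp2_col = gp$grasp_2[["col"]],
        cut_row = cp$point[["row"]], cut_col = cp$point[["col"]],
        cut_snapped = cp$snapped, cut_snap_dist = cp$snap_distance)
    }, error = function(e) {
      warning(sprintf("pair (fruit %d, stem %d) skipped: %s", i, j,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    rows[[k]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(image_id = character(), fruit_index = integer(),
                          stem_index = integer(), grasp1_row = double(),
                          grasp1_col = double(), grasp2_row = double(),
                          grasp2_col = double(), cut_row = double(),
                          cut_col = double(), cut_snapped = logical(),
                          cut_snap_dist = double())
  out
}
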