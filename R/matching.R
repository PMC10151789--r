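#' Matching configuration
#'
#' Two thresholds gate a fruit-stem candidate pair: a stem boundary pixel is
#' "adjacent" when its Euclidean distance to the nearest fruit pixel is
#' below `dis_thr`, and a candidate needs strictly more than `num_thr` such
#' adjacent pixels. Defaults admit a one-pixel-gap attachment with a contact
#' segment of at least six pixels, which is what an attached stem of
#' realistic width produces; both knobs are exposed because the right values
#' scale with image resolution.
#'
#' @param dis_thr Adjacency distance threshold in pixels (> 0).
#' @param num_thr Minimum adjacent-pixel count (the gate is strict `>`).
#' @return A `match_config` list.
#' @export
match_config <- function(dis_thr = 2.0, num_thr = 5L) {
  dis_thr <- as.numeric(dis_thr); num_thr <- as.integer(num_thr)
  if (!is.finite(dis_thr) || dis_thr <= 0)
    stop("`dis_thr` must be a positive finite number of pixels", call. = FALSE)
  if (is.na(num_thr) || num_thr < 0)
    stop("`num_thr` must be a non-negative integer", call. = FALSE)
  structure(list(dis_thr = dis_thr, num_thr = num_thr),
            class = "match_config")
}

#' Count stem boundary pixels adjacent to a fruit
#'
#' The count is over the stem's boundary pixels (set pixels with an unset
#' 4-neighbour), each tested against the Euclidean distance transform of
#' the fruit mask; a pixel counts when its distance to the nearest fruit
#' pixel is strictly below `dis_thr`. Restricting to the boundary makes the
#' count proportional to the length of the contact zone rather than the
#' stem's area.
#'
#' @param fruit,stem [instance_mask()] objects or binary matrices on the
#'   same canvas.
#' @param dis_thr Distance threshold in pixels.
#' @return Integer count of adjacent stem boundary pixels.
#' @export
adjacency_count <- function(fruit, stem, dis_thr = 2.0) {
  f <- as_raster(fruit); s <- as_raster(stem)
  if (!all(dim(f) == dim(s)))
    stop("fruit and stem rasters must share one canvas", call. = FALSE)
  if (sum(f) < 1 || sum(s) < 1)
    stop("masks must be nonempty", call. = FALSE)
  bp <- boundary_pixels(s)
  d <- EBImage::distmap(1 - f)     # Euclidean distance to the nearest fruit pixel
  sum(d[bp] < dis_thr)
}

#' Matching degree of a candidate pair
#'
#' `arctan(|dcol| / |drow|)` of the centroid displacement: 0 when the stem
#' sits directly above (or below) the fruit, approaching `pi/2` as the
#' offset becomes horizontal. The candidate with the smallest degree wins a
#' contested match. When the centroids share a row the limit value `pi/2`
#' is returned with attribute `limit = TRUE`.
#'
#' @param fruit_centroid,stem_centroid Numeric `(row, col)` points.
#' @return Angle in radians in `[0, pi/2]`.
#' @export
matching_degree <- function(fruit_centroid, stem_centroid) {
  drow <- abs(stem_centroid[[1]] - fruit_centroid[[1]])
  dcol <- abs(stem_centroid[[2]] - fruit_centroid[[2]])
  if (drow == 0) return(structure(pi / 2, limit = TRUE))
  atan(dcol / drow)
}

#' Match fruit masks to their stem masks
#'
#' Finds one-to-one fruit-stem correspondences using three priors of
#' dome-type (trellis) cultivation: the two masks of one pumpkin are
#' adjacent; under gravity the stem centroid lies strictly above the fruit
#' centroid (smaller row); and one fruit takes at most one stem. All
#' candidate pairs passing the above+adjacency gates are enumerated, then
#' resolved to a one-to-one assignment greedily in order of ascending
#' matching degree (ties: larger adjacency count, then smaller fruit and
#' stem index). At most `min(M, N)` pairs are returned for `M` fruits and
#' `N` stems. Unmatched instances — e.g. a fruit whose stem is fully
#' occluded — are reported in the `unmatched_fruits` / `unmatched_stems`
#' attributes so heavily occluded pumpkins can be filtered out rather than
#' mis-picked.
#'
#' @param scene A [pp_scene()].
#' @param config A [match_config()].
#' @return A tibble with one row per matched pair: `image_id`,
#'   `fruit_index`, `stem_index`, `adjacency_count`, `degree` (radians),
#'   plus attributes `unmatched_fruits` and `unmatched_stems` (integer
#'   index vectors).
#' @examples
#' f <- matrix(0L, 32, 32); f[15:25, 10:22] <- 1L
#' s <- matrix(0L, 32, 32); s[8:14, 15:18] <- 1L
#' sc <- pp_scene(32, 32, list(instance_mask(f, "fruit")),
#'                list(instance_mask(s, "stem")))
#' match_scene(sc)
#' @export
match_scene <- function(scene, config = match_config()) {
  stopifnot(inherits(scene, "pp_scene"), inherits(config, "match_config"))
  M <- length(scene$fruits); N <- length(scene$stems)
  empty <- tibble::tibble(image_id = character(), fruit_index = integer(),
                          stem_index = integer(), adjacency_count = integer(),
                          degree = double())
  if (M == 0 || N == 0) {
    attr(empty, "unmatched_fruits") <- seq_len(M)
    attr(empty, "unmatched_stems") <- seq_len(N)
    return(empty)
  }
  cf <- t(vapply(scene$fruits, mask_centroid, numeric(2)))
  cs <- t(vapply(scene$stems, mask_centroid, numeric(2)))
  # distance-to-fruit field computed once per fruit, reused across stems
  dmaps <- lapply(scene$fruits, function(m) EBImage::distmap(1 - m$raster))
  sbounds <- lapply(scene$stems, boundary_pixels)
  cand <- list()
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      if (cs[j, 1] >= cf[i, 1]) next        # gravity: stem strictly above
      adj <- sum(dmaps[[i]][sbounds[[j]]] < config$dis_thr)
      if (adj <= config$num_thr) next       # adjacency gate (strict >)
      d <- matching_degree(cf[i, ], cs[j, ])
      cand[[length(cand) + 1L]] <-
        list(i = i, j = j, adj = as.integer(adj), degree = as.numeric(d))
    }
  }
  if (length(cand) == 0) {
    attr(empty, "unmatched_fruits") <- seq_len(M)
    attr(empty, "unmatched_stems") <- seq_len(N)
    return(empty)
  }
  ctab <- dplyr::bind_rows(lapply(cand, tibble::as_tibble))
  ctab <- dplyr::arrange(ctab, .data$degree, dplyr::desc(.data$adj),
                         .data$i, .data$j)
  used_f <- rep(FALSE, M); used_s <- rep(FALSE, N)
  keep <- logical(nrow(ctab))
  for (k in seq_len(nrow(ctab))) {
    i <- ctab$i[k]; j <- ctab$j[k]
    if (!used_f[i] && !used_s[j]) {
      keep[k] <- TRUE; used_f[i] <- TRUE; used_s[j] <- TRUE
    }
  }
  out <- ctab[keep, ]
  out <- tibble::tibble(image_id = scene$image_id,
                        fruit_index = out$i, stem_index = out$j,
                        adjacency_count = out$adj, degree = out$degree)
  out <- dplyr::arrange(out, .data$fruit_index)
  attr(out, "unmatched_fruits") <- which(!used_f)
  attr(out, "unmatched_stems") <- which(!used_s)
  out
}
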