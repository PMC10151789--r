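#' Refinement schedule for point-rendering inference
#'
#' A coarse `start_size` x `start_size` probability map is upsampled by
#' `upsample_factor` for `steps` iterations, re-predicting the `n_points`
#' most uncertain cells at each scale. The defaults reproduce the standard
#' schedule: a 7x7 coarse prediction refined in 5 steps to 224x224, with
#' `n_points = 28^2 = 784` re-predicted points per step.
#'
#' @param start_size Side length of the coarse map (pixels).
#' @param steps Number of upsample-and-repredict iterations.
#' @param n_points Uncertain points re-predicted per iteration.
#' @param upsample_factor Integer scale factor per iteration (>= 2).
#' @return A `refine_schedule` list with the derived `final_size`.
#' @export
refine_schedule <- function(start_size = 7L, steps = 5L, n_points = 784L,
                            upsample_factor = 2L) {
  start_size <- as.integer(start_size); steps <- as.integer(steps)
  n_points <- as.integer(n_points)
  upsample_factor <- as.integer(upsample_factor)
  stopifnot(start_size >= 1, steps >= 1, n_points >= 1, upsample_factor >= 2)
  structure(list(start_size = start_size, steps = steps, n_points = n_points,
                 upsample_factor = upsample_factor,
                 final_size = start_size * upsample_factor^steps),
            class = "refine_schedule")
}

#' Validate a probability map
#'
#' @param values Numeric matrix with all entries in `[0, 1]`.
#' @param instance_ref Opaque identifier carried as an attribute.
#' @return The matrix, validated, with attribute `instance_ref`.
#' @export
prob_map <- function(values, instance_ref = "map") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(values < 0) || any(values > 1))
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  attr(values, "instance_ref") <- as.character(instance_ref)
  values
}

#' Select the most uncertain cells of a probability map
#'
#' Uncertainty is the closeness of a predicted probability to 0.5: the `n`
#' cells with the smallest `|value - 0.5|` are returned, most uncertain
#' first. Ties are broken by row-major scan order (row 1 left to right,
#' then row 2, ...). If the map has fewer than `n` cells, every cell is
#' returned. The function is pure: identical input gives identical output
#' ordering.
#'
#' @param map Numeric probability matrix.
#' @param n Number of cells to select.
#' @return Tibble with columns `row`, `col`, `value`, in selection order.
#' @export
select_uncertain_points <- function(map, n) {
  stopifnot(is.matrix(map), n >= 1)
  h <- nrow(map); w <- ncol(map)
  rm_idx <- seq_len(h * w)                     # row-major linear index
  rows <- (rm_idx - 1L) %/% w + 1L
  cols <- (rm_idx - 1L) %% w + 1L
  u <- abs(map[cbind(rows, cols)] - 0.5)
  ord <- order(u, rm_idx)[seq_len(min(n, h * w))]
  tibble::tibble(row = rows[ord], col = cols[ord],
                 value = map[cbind(rows[ord], cols[ord])])
}

# 1-D bilinear interpolation weights (align-corners-false convention):
# output cell centers are mapped into input cell-index space and the two
# flanking input cells are mixed; edge cells clamp.
interp_matrix <- function(n_in, factor) {
  n_out <- n_in * factor
  src <- (seq_len(n_out) - 0.5) / factor - 0.5   # 0-based input index space
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  w_hi <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), lo + 1)] <- W[cbind(seq_len(n_out), lo + 1)] + (1 - w_hi)
  W[cbind(seq_len(n_out), hi + 1)] <- W[cbind(seq_len(n_out), hi + 1)] + w_hi
  W
}

#' Bilinear upsampling of a probability map
#'
#' Separable bilinear interpolation with the align-corners-false
#' convention: an output cell takes the value at its center's position in
#' the input grid, with edge cells clamped to the border value. Output
#' values are convex combinations of input values, so they remain in
#' `[0, 1]` and a constant map stays exactly constant.
#'
#' @param map Numeric probability matrix.
#' @param factor Integer upscale factor (>= 2).
#' @return Matrix of size `dim(map) * factor`.
#' @export
bilinear_upsample <- function(map, factor) {
  stopifnot(is.matrix(map), factor >= 2)
  Rw <- interp_matrix(nrow(map), as.integer(factor))
  Cw <- interp_matrix(ncol(map), as.integer(factor))
  Rw %*% map %*% t(Cw)
}

#' Identity point predictor
#'
#' Returns the interpolated value already present at each queried cell, so
#' [refine()] degenerates to pure repeated bilinear upsampling. Useful as a
#' baseline and for verifying the refinement bookkeeping.
#'
#' @param coords Two-column matrix of normalized `(row, col)` query centers.
#' @param values Current map values at the queried cells.
#' @return `values`, unchanged.
#' @export
identity_predictor <- function(coords, values) values

#' Ground-truth oracle point predictor
#'
#' Builds a predictor that answers every query with the ground-truth
#' indicator of a reference mask, emulating a perfectly trained point head.
#' Queries arrive as normalized `(row, col)` cell centers in `[0, 1]^2` and
#' are looked up in the mask by containing pixel.
#'
#' @param truth [instance_mask()] or binary matrix at any resolution.
#' @return A predictor `function(coords, values)`.
#' @export
oracle_predictor <- function(truth) {
  r <- as_raster(truth)
  h <- nrow(r); w <- ncol(r)
  function(coords, values) {
    pr <- pmin(pmax(ceiling(coords[, 1] * h), 1L), h)
    pc <- pmin(pmax(ceiling(coords[, 2] * w), 1L), w)
    as.numeric(r[cbind(pr, pc)])
  }
}

#' Point-rendering refinement of a coarse probability map
#'
#' Iteratively upsamples a coarse per-instance probability map and
#' re-predicts only the most uncertain cells at each scale: per iteration
#' the map is bilinearly upsampled by `schedule$upsample_factor`, the
#' `schedule$n_points` cells with probability closest to 0.5 are selected
#' (these concentrate near the instance boundary, where segmentation is
#' hardest), and the supplied predictor overwrites their values. The
#' predictor abstracts the trained point head: it receives the queried
#' cells' normalized `(row, col)` centers in `[0, 1]^2` together with their
#' current interpolated values, and must return probabilities in `[0, 1]`.
#' Cells never queried keep their interpolated values.
#'
#' @param coarse Numeric matrix of size `schedule$start_size` squared.
#' @param predictor `function(coords, values) -> probabilities`; see
#'   [identity_predictor()] and [oracle_predictor()].
#' @param schedule A [refine_schedule()].
#' @return The final probability matrix (`final_size` squared) with
#'   attribute `n_queries`, the total number of predictor queries issued.
#' @export
refine <- function(coarse, predictor, schedule = refine_schedule()) {
  stopifnot(inherits(schedule, "refine_schedule"), is.matrix(coarse))
  if (nrow(coarse) != schedule$start_size || ncol(coarse) != schedule$start_size)
    stop(sprintf("coarse map must be %d x %d for this schedule",
                 schedule$start_size, schedule$start_size), call. = FALSE)
  map <- coarse
  queries <- 0L
  for (s in seq_len(schedule$steps)) {
    map <- bilinear_upsample(map, schedule$upsample_factor)
    pts <- select_uncertain_points(map, schedule$n_points)
    cells <- cbind(pts$row, pts$col)
    coords <- cbind((pts$row - 0.5) / nrow(map), (pts$col - 0.5) / ncol(map))
    p <- predictor(coords, map[cells])
    if (length(p) != nrow(pts) || anyNA(p) || any(p < 0) || any(p > 1))
      stop("predictor contract violation: expected probabilities in [0, 1], one per query",
           call. = FALSE)
    map[cells] <- p
    queries <- queries + nrow(pts)
  }
  attr(map, "n_queries") <- queries
  map
}
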