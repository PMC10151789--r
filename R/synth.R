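#' Specification for one synthetic harvest scene
#'
#' Describes a trellis ("dome-type") canopy scene at mask level: each
#' pumpkin is a horizontally elongated ellipse (the flattened dome-grown
#' fruit shape) with a ribbon stem whose base touches the fruit's top arc
#' within `stem_angle_jitter` of vertical — gravity makes real stems hang
#' close to vertical. Lone fruits and lone stems emulate instances whose
#' partner was missed or fully occluded; occluders emulate leaves eroding a
#' chunk out of a mask without changing which pumpkin it belongs to.
#'
#' @param canvas `(height, width)` in pixels.
#' @param n_pumpkins Number of fruit+stem pairs.
#' @param n_lone_fruits,n_lone_stems Distractor instances placed away from
#'   every other instance.
#' @param occluder_prob Per-instance probability of an occluding bite.
#' @param fruit_radius_range Semi-major (horizontal) fruit axis range, px.
#' @param stem_size_range Stem length range, px; stem width is about 40%
#'   of the length, clamped to `[6, 8]` px so the stem-fruit contact
#'   segment passes the default adjacency gate.
#' @param stem_angle_jitter Max |angle| of the stem from vertical, radians.
#' @param overlap_allowed Allow pumpkin units to be placed overlapping?
#' @param seed RNG seed; scenes are bit-reproducible from it.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(canvas = c(256, 256), n_pumpkins = 2,
                       n_lone_fruits = 0, n_lone_stems = 0,
                       occluder_prob = 0, fruit_radius_range = c(12, 22),
                       stem_size_range = c(10, 18),
                       stem_angle_jitter = 0.15, overlap_allowed = FALSE,
                       seed = 1L) {
  stopifnot(length(canvas) == 2, all(canvas >= 32),
            n_pumpkins >= 0, n_lone_fruits >= 0, n_lone_stems >= 0,
            occluder_prob >= 0, occluder_prob <= 1,
            all(fruit_radius_range > 0), all(stem_size_range > 0),
            stem_angle_jitter >= 0)
  structure(list(canvas = as.integer(canvas),
                 n_pumpkins = as.integer(n_pumpkins),
                 n_lone_fruits = as.integer(n_lone_fruits),
                 n_lone_stems = as.integer(n_lone_stems),
                 occluder_prob = occluder_prob,
                 fruit_radius_range = fruit_radius_range,
                 stem_size_range = stem_size_range,
                 stem_angle_jitter = stem_angle_jitter,
                 overlap_allowed = isTRUE(overlap_allowed),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

ellipse_raster <- function(h, w, cr, cc, a_col, b_row) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  matrix(as.integer(((cols - cc) / a_col)^2 + ((rows - cr) / b_row)^2 <= 1),
         h, w)
}

# Thick-segment raster: pixels within width/2 of the segment p0 -> p1.
ribbon_raster <- function(h, w, p0, p1, width) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  vr <- p1[1] - p0[1]; vc <- p1[2] - p0[2]
  len2 <- vr^2 + vc^2
  t <- ((rows - p0[1]) * vr + (cols - p0[2]) * vc) / len2
  t <- pmin(pmax(t, 0), 1)
  dr <- rows - (p0[1] + t * vr); dc <- cols - (p0[2] + t * vc)
  matrix(as.integer(dr^2 + dc^2 <= (width / 2)^2), h, w)
}

single_component <- function(raster) {
  if (sum(raster) == 0) return(FALSE)
  max(EBImage::bwlabel(raster)) == 1
}

# Bite a leaf-shaped (disk) occluder out of a mask. Leaves cover an
# instance from its silhouette edge inward, so the bite is anchored on a
# boundary pixel; the mask keeps >= 60% of its pixels and stays one
# 4-connected component, else the bite is abandoned.
occlude_mask <- function(raster, tries = 10) {
  idx <- boundary_pixels(raster)
  area <- sum(raster)
  reff <- sqrt(area / pi)
  for (t in seq_len(tries)) {
    ctr <- idx[sample.int(nrow(idx), 1), ]
    rad <- stats::runif(1, 0.2, 0.35) * reff
    d2 <- outer((seq_len(nrow(raster)) - ctr[1])^2, (seq_len(ncol(raster)) - ctr[2])^2, `+`)
    cand <- raster
    cand[d2 <= rad^2] <- 0L
    if (sum(cand) >= 0.6 * area && single_component(cand))
      return(list(raster = cand, occluded = TRUE))
  }
  list(raster = raster, occluded = FALSE)
}

# ---- independent brute-force ground truth -------------------------------
# These deliberately avoid the matching/keypoints code paths (plain loops
# and explicit formulas) so generator and detector cross-validate.

brute_centroid <- function(raster) {
  idx <- which(raster == 1L, arr.ind = TRUE)
  s <- c(0, 0)
  for (k in seq_len(nrow(idx))) s <- s + idx[k, ]
  s / nrow(idx)
}

#' Brute-force adjacency count
#'
#' All-pairs distance scan between the stem's boundary pixels and every
#' fruit pixel; used as an independent oracle for [adjacency_count()].
#'
#' @inheritParams adjacency_count
#' @return Integer count.
#' @export
brute_adjacency_count <- function(fruit, stem, dis_thr = 2.0) {
  f <- as_raster(fruit); s <- as_raster(stem)
  fi <- which(f == 1L, arr.ind = TRUE)
  bp <- boundary_pixels(s)
  cnt <- 0L
  for (k in seq_len(nrow(bp))) {
    d2 <- (fi[, 1] - bp[k, 1])^2 + (fi[, 2] - bp[k, 2])^2
    if (min(d2) < dis_thr^2) cnt <- cnt + 1L
  }
  cnt
}

#' Brute-force keypoints for one fruit-stem pair
#'
#' Exhaustive per-pixel search implementing the same geometric definitions
#' as the keypoints module from first principles: explicit coordinate sums
#' for the centroids, per-pixel point-line distances, a strict side
#' partition excluding on-line pixels, smallest-row-then-column
#' tie-breaking, and an exhaustive nearest-pixel scan for an off-mask stem
#' centroid. Used to generate ground truth and as the oracle the fast
#' implementation is tested against.
#'
#' @param fruit,stem [instance_mask()] objects or binary matrices.
#' @return List with `grasp_1`, `grasp_2`, `cut` (named `(row, col)`), and
#'   `cut_snapped`; or `NULL` when the geometry is degenerate.
#' @export
brute_force_keypoints <- function(fruit, stem) {
  f <- as_raster(fruit); s <- as_raster(stem)
  cf <- brute_centroid(f); cs <- brute_centroid(s)
  if (max(abs(cf - cs)) <= 1e-9) return(NULL)
  fi <- which(f == 1L, arr.ind = TRUE)
  vertical <- abs(cf[2] - cs[2]) <= 1e-9
  best <- list(`-1` = NULL, `1` = NULL)   # per-side (dist, row, col)
  for (k in seq_len(nrow(fi))) {
    r <- fi[k, 1]; c <- fi[k, 2]
    if (vertical) {
      sgn_val <- c - cf[2]
      dist <- abs(sgn_val)
    } else {
      kk <- (cs[1] - cf[1]) / (cs[2] - cf[2])
      bb <- cf[1] - kk * cf[2]
      sgn_val <- r - (kk * c + bb)
      dist <- abs(sgn_val) / sqrt(1 + kk^2)
    }
    if (dist <= 1e-9) next
    side <- if (sgn_val < 0) "-1" else "1"
    cur <- best[[side]]
    if (is.null(cur) || dist > cur[1] ||
        (dist == cur[1] && (r < cur[2] || (r == cur[2] && c < cur[3]))))
      best[[side]] <- c(dist, r, c)
  }
  if (is.null(best[["-1"]]) || is.null(best[["1"]])) return(NULL)
  best <- lapply(best, unname)
  cs <- unname(cs)
  pr <- floor(cs[1] + 0.5); pc <- floor(cs[2] + 0.5)
  if (s[pr, pc] == 1L) {
    cut <- c(row = cs[1], col = cs[2]); snapped <- FALSE
  } else {
    si <- which(s == 1L, arr.ind = TRUE)
    bd <- Inf; brow <- NA; bcol <- NA
    for (k in seq_len(nrow(si))) {
      d <- sqrt((si[k, 1] - cs[1])^2 + (si[k, 2] - cs[2])^2)
      if (d < bd || (d == bd && (si[k, 1] < brow ||
                                 (si[k, 1] == brow && si[k, 2] < bcol)))) {
        bd <- d; brow <- unname(si[k, 1]); bcol <- unname(si[k, 2])
      }
    }
    cut <- c(row = brow, col = bcol); snapped <- TRUE
  }
  list(grasp_1 = c(row = best[["-1"]][2], col = best[["-1"]][3]),
       grasp_2 = c(row = best[["1"]][2], col = best[["1"]][3]),
       cut = cut, cut_snapped = snapped)
}

# -------------------------------------------------------------------------

#' Generate a synthetic scene with ground truth
#'
#' Places `n_pumpkins` fruit+stem units plus lone distractors on the
#' canvas by rejection sampling (units keep an 8 px separation unless
#' `overlap_allowed`; lone instances keep 15 px from everything), then
#' optionally bites occluders out of instances. Ground-truth pairs and
#' keypoints are derived with the independent brute-force implementations,
#' never the detection code. Fully reproducible from `spec$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [scene_spec()].
#' @param image_id Identifier for the scene.
#' @return List with `scene` (a [pp_scene()]) and `truth` (list of `pairs`
#'   tibble, `keypoints` tibble, `occlusion` tibble).
#' @export
generate_scene <- function(spec, image_id = sprintf("synth_%06d", spec$seed)) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  h <- spec$canvas[1]; w <- spec$canvas[2]
  units <- list()      # bounding boxes (r0, r1, c0, c1) of placed material
  sep_ok <- function(bb, sep) {
    for (u in units) {
      if (bb[1] - sep <= u[2] && u[1] - sep <= bb[2] &&
          bb[3] - sep <= u[4] && u[3] - sep <= bb[4]) return(FALSE)
    }
    TRUE
  }
  fruits <- list(); stems <- list()
  pairs <- list()
  place_pumpkin <- function() {
    for (try in 1:200) {
      a <- stats::runif(1, spec$fruit_radius_range[1], spec$fruit_radius_range[2])
      b <- a * stats::runif(1, 0.6, 0.8)       # flatter than wide
      L <- stats::runif(1, spec$stem_size_range[1], spec$stem_size_range[2])
      sw <- min(max(round(0.4 * L), 6), 8)
      th <- if (spec$stem_angle_jitter > 0)
        stats::runif(1, -spec$stem_angle_jitter, spec$stem_angle_jitter) else 0
      need_top <- b + L + sw
      cr <- stats::runif(1, need_top + 2, h - b - 2)
      cc <- stats::runif(1, a + sw + 2, w - a - sw - 2)
      ext <- abs(sin(th)) * L + sw / 2
      bb <- c(cr - need_top, cr + b + 1, cc - max(a, ext) - 1, cc + max(a, ext) + 1)
      if (!spec$overlap_allowed && !sep_ok(bb, 8)) next
      fr <- ellipse_raster(h, w, cr, cc, a, b)
      # start the ribbon inside the fruit so it crosses the full top arc;
      # the overlap is carved out below, leaving a contact zone >= the
      # ribbon width hugging the arc at 1 px distance
      p0 <- c(cr - b + sw / 2, cc)
      p1 <- p0 + L * c(-cos(th), sin(th))
      st <- ribbon_raster(h, w, p0, p1, sw)
      if (sum(fr) < 20 || sum(st) < 10) next
      st[fr == 1L] <- 0L                       # instances do not overlap
      if (!single_component(st)) next
      units[[length(units) + 1L]] <<- bb
      return(list(fruit = fr, stem = st))
    }
    stop("canvas too small for the requested instance count", call. = FALSE)
  }
  place_lone <- function(kind) {
    for (try in 1:200) {
      if (kind == "fruit") {
        a <- stats::runif(1, spec$fruit_radius_range[1], spec$fruit_radius_range[2])
        b <- a * stats::runif(1, 0.6, 0.8)
        cr <- stats::runif(1, b + 2, h - b - 2)
        cc <- stats::runif(1, a + 2, w - a - 2)
        bb <- c(cr - b, cr + b, cc - a, cc + a)
        if (!sep_ok(bb, 15)) next
        units[[length(units) + 1L]] <<- bb
        return(ellipse_raster(h, w, cr, cc, a, b))
      } else {
        L <- stats::runif(1, spec$stem_size_range[1], spec$stem_size_range[2])
        sw <- min(max(round(0.4 * L), 6), 8)
        th <- stats::runif(1, -0.3, 0.3)
        r0 <- stats::runif(1, L + sw + 2, h - sw - 2)
        c0 <- stats::runif(1, L + sw + 2, w - L - sw - 2)
        p0 <- c(r0, c0); p1 <- p0 + L * c(-cos(th), sin(th))
        bb <- c(min(p0[1], p1[1]) - sw, max(p0[1], p1[1]) + sw,
                min(p0[2], p1[2]) - sw, max(p0[2], p1[2]) + sw)
        if (!sep_ok(bb, 15)) next
        units[[length(units) + 1L]] <<- bb
        return(ribbon_raster(h, w, p0, p1, sw))
      }
    }
    stop("canvas too small for the requested instance count", call. = FALSE)
  }
  for (k in seq_len(spec$n_pumpkins)) {
    pk <- place_pumpkin()
    fruits[[length(fruits) + 1L]] <- pk$fruit
    stems[[length(stems) + 1L]] <- pk$stem
    pairs[[k]] <- c(fruit_index = length(fruits), stem_index = length(stems))
  }
  for (k in seq_len(spec$n_lone_fruits))
    fruits[[length(fruits) + 1L]] <- place_lone("fruit")
  for (k in seq_len(spec$n_lone_stems))
    stems[[length(stems) + 1L]] <- place_lone("stem")
  occ <- list()
  bite <- function(lst, class_label) {
    lapply(seq_along(lst), function(i) {
      r <- lst[[i]]
      hit <- FALSE
      if (spec$occluder_prob > 0 && stats::runif(1) < spec$occluder_prob) {
        res <- occlude_mask(r)
        r <- res$raster; hit <- res$occluded
      }
      occ[[length(occ) + 1L]] <<- tibble::tibble(class = class_label,
                                                 index = i, occluded = hit)
      r
    })
  }
  fruits <- bite(fruits, "fruit")
  stems <- bite(stems, "stem")
  scene <- pp_scene(h, w,
                    lapply(fruits, instance_mask, class_label = "fruit"),
                    lapply(stems, instance_mask, class_label = "stem"),
                    image_id = image_id)
  pair_tab <- if (length(pairs) == 0) {
    tibble::tibble(image_id = character(), fruit_index = integer(),
                   stem_index = integer(), degree = double())
  } else {
    pt <- do.call(rbind, pairs)
    deg <- vapply(seq_len(nrow(pt)), function(k) {
      cf <- brute_centroid(fruits[[pt[k, 1]]])
      cs <- brute_centroid(stems[[pt[k, 2]]])
      if (cs[1] == cf[1]) pi / 2 else atan(abs(cs[2] - cf[2]) / abs(cs[1] - cf[1]))
    }, numeric(1))
    tibble::tibble(image_id = image_id, fruit_index = pt[, 1],
                   stem_index = pt[, 2], degree = deg)
  }
  kp <- dplyr::bind_rows(lapply(seq_len(nrow(pair_tab)), function(k) {
    bf <- brute_force_keypoints(fruits[[pair_tab$fruit_index[k]]],
                                stems[[pair_tab$stem_index[k]]])
    if (is.null(bf)) return(NULL)
    tibble::tibble(image_id = image_id,
                   fruit_index = pair_tab$fruit_index[k],
                   stem_index = pair_tab$stem_index[k],
                   grasp1_row = bf$grasp_1[["row"]], grasp1_col = bf$grasp_1[["col"]],
                   grasp2_row = bf$grasp_2[["row"]], grasp2_col = bf$grasp_2[["col"]],
                   cut_row = bf$cut[["row"]], cut_col = bf$cut[["col"]],
                   cut_snapped = bf$cut_snapped)
  }))
  list(scene = scene,
       truth = list(pairs = pair_tab, keypoints = kp,
                    occlusion = dplyr::bind_rows(occ)))
}

#' Generate and write a synthetic dataset
#'
#' One annotation file per spec plus a `manifest.json` listing every file
#' with its seed and the ground-truth pairs, so the whole dataset can be
#' regenerated bit-identically from the manifest alone.
#'
#' @param spec_list List of [scene_spec()] objects.
#' @param out_dir Output directory (created if needed).
#' @param dialect `"labelme"` or `"coco"`.
#' @return Tibble manifest (file, image_id, seed, n_pairs), invisibly.
#' @export
generate_dataset <- function(spec_list, out_dir, dialect = c("labelme", "coco")) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list(); truths <- list()
  for (k in seq_along(spec_list)) {
    spec <- spec_list[[k]]
    id <- sprintf("scene_%04d", k)
    gen <- generate_scene(spec, image_id = id)
    fn <- file.path(out_dir, paste0(id, ".json"))
    save_scene(gen$scene, fn, dialect = dialect)
    entries[[k]] <- tibble::tibble(file = basename(fn), image_id = id,
                                   seed = spec$seed,
                                   n_pairs = nrow(gen$truth$pairs))
    truths[[k]] <- gen$truth$pairs
  }
  manifest <- dplyr::bind_rows(entries)
  jsonlite::write_json(
    list(dialect = dialect, files = manifest,
         truth_pairs = dplyr::bind_rows(truths)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
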