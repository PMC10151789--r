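test_that("mask centroid is the mean of set-pixel coordinates", {
  m <- matrix(0L, 8, 8); m[3, 5] <- 1L
  expect_equal(unname(mask_centroid(m)), c(3, 5))
  m2 <- matrix(0L, 4, 4); m2[1:2, 1:2] <- 1L
  expect_equal(unname(mask_centroid(m2)), c(1.5, 1.5))
  blob <- make_blob(32, 32, 99)
  idx <- which(blob == 1L, arr.ind = TRUE)
  expect_equal(unname(mask_centroid(blob)),
               c(sum(idx[, 1]) / nrow(idx), sum(idx[, 2]) / nrow(idx)))
  expect_error(mask_centroid(matrix(0L, 3, 3)), "set pixels")
})

test_that("adjacency count matches all-pairs brute force", {
  # far-apart masks
  f <- make_rect(30, 30, 20, 25, 2, 7)
  s <- make_rect(30, 30, 2, 5, 20, 25)
  expect_equal(adjacency_count(f, s, 2), 0)
  # stem sharing a 6-pixel border segment with the fruit
  f2 <- make_rect(20, 20, 10, 15, 5, 14)
  s2 <- make_rect(20, 20, 4, 9, 7, 12)    # 6 cols touching fruit top
  expect_equal(adjacency_count(f2, s2, 1.5), 6)
  expect_equal(oracle_adjacency(f2, s2, 1.5), 6)
  # saturation: huge threshold counts every stem boundary pixel
  expect_equal(adjacency_count(f2, s2, 1e6), nrow(boundary_pixels(s2)))
  # randomized agreement with two independent oracles
  for (seed in 1:8) {
    set.seed(seed)
    f3 <- make_blob(40, 40, seed)
    s3 <- make_rect(40, 40, sample(1:10, 1), sample(11:20, 1),
                    sample(1:15, 1), sample(16:30, 1))
    thr <- runif(1, 1, 5)
    expect_equal(adjacency_count(f3, s3, thr), oracle_adjacency(f3, s3, thr))
    expect_equal(adjacency_count(f3, s3, thr), brute_adjacency_count(f3, s3, thr))
  }
  expect_error(adjacency_count(make_rect(5, 5, 1, 2, 1, 2),
                               make_rect(6, 6, 1, 2, 1, 2)), "canvas")
})

test_that("matching degree follows arctan(|dcol| / |drow|)", {
  expect_equal(as.numeric(matching_degree(c(10, 5), c(2, 5))), 0)
  expect_equal(as.numeric(matching_degree(c(10, 5), c(2, 13))), pi / 4)
  expect_equal(as.numeric(matching_degree(c(20, 4), c(8, 1))), atan(3 / 12))
  # cross-check against atan2 of the displacement
  expect_equal(as.numeric(matching_degree(c(20, 4), c(8, 1))),
               abs(atan2(1 - 4, abs(8 - 20))))
  lim <- matching_degree(c(5, 1), c(5, 9))
  expect_equal(as.numeric(lim), pi / 2)
  expect_true(isTRUE(attr(lim, "limit")))
})

test_that("a lone attached pumpkin is matched; a stem below is not", {
  sc <- make_pumpkin_scene()
  p <- match_scene(sc)
  expect_equal(nrow(p), 1)
  expect_equal(p$fruit_index, 1L)
  expect_equal(p$stem_index, 1L)
  expect_length(attr(p, "unmatched_fruits"), 0)

  # gravity constraint: same geometry flipped upside down yields nothing
  flip <- function(m) m$raster[nrow(m$raster):1, ]
  sc2 <- pp_scene(48, 48, list(instance_mask(flip(sc$fruits[[1]]), "fruit")),
                  list(instance_mask(flip(sc$stems[[1]]), "stem")))
  p2 <- match_scene(sc2)
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "unmatched_fruits"), 1L)
  expect_equal(attr(p2, "unmatched_stems"), 1L)
})

test_that("contested assignments equal the exhaustive minimum-degree matching", {
  # 3 fruits in a row, 2 stems, each stem adjacent to two fruits
  h <- 60; w <- 90
  f1 <- make_rect(h, w, 30, 44, 5, 30)
  f2 <- make_rect(h, w, 30, 44, 31, 56)
  f3 <- make_rect(h, w, 30, 44, 57, 82)
  s1 <- make_rect(h, w, 18, 29, 24, 35)   # straddles the f1|f2 boundary
  s2 <- make_rect(h, w, 18, 29, 52, 63)   # straddles the f2|f3 boundary
  sc <- pp_scene(h, w, lapply(list(f1, f2, f3), instance_mask, class_label = "fruit"),
                 lapply(list(s1, s2), instance_mask, class_label = "stem"))
  cfg <- match_config()
  # independent oracle: enumerate every one-to-one assignment of the gated
  # candidates and take the minimum total degree
  cand <- list()
  for (i in 1:3) for (j in 1:2) {
    cf <- mask_centroid(sc$fruits[[i]]$raster)
    cs <- mask_centroid(sc$stems[[j]]$raster)
    if (cs[1] >= cf[1]) next
    if (adjacency_count(sc$fruits[[i]], sc$stems[[j]], cfg$dis_thr) <= cfg$num_thr) next
    cand[[length(cand) + 1]] <- c(i, j, as.numeric(matching_degree(cf, cs)))
  }
  cand <- do.call(rbind, cand)
  expect_gte(nrow(cand), 4)               # every stem is contested
  best <- NULL
  for (size in seq_len(min(3, 2))) {
    combos <- utils::combn(nrow(cand), size)
    for (ci in seq_len(ncol(combos))) {
      sel <- cand[combos[, ci], , drop = FALSE]
      if (anyDuplicated(sel[, 1]) || anyDuplicated(sel[, 2])) next
      tot <- sum(sel[, 3])
      if (is.null(best) || size > nrow(best$sel) ||
          (size == nrow(best$sel) && tot < best$tot))
        best <- list(sel = sel, tot = tot)
    }
  }
  p <- match_scene(sc, cfg)
  got <- p[order(p$fruit_index), c("fruit_index", "stem_index")]
  want <- best$sel[order(best$sel[, 1]), 1:2, drop = FALSE]
  expect_equal(as.matrix(got), want, ignore_attr = TRUE)
})

test_that("matching respects cardinality, uniqueness and symmetry properties", {
  for (seed in 1:15) {
    g <- generate_scene(scene_spec(n_pumpkins = (seed %% 4) + 1,
                                   n_lone_fruits = seed %% 2,
                                   n_lone_stems = (seed + 1) %% 2,
                                   canvas = c(160, 160), seed = 1000 + seed))
    p <- match_scene(g$scene)
    expect_lte(nrow(p), min(length(g$scene$fruits), length(g$scene$stems)))
    expect_equal(anyDuplicated(p$fruit_index), 0)
    expect_equal(anyDuplicated(p$stem_index), 0)
  }

  # translation invariance
  g <- generate_scene(scene_spec(n_pumpkins = 2, canvas = c(120, 120), seed = 77))
  shift <- function(m, dr, dc) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0L, h, w)
    out[(1 + dr):h, (1 + dc):w] <- m[1:(h - dr), 1:(w - dc)]
    out
  }
  sc <- g$scene
  sc_t <- pp_scene(120, 120,
                   lapply(sc$fruits, function(m) instance_mask(shift(m$raster, 7, 9), "fruit")),
                   lapply(sc$stems, function(m) instance_mask(shift(m$raster, 7, 9), "stem")))
  p0 <- match_scene(sc); pt <- match_scene(sc_t)
  expect_equal(pt$fruit_index, p0$fruit_index)
  expect_equal(pt$stem_index, p0$stem_index)
  expect_equal(pt$degree, p0$degree, tolerance = 1e-12)

  # horizontal mirror invariance
  mir <- function(m) m[, ncol(m):1]
  sc_m <- pp_scene(120, 120,
                   lapply(sc$fruits, function(m) instance_mask(mir(m$raster), "fruit")),
                   lapply(sc$stems, function(m) instance_mask(mir(m$raster), "stem")))
  pm <- match_scene(sc_m)
  expect_equal(pm$fruit_index, p0$fruit_index)
  expect_equal(pm$stem_index, p0$stem_index)
  expect_equal(pm$degree, p0$degree, tolerance = 1e-12)
})
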