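# Shared fixture builders. Everything is generated in code; no data files.

make_disk <- function(h, w, cr, cc, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  matrix(as.integer((rows - cr)^2 + (cols - cc)^2 <= radius^2), h, w)
}

make_rect <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(0L, h, w)
  m[r0:r1, c0:c1] <- 1L
  m
}

# A random blobby "fruit": an ellipse with a few disk bites taken out,
# guaranteed nonempty.
make_blob <- function(h, w, seed) {
  set.seed(seed)
  cr <- runif(1, h * 0.3, h * 0.7); cc <- runif(1, w * 0.3, w * 0.7)
  a <- runif(1, w * 0.15, w * 0.3); b <- runif(1, h * 0.12, h * 0.25)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- matrix(as.integer(((cols - cc) / a)^2 + ((rows - cr) / b)^2 <= 1), h, w)
  for (i in seq_len(sample(0:2, 1))) {
    br <- runif(1, cr - b, cr + b); bc <- runif(1, cc - a, cc + a)
    bite <- make_disk(h, w, br, bc, runif(1, 2, 5))
    cand <- m; cand[bite == 1L] <- 0L
    if (sum(cand) > 30) m <- cand
  }
  m
}

# One simple attached pumpkin (rect fruit + rect stem touching its top),
# centered so the centroid line is exactly vertical.
make_pumpkin_scene <- function(h = 48, w = 48, image_id = "toy") {
  f <- make_rect(h, w, 24, 38, 14, 34)   # fruit, 15 x 21
  s <- make_rect(h, w, 12, 23, 21, 27)   # stem, 12 x 7, touching fruit top
  pp_scene(h, w, list(instance_mask(f, "fruit")),
           list(instance_mask(s, "stem")), image_id = image_id)
}

# Independent all-pairs adjacency oracle local to the tests (distinct from
# both adjacency_count and brute_adjacency_count): set-pixel to set-pixel
# minimum distances via outer().
oracle_adjacency <- function(fruit, stem, dis_thr) {
  f <- if (inherits(fruit, "instance_mask")) fruit$raster else fruit
  s <- if (inherits(stem, "instance_mask")) stem$raster else stem
  bp <- boundary_pixels(s)
  fi <- which(f == 1L, arr.ind = TRUE)
  dr <- outer(bp[, 1], fi[, 1], `-`)
  dc <- outer(bp[, 2], fi[, 2], `-`)
  dmin <- sqrt(apply(dr^2 + dc^2, 1, min))
  sum(dmin < dis_thr)
}

expect_same_raster <- function(a, b) {
  ra <- if (inherits(a, "instance_mask")) a$raster else a
  rb <- if (inherits(b, "instance_mask")) b$raster else b
  expect_identical(ra, rb)
}
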