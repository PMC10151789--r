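#' Rasterize a polygon onto a pixel canvas
#'
#' Fill rule: a pixel is set iff its center lies inside the polygon under
#' the even-odd rule, or exactly on the polygon boundary. Pixel centers sit
#' at integer `(row, col)` coordinates (pixel `(r, c)` has its center at
#' `(r, c)`). The result is independent of the vertex starting index and of
#' the winding orientation. Vertices may lie outside the canvas; the fill is
#' clipped to it.
#'
#' @param polygon Two-column matrix of `(row, col)` vertices, at least 3.
#' @param height,width Canvas size in pixels.
#' @return Integer `height` x `width` matrix of 0/1.
#' @examples
#' tri <- rbind(c(1, 1), c(5, 1), c(1, 5))
#' sum(rasterize(tri, 5, 5))  # 15
#' @export
rasterize <- function(polygon, height, width) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("polygon needs at least 3 (row, col) vertices", call. = FALSE)
  if (polygon_area(polygon) < 1e-12)
    stop("degenerate polygon with zero area", call. = FALSE)
  height <- as.integer(height); width <- as.integer(width)
  grid <- expand.grid(row = seq_len(height), col = seq_len(width))
  inside <- point_in_polygon(grid$row, grid$col, polygon)
  matrix(as.integer(inside), height, width)
}

# Shoelace area (absolute value).
polygon_area <- function(polygon) {
  r <- polygon[, 1]; c <- polygon[, 2]
  n <- nrow(polygon)
  j <- c(2:n, 1)
  abs(sum(c * r[j] - c[j] * r)) / 2
}

# Even-odd test, boundary-inclusive, vectorised over query points.
point_in_polygon <- function(pr, pc, polygon, eps = 1e-9) {
  n <- nrow(polygon)
  vr <- polygon[, 1]; vc <- polygon[, 2]
  inside <- rep(FALSE, length(pr))
  on_edge <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- vr[i]; xi <- vc[i]; yj <- vr[j]; xj <- vc[j]
    # on-segment: zero cross product and within the segment's bbox
    cross <- (xj - xi) * (pr - yi) - (yj - yi) * (pc - xi)
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    if (seg_len2 > 0) {
      on <- abs(cross) <= eps * sqrt(seg_len2) &
        pr >= pmin(yi, yj) - eps & pr <= pmax(yi, yj) + eps &
        pc >= pmin(xi, xj) - eps & pc <= pmax(xi, xj) + eps
      on_edge <- on_edge | on
    }
    # even-odd ray cast along +col
    crosses <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Trace a raster back to a boundary polygon
#'
#' Returns the polygon running along the pixel edges (vertices at
#' half-integer coordinates) that encloses exactly the set pixels: feeding
#' the result to [rasterize()] reproduces the raster bit for bit, which is
#' verified before returning. Only single 4-connected components without
#' holes can be traced; save complex masks through the COCO dialect (which
#' uses run-length encoding) instead.
#'
#' @inheritParams mask_centroid
#' @return Two-column matrix of `(row, col)` vertices, clockwise on screen.
#' @export
raster_to_polygon <- function(mask) {
  r <- as_raster(mask)
  h <- nrow(r); w <- ncol(r)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- r
  set <- which(pad == 1L, arr.ind = TRUE)
  # directed boundary edges, interior kept on the left (clockwise on screen);
  # vertices stored as doubled integers: vertex (r + 0.5, c + 0.5) -> (2r+1, 2c+1)
  edges_from <- list(); edges_to <- list()
  add <- function(fr, fc, tr, tc) {
    edges_from[[length(edges_from) + 1L]] <<- c(fr, fc)
    edges_to[[length(edges_to) + 1L]] <<- c(tr, tc)
  }
  for (k in seq_len(nrow(set))) {
    i <- set[k, 1]; j <- set[k, 2]            # padded coords; true pixel = (i-1, j-1)
    ri <- i - 1L; cj <- j - 1L
    t2 <- 2L * ri - 1L; b2 <- 2L * ri + 1L    # doubled half-integer rows
    l2 <- 2L * cj - 1L; r2 <- 2L * cj + 1L
    if (pad[i - 1L, j] == 0L) add(t2, r2, t2, l2)   # top, walk left
    if (pad[i + 1L, j] == 0L) add(b2, l2, b2, r2)   # bottom, walk right
    if (pad[i, j - 1L] == 0L) add(t2, l2, b2, l2)   # left, walk down
    if (pad[i, j + 1L] == 0L) add(b2, r2, t2, r2)   # right, walk up
  }
  nf <- length(edges_from)
  fr <- vapply(edges_from, `[`, integer(1), 1L)
  fc <- vapply(edges_from, `[`, integer(1), 2L)
  tr <- vapply(edges_to, `[`, integer(1), 1L)
  tc <- vapply(edges_to, `[`, integer(1), 2L)
  key <- function(a, b) paste(a, b)
  out_by_vertex <- split(seq_len(nf), key(fr, fc))
  used <- rep(FALSE, nf)
  # walk the loop, preferring the sharpest left turn at pinch vertices
  cur <- 1L
  path <- integer(0)
  repeat {
    used[cur] <- TRUE
    path <- c(path, cur)
    nxt <- out_by_vertex[[key(tr[cur], tc[cur])]]
    nxt <- nxt[!used[nxt]]
    if (length(nxt) == 0) break
    if (length(nxt) > 1) {
      din <- c(tr[cur] - fr[cur], tc[cur] - fc[cur])
      turn <- vapply(nxt, function(e) {
        dout <- c(tr[e] - fr[e], tc[e] - fc[e])
        # screen-coords cross product; negative = left turn
        din[1] * dout[2] - din[2] * dout[1]
      }, numeric(1))
      nxt <- nxt[order(turn)]
    }
    cur <- nxt[1]
  }
  if (length(path) < nf || !all(c(tr[cur], tc[cur]) == c(fr[path[1]], fc[path[1]])))
    stop("mask has holes or multiple components; use the COCO dialect",
         call. = FALSE)
  vr <- fr[path] / 2; vc <- fc[path] / 2
  # drop collinear mid-vertices
  n <- length(vr)
  keep <- vapply(seq_len(n), function(i) {
    p <- if (i == 1) n else i - 1L
    q <- if (i == n) 1L else i + 1L
    (vr[q] - vr[p]) * (vc[i] - vc[p]) != (vc[q] - vc[p]) * (vr[i] - vr[p])
  }, logical(1))
  poly <- cbind(row = vr[keep], col = vc[keep])
  if (!identical(rasterize(poly, h, w), r))
    stop("mask is too intricate to vectorise exactly; use the COCO dialect",
         call. = FALSE)
  poly
}
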