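## Shared raster-geometry helpers.
##
## Conventions used throughout the package:
##  * images are numeric matrices indexed [row, col]; a point is (x, y) with
##    x = column, y = row, origin top-left (display space);
##  * angles are undirected orientations in degrees in [0, 180), measured from
##    the +x axis counter-clockwise in display space, so the direction vector
##    of angle theta is (cos(theta), -sin(theta)) in (x, y).

deg2rad <- function(a) a * pi / 180

#' Undirected angular difference between two orientations
#'
#' @param a,b orientations in degrees (any real; reduced mod 180).
#' @return difference in degrees in \[0, 90\].
#' @keywords internal
angle_diff <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

## Direction unit vector for an angle in display space (y axis points down).
angle_dir <- function(theta) {
  t <- deg2rad(theta)
  c(cos(t), -sin(t))
}

## Orientation in [0, 180) of the vector (dx, dy) in display space.
vec_angle <- function(dx, dy) {
  a <- atan2(-dy, dx) * 180 / pi
  a %% 180
}

#' Bresenham line rasterization
#'
#' Integer pixel chain from `p0` to `p1` inclusive.
#'
#' @param p0,p1 integer (x, y) endpoints.
#' @return two-column integer matrix of (x, y) pixels.
#' @keywords internal
bresenham <- function(p0, p1) {
  x0 <- round(p0[1]); y0 <- round(p0[2])
  x1 <- round(p1[1]); y1 <- round(p1[2])
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  n <- max(dx, dy)
  if (n == 0L) return(cbind(x = x0, y = y0))
  t <- seq(0, 1, length.out = n + 1L)
  cbind(x = round(x0 + t * (x1 - x0)), y = round(y0 + t * (y1 - y0)))
}

## Pixels along a ray: `length` unit-spaced samples from `start` (inclusive)
## in direction `theta`.  Samples may repeat pixels for oblique angles; the
## sample count, not the distinct pixel count, defines averaging weight.
ray_samples <- function(start, theta, length) {
  n <- max(1L, as.integer(round(length)))
  d <- angle_dir(theta)
  i <- seq_len(n) - 1L
  cbind(x = round(start[1] + i * d[1]), y = round(start[2] + i * d[2]))
}

## Values of matrix `m` at (x, y) points; off-image points give `fill`.
px_values <- function(m, pts, fill = 0) {
  x <- pts[, 1]; y <- pts[, 2]
  ok <- x >= 1 & x <= ncol(m) & y >= 1 & y <= nrow(m)
  v <- rep(fill, length(x))
  if (any(ok)) v[ok] <- m[cbind(y[ok], x[ok])]
  v
}

## Euclidean length of a polyline given as (x, y) matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

## Integer offsets (dx, dy) of the disk of diameter d: pixel centers within
## distance d/2 of the center pixel.  Single rasterization rule shared by the
## width map, its oracle-facing documentation, and stroke rendering.
disk_offsets <- function(d) {
  r <- d / 2
  k <- ceiling(r)
  g <- expand.grid(dx = -k:k, dy = -k:k)
  g <- g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

## Mark TRUE on `mask` every pixel of the disk of diameter d around each
## (x, y) point; used for claim bookkeeping and stroke dilation.
stamp_disks <- function(mask, pts, d) {
  off <- disk_offsets(d)
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1] + off[, 1]
    y <- pts[i, 2] + off[, 2]
    ok <- x >= 1 & x <= ncol(mask) & y >= 1 & y <= nrow(mask)
    mask[cbind(y[ok], x[ok])] <- TRUE
  }
  mask
}

## Deduplicate an (x, y) pixel matrix preserving first occurrence order.
unique_pixels <- function(pts) {
  if (nrow(pts) == 0L) return(pts)
  key <- paste(pts[, 1], pts[, 2])
  pts[!duplicated(key), , drop = FALSE]
}

#' Connected components of a binary mask
#'
#' Two-pass union-find labeling with 8-connectivity.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background), labels 1..n in
#'   first-encounter (row-major) order.
#' @keywords internal
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      if (!mask[y, x]) next
      nb <- integer(0)
      if (y > 1L) {
        if (x > 1L && lab[y - 1L, x - 1L] > 0L) nb <- c(nb, lab[y - 1L, x - 1L])
        if (lab[y - 1L, x] > 0L) nb <- c(nb, lab[y - 1L, x])
        if (x < w && lab[y - 1L, x + 1L] > 0L) nb <- c(nb, lab[y - 1L, x + 1L])
      }
      if (x > 1L && lab[y, x - 1L] > 0L) nb <- c(nb, lab[y, x - 1L])
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[y, x] <- nxt
      } else {
        roots <- vapply(nb, find, integer(1))
        r <- min(roots)
        lab[y, x] <- r
        for (q in roots) parent[q] <- r
      }
    }
  }
  if (nxt == 0L) return(lab)
  root <- vapply(seq_len(nxt), find, integer(1))
  ## compact labels in first-encounter order of their roots
  remap <- integer(nxt)
  cnt <- 0L
  idx <- which(t(lab) > 0L)  # row-major scan order
  labs_rm <- t(lab)[idx]
  for (l in labs_rm) {
    r <- root[l]
    if (remap[r] == 0L) {
      cnt <- cnt + 1L
      remap[r] <- cnt
    }
  }
  lab[lab > 0L] <- remap[root[lab[lab > 0L]]]
  lab
}
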