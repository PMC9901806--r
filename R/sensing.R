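## Width-map ridge sensing and straight-line filament detection.
##
## The width map stores, per foreground pixel, the largest circle-mask
## diameter centered there whose miss fraction (disk pixels that fall on
## background or off the image) stays within the tolerance; diameters are
## grown until the condition first fails.  Both the straight-line sensor and
## the curve tracer walk on this map.

#' Compute the circle-mask width map
#'
#' For each foreground pixel the stored value is the largest disk diameter
#' `d` such that for every diameter up to `d` the fraction of disk pixels
#' that miss the foreground (background or off-image) is at most
#' `tolerance`. The disk of diameter `d` contains the pixels whose center
#' distance from the center pixel is at most `d/2`. Background pixels map
#' to 0.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param tolerance maximum allowed miss fraction in \[0, 1\] (default 0:
#'   strict).
#' @param max_diameter optional cap on the probed diameter (defaults to the
#'   shorter image side).
#' @return integer matrix of diameters, same shape as `mask`.
#' @export
compute_width_map <- function(mask, tolerance = 0, max_diameter = NULL) {
  stopifnot(is.matrix(mask), tolerance >= 0, tolerance <= 1)
  h <- nrow(mask); w <- ncol(mask)
  wm <- matrix(0L, h, w)
  if (!any(mask)) return(wm)
  if (is.null(max_diameter)) max_diameter <- min(h, w)
  m <- matrix(as.numeric(mask), h, w)
  alive <- mask  # pixels whose growth has not yet failed
  d <- 1L
  while (any(alive) && d <= max_diameter) {
    off <- disk_offsets(d)
    n_disk <- nrow(off)
    hits <- round(shift_sum(m, off))
    ok <- (n_disk - hits) / n_disk <= tolerance + 1e-12
    grew <- alive & ok
    wm[grew] <- d
    alive <- grew
    d <- d + 1L
  }
  wm
}

## Sum of m over the given (dx, dy) offsets for every pixel, zero-padded:
## equivalently a correlation of m with the offset indicator, done by FFT.
shift_sum <- function(m, off) {
  h <- nrow(m); w <- ncol(m)
  k <- max(abs(off))
  kern <- matrix(0, 2L * k + 1L, 2L * k + 1L)
  kern[cbind(off[, 2] + k + 1L, off[, 1] + k + 1L)] <- 1
  ## correlation = convolution with the flipped kernel; disks are symmetric
  conv2(m, kern)
}

#' Threshold a width map at a diameter
#'
#' Foreground exactly where the stored diameter is at least
#' `current_diameter`; at diameter 1 this reproduces the original mask's
#' foreground.
#'
#' @param wm integer width-map matrix.
#' @param current_diameter positive integer.
#' @return logical matrix.
#' @export
threshold_width_map <- function(wm, current_diameter) {
  stopifnot(current_diameter >= 1)
  wm > (current_diameter - 1)
}

#' Mean width along a directed ray
#'
#' Averages width-map values over `length` unit-spaced samples from `start`
#' (inclusive) in direction `angle`; samples falling off the image count as
#' width 0.
#'
#' @param wm width-map matrix.
#' @param start (x, y) start pixel.
#' @param angle direction in degrees (display-space convention).
#' @param length ray length in pixels (number of samples).
#' @return mean width (real).
#' @export
directional_mean_width <- function(wm, start, angle, length) {
  pts <- ray_samples(start, angle, length)
  mean(px_values(wm, pts, fill = 0))
}

## ---------------------------------------------------------------------------
## Orientation field

#' Create an empty orientation field
#' @param h,w image dimensions.
#' @return numeric matrix of `NA` (UNSET), to be filled with orientations in
#'   degrees in \[0, 180).
#' @export
orientation_field <- function(h, w) matrix(NA_real_, h, w)

#' Mark a filament's orientation into the field
#'
#' Each straight piece writes its own orientation over its rasterized pixels;
#' pixels already set keep their first (longer filament's) orientation.
#'
#' @param of orientation-field matrix.
#' @param f `fs_filament`.
#' @return updated field.
#' @export
mark_orientation <- function(of, f) {
  for (seg in filament_pieces(f)) {
    pts <- seg$pixels
    ok <- pts[, 1] >= 1 & pts[, 1] <= ncol(of) & pts[, 2] >= 1 & pts[, 2] <= nrow(of)
    idx <- cbind(pts[ok, 2], pts[ok, 1])
    unset <- is.na(of[idx])
    of[idx[unset, , drop = FALSE]] <- seg$angle
  }
  of
}

## ---------------------------------------------------------------------------
## Filament container

#' Construct a filament
#'
#' A filament is an ordered polyline of straight pieces: `points` are the
#' piece vertices (not every raster pixel — turning angles, hence curvature,
#' are measured at vertices), `widths` the per-vertex width-map diameters.
#'
#' @param points two-column (x, y) matrix of vertices, >= 2 rows.
#' @param widths per-vertex widths (recycled if length 1).
#' @param score accumulated width-sum score (gatherer score).
#' @return object of class `fs_filament`.
#' @export
fs_filament <- function(points, widths = 1, score = NA_real_) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  keep <- c(TRUE, rowSums(abs(diff(points))) > 0)  # drop repeated vertices
  points <- points[keep, , drop = FALSE]
  widths <- rep_len(widths, nrow(points))
  stopifnot(nrow(points) >= 2)
  structure(list(points = points, widths = as.numeric(widths),
                 score = score), class = "fs_filament")
}

#' @export
print.fs_filament <- function(x, ...) {
  cat(sprintf("<fs_filament: %d vertices, length %.1f px, mean width %.2f>\n",
              nrow(x$points), polyline_length(x$points), mean(x$widths)))
  invisible(x)
}

#' Filament polyline length (pixels)
#' @param f `fs_filament`.
#' @return Euclidean polyline length.
#' @export
filament_length <- function(f) polyline_length(f$points)

## Straight pieces of a filament: per piece the vertex pair, its orientation,
## and its Bresenham raster.
filament_pieces <- function(f) {
  p <- f$points
  lapply(seq_len(nrow(p) - 1L), function(i) {
    a <- p[i, ]; b <- p[i + 1L, ]
    list(from = a, to = b,
         angle = vec_angle(b[1] - a[1], b[2] - a[2]),
         pixels = bresenham(a, b))
  })
}

#' Rasterized centerline pixels of a filament
#' @param f `fs_filament`.
#' @return two-column (x, y) integer matrix, deduplicated.
#' @export
filament_pixels <- function(f) {
  unique_pixels(do.call(rbind, lapply(filament_pieces(f), `[[`, "pixels")))
}

## ---------------------------------------------------------------------------
## Straight-line sensor

#' Sensor settings for straight-line detection
#'
#' @param minimal_length minimal filament length `l_min` in pixels (>= 2).
#' @param tolerance width-map miss tolerance in \[0, 1\].
#' @param angle_increment angular sampling increment in degrees.
#' @return list of class `fs_sensor_settings`.
#' @export
sensor_settings <- function(minimal_length = 30, tolerance = 0,
                            angle_increment = 3) {
  stopifnot(minimal_length >= 2, tolerance >= 0, tolerance <= 1,
            angle_increment > 0)
  structure(list(minimal_length = minimal_length, tolerance = tolerance,
                 angle_increment = angle_increment),
            class = "fs_sensor_settings")
}

#' Detect straight filaments (line-sensor mode)
#'
#' Scans the foreground of the width map along sampled orientations, collects
#' maximal straight runs of length at least `l_min`, then accepts runs
#' longest-first: an accepted run claims the pixels it covers (its centerline
#' dilated to the local width) and later runs that are mostly (> 50%) on
#' claimed pixels are dropped, so a thick stroke yields one filament rather
#' than a bundle of parallel ones. Each accepted filament marks its angle in
#' the orientation field.
#'
#' @param wm width-map matrix (see [compute_width_map()]).
#' @param s `fs_sensor_settings`.
#' @return `list(filaments = <list of fs_filament, longest first>,
#'   orientation_field = <matrix>)`.
#' @export
scan_straight_filaments <- function(wm, s = sensor_settings()) {
  h <- nrow(wm); w <- ncol(wm)
  of <- orientation_field(h, w)
  claimed <- matrix(FALSE, h, w)
  filaments <- list()
  diameters <- sort(unique(wm[wm >= 1L]), decreasing = TRUE)
  angles <- seq(0, 180 - s$angle_increment, by = s$angle_increment)
  ## per-diameter pass, widest structures first: at each level only pixels
  ## with wm >= d are foreground, so a thick stroke is found at its
  ## centerline before its edge rows appear at lower diameters
  for (d in diameters) {
    fg <- threshold_width_map(wm, d)
    runs <- list()
    for (theta in angles) {
      for (line in scan_lines(h, w, theta)) {
        v <- fg[cbind(line[, 2], line[, 1])]
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
          seg <- line[starts[k]:ends[k], , drop = FALSE]
          if (polyline_length(seg[c(1L, nrow(seg)), , drop = FALSE]) + 1 <
              s$minimal_length) next
          runs[[length(runs) + 1L]] <- seg
        }
      }
    }
    if (length(runs) == 0L) next
    len <- vapply(runs, function(r)
      polyline_length(r[c(1L, nrow(r)), , drop = FALSE]), numeric(1))
    ord <- order(-len,
                 vapply(runs, function(r) r[1, 2], numeric(1)),
                 vapply(runs, function(r) r[1, 1], numeric(1)))
    for (i in ord) {
      seg <- runs[[i]]
      vals <- wm[cbind(seg[, 2], seg[, 1])]
      free <- !claimed[cbind(seg[, 2], seg[, 1])]
      if (mean(free) <= 0.5) next  # mostly re-using a longer line's pixels
      ## trim claimed pixels from the run ends
      first <- which(free)[1]; last <- which(free)[sum(free)]
      seg <- seg[first:last, , drop = FALSE]
      vals <- vals[first:last]
      if (polyline_length(seg[c(1L, nrow(seg)), , drop = FALSE]) + 1 <
          s$minimal_length) next
      ends <- seg[c(1L, nrow(seg)), , drop = FALSE]
      f <- fs_filament(ends, widths = mean(vals), score = sum(vals))
      claimed <- stamp_disks(claimed, seg, d = max(vals) + 2)
      of <- mark_orientation(of, f)
      filaments[[length(filaments) + 1L]] <- f
    }
  }
  len2 <- vapply(filaments, filament_length, numeric(1))
  list(filaments = filaments[order(-len2)], orientation_field = of)
}

## Families of parallel Bresenham lines at orientation theta covering an
## h x w grid, one line per unit perpendicular offset.
scan_lines <- function(h, w, theta) {
  d <- angle_dir(theta)
  lines <- list()
  if (abs(d[1]) >= abs(d[2])) {
    ## closer to horizontal: one line per starting row along the left edge,
    ## extended across the full width
    slope <- d[2] / d[1]
    y_extent <- abs(slope) * (w - 1)
    y0s <- seq(floor(1 - max(0, -slope * (w - 1))) - ceiling(y_extent),
               h + ceiling(y_extent))
    for (y0 in y0s) {
      p0 <- c(1, y0); p1 <- c(w, y0 + slope * (w - 1))
      ln <- bresenham(p0, p1)
      ok <- ln[, 1] >= 1 & ln[, 1] <= w & ln[, 2] >= 1 & ln[, 2] <= h
      if (any(ok)) lines[[length(lines) + 1L]] <- ln[ok, , drop = FALSE]
    }
  } else {
    slope <- d[1] / d[2]
    x_extent <- abs(slope) * (h - 1)
    x0s <- seq(1 - ceiling(x_extent) - ceiling(abs(slope) * h), w + ceiling(x_extent))
    for (x0 in x0s) {
      p0 <- c(x0, 1); p1 <- c(x0 + slope * (h - 1), h)
      ln <- bresenham(p0, p1)
      ok <- ln[, 1] >= 1 & ln[, 1] <= w & ln[, 2] >= 1 & ln[, 2] <= h
      if (any(ok)) lines[[length(lines) + 1L]] <- ln[ok, , drop = FALSE]
    }
  }
  lines
}
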