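## Per-filament and per-cell descriptors, the nematic order parameter, and
## the pixel-wise / object-wise comparison operators.

#' Descriptors of a single filament
#'
#' Length is the Euclidean polyline length, width the mean per-vertex width,
#' angle the orientation of the endpoint-to-endpoint chord in \[0, 180)
#' degrees (or, with `angle_mode = "weighted"`, the length-weighted circular
#' mean of piece orientations), and curvature the total absolute turning
#' angle (radians) at interior vertices divided by length — a discrete mean
#' curvature that converges to 1/R on circular arcs.
#'
#' @param f `fs_filament`.
#' @param img optional intensity image (unused by the current descriptors,
#'   accepted for interface stability).
#' @param id filament identifier for the record.
#' @param angle_mode `"chord"` (default) or `"weighted"`.
#' @return one-row data.frame: id, center_x, center_y, length, mean_width,
#'   angle, curvature.
#' @export
filament_descriptors <- function(f, img = NULL, id = 1L,
                                 angle_mode = c("chord", "weighted")) {
  angle_mode <- match.arg(angle_mode)
  p <- f$points
  n <- nrow(p)
  len <- polyline_length(p)
  angle <- if (angle_mode == "chord") {
    vec_angle(p[n, 1] - p[1, 1], p[n, 2] - p[1, 2])
  } else {
    segs <- filament_pieces(f)
    w <- vapply(segs, function(s) sqrt(sum((s$to - s$from)^2)), numeric(1))
    a <- vapply(segs, `[[`, numeric(1), "angle")
    (Arg(sum(w * exp(2i * deg2rad(a)))) * 180 / pi / 2) %% 180
  }
  curv <- 0
  if (n > 2L) {
    v <- diff(p)
    turn <- numeric(n - 2L)
    for (i in seq_len(n - 2L)) {
      a <- v[i, ]; b <- v[i + 1L, ]
      cosang <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      turn[i] <- acos(pmin(1, pmax(-1, cosang)))
    }
    curv <- sum(abs(turn)) / len
  }
  data.frame(id = id, center_x = mean(p[, 1]), center_y = mean(p[, 2]),
             length = len, mean_width = mean(f$widths),
             angle = unname(angle), curvature = unname(curv),
             row.names = NULL)
}

#' Descriptor table for a filament set
#' @param filaments list of `fs_filament`.
#' @param img optional intensity image.
#' @return data.frame, one row per filament (ids 1..n).
#' @export
filament_table <- function(filaments, img = NULL) {
  if (length(filaments) == 0L)
    return(data.frame(id = integer(0), center_x = numeric(0),
                      center_y = numeric(0), length = numeric(0),
                      mean_width = numeric(0), angle = numeric(0),
                      curvature = numeric(0)))
  do.call(rbind, lapply(seq_along(filaments), function(i)
    filament_descriptors(filaments[[i]], img, id = i)))
}

#' Nematic order parameter of a filament population
#'
#' Length-weighted nematic order
#' `S = |sum_k l_k exp(2 i theta_k)| / sum_k l_k`, in \[0, 1\]: 1 for perfect
#' alignment, 0 for an isotropic population. Invariant under global rotation.
#'
#' @param records data.frame with `length` and `angle` (degrees) columns, as
#'   produced by [filament_table()].
#' @return real in \[0, 1\].
#' @export
order_parameter <- function(records) {
  if (nrow(records) == 0L) stop("order_parameter needs at least one filament")
  w <- records$length
  th <- deg2rad(records$angle)
  Mod(sum(w * exp(2i * th))) / sum(w)
}

#' Cell shape descriptors from a binary mask
#'
#' Selects the largest 8-connected foreground component (or all foreground
#' with `component = "all"`). Area is the pixel count; centroid the pixel
#' mean; half axes derive from the eigenvalues of the second central moment
#' matrix (`2 * sqrt(eigenvalue)`, exact for solid ellipses); aspect ratio is
#' long/short; mean brightness averages `img` over the foreground; the
#' contour is the ordered outer boundary pixel polygon.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @param img optional intensity image for mean brightness.
#' @param component `"largest"` (default) or `"all"`.
#' @return list of class `fs_cell_record`: area, centroid, long_half_axis,
#'   short_half_axis, aspect_ratio, mean_brightness, contour.
#' @export
cell_shape_descriptors <- function(mask, img = NULL,
                                   component = c("largest", "all")) {
  component <- match.arg(component)
  if (!any(mask)) stop("empty mask: no cell to describe")
  sel <- mask
  if (component == "largest") {
    lab <- label_components(mask)
    counts <- tabulate(lab[lab > 0L])
    sel <- lab == which.max(counts)
  }
  idx <- which(sel, arr.ind = TRUE)  # (row, col)
  x <- idx[, 2]; y <- idx[, 1]
  area <- length(x)
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2); myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)$values
  long_ax <- 2 * sqrt(max(ev[1], 0))
  short_ax <- 2 * sqrt(max(ev[2], 1e-12))
  structure(list(
    area = area, centroid = c(x = cx, y = cy),
    long_half_axis = long_ax, short_half_axis = short_ax,
    aspect_ratio = long_ax / short_ax,
    mean_brightness = if (is.null(img)) NA_real_ else mean(img[sel]),
    contour = boundary_polygon(sel)
  ), class = "fs_cell_record")
}

## Ordered outer boundary: foreground pixels with a 4-neighbor background or
## border contact, sorted by angle around the centroid (adequate for the
## star-shaped blobs this package measures; not a general contour tracer).
boundary_polygon <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  bd <- mask & !inner
  idx <- which(bd, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  ctr <- colMeans(pts)
  pts[order(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])), , drop = FALSE]
}

## Rasterize a filament set into a pixel-key character vector.
filament_pixel_keys <- function(filaments, shape) {
  unlist(lapply(filaments, function(f) {
    px <- filament_pixels(f)
    ok <- px[, 1] >= 1 & px[, 1] <= shape[2] & px[, 2] >= 1 & px[, 2] <= shape[1]
    px <- px[ok, , drop = FALSE]
    paste(px[, 1], px[, 2])
  }))
}

#' Pixel-wise comparison of two filament sets
#'
#' Partitions the union of rasterized centerline pixels into pixels only in
#' A, only in B, and in both; the partition is exact.
#'
#' @param A,B lists of `fs_filament`.
#' @param shape image dimensions `c(h, w)`.
#' @return `list(only_A =, only_B =, both =)` pixel counts.
#' @export
compare_pixelwise <- function(A, B, shape) {
  pa <- unique(filament_pixel_keys(A, shape))
  pb <- unique(filament_pixel_keys(B, shape))
  both <- length(intersect(pa, pb))
  list(only_A = length(pa) - both, only_B = length(pb) - both, both = both)
}

#' Object-wise comparison of two filament sets
#'
#' Object `a` can match `b` iff at least `match_fraction` of `a`'s pixels are
#' covered by `b`'s pixels. Pairs are assigned greedily one-to-one in
#' decreasing overlap-count order (ties by smaller A index, then smaller B
#' index), mirroring the containment criterion of object-wise benchmarking
#' with a 75% default match fraction.
#'
#' @param A,B lists of `fs_filament`.
#' @param shape image dimensions `c(h, w)`.
#' @param match_fraction required covered fraction of the A object, in (0, 1\].
#' @return `list(matched = <two-column matrix of (a, b) indices>,
#'   only_A = <unmatched A indices>, only_B = <unmatched B indices>)`.
#' @export
compare_objectwise <- function(A, B, shape, match_fraction = 0.75) {
  stopifnot(match_fraction > 0, match_fraction <= 1)
  pa <- lapply(A, function(f) unique(filament_pixel_keys(list(f), shape)))
  pb <- lapply(B, function(f) unique(filament_pixel_keys(list(f), shape)))
  cand <- NULL
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    ov <- length(intersect(pa[[i]], pb[[j]]))
    if (length(pa[[i]]) > 0 && ov / length(pa[[i]]) >= match_fraction)
      cand <- rbind(cand, c(i, j, ov))
  }
  matched <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("a", "b")))
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    used_a <- logical(length(pa)); used_b <- logical(length(pb))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      matched <- rbind(matched, c(i, j))
    }
  }
  list(matched = matched,
       only_A = setdiff(seq_along(pa), matched[, 1]),
       only_B = setdiff(seq_along(pb), matched[, 2]))
}

#' Write a filament descriptor CSV
#'
#' One row per filament plus one `frame_summary` row (count, means, order
#' parameter), comma-separated with a header, written atomically.
#'
#' @param filaments list of `fs_filament`.
#' @param path output path.
#' @param img optional intensity image.
#' @return the descriptor data.frame, invisibly.
#' @export
write_filament_csv <- function(filaments, path, img = NULL) {
  tab <- filament_table(filaments, img)
  out <- cbind(row_type = rep("filament", nrow(tab)), tab)
  if (nrow(tab) > 0L) {
    summary_row <- data.frame(
      row_type = "frame_summary", id = nrow(tab),
      center_x = mean(tab$center_x), center_y = mean(tab$center_y),
      length = mean(tab$length), mean_width = mean(tab$mean_width),
      angle = mean(tab$angle), curvature = mean(tab$curvature))
    summary_row$angle <- (Arg(sum(tab$length * exp(2i * deg2rad(tab$angle)))) *
                            180 / pi / 2) %% 180
    out <- rbind(out, summary_row)
  }
  write_csv_atomic(out, path)
  invisible(tab)
}

## Atomic CSV write: temp file in the target directory, then rename.
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(format(df, trim = TRUE, scientific = FALSE, digits = 12),
                   tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
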