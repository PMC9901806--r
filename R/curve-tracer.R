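## Seeded bidirectional curve tracing over the width map.
##
## From each seed pixel (visited in decreasing width-map diameter order) the
## tracer probes all directions in increments of 3 deg * phi_diff over rays
## of length 2*l_str, keeps the opposite pair with the largest summed mean
## width, and grows a gatherer from each side: every step extends by at most
## l_str in the best of {previous direction, +/- one increment}, trailing
## points with insufficient width are trimmed, and growth stops when no
## candidate direction has mean width >= 1.  Joined gatherers become
## candidate filaments, ranked longest-first and validated against the
## orientation field built from previously accepted (longer) filaments.

#' Tracer settings for curved filament detection
#'
#' @param l_min minimal accepted filament length in pixels.
#' @param l_str length of straight probe pieces in pixels (step length; the
#'   seed probe uses rays of `2 * l_str`).
#' @param phi_diff multiplier of the hard-coded 3 degree probing increment
#'   (effective increment `3 * phi_diff` degrees).
#' @param alpha_tol tolerance angle in degrees for "conflicting orientation"
#'   (default 20).
#' @param conflict_fraction_limit a piece is accepted only if strictly less
#'   than this fraction of its pixels conflicts (default 0.30).
#' @param tolerance width-map miss tolerance passed to the width map.
#' @return list of class `fs_tracer_settings`.
#' @export
tracer_settings <- function(l_min = 30, l_str = 10, phi_diff = 1,
                            alpha_tol = 20, conflict_fraction_limit = 0.30,
                            tolerance = 0) {
  stopifnot(l_min >= l_str, l_str >= 2, phi_diff > 0,
            alpha_tol > 0, alpha_tol < 90,
            conflict_fraction_limit > 0, conflict_fraction_limit < 1)
  structure(list(l_min = l_min, l_str = l_str, phi_diff = phi_diff,
                 alpha_tol = alpha_tol,
                 conflict_fraction_limit = conflict_fraction_limit,
                 tolerance = tolerance),
            class = "fs_tracer_settings")
}

tracer_increment <- function(s) 3 * s$phi_diff

#' Probe the best opposite direction pair at a seed
#'
#' Probes directions `k * (3 * phi_diff)` degrees over \[0, 360) with rays of
#' length `2 * l_str` (seed pixel included) and returns the opposite pair
#' maximizing the summed directional mean width. Ties go to the smallest
#' angle.
#'
#' @param wm width-map matrix.
#' @param p (x, y) seed pixel with `wm[p] >= 1`.
#' @param s `fs_tracer_settings`.
#' @return `list(angle_a, angle_b, mean_width_a, mean_width_b)` with
#'   `angle_b = angle_a + 180`.
#' @export
seed_direction_pair <- function(wm, p, s = tracer_settings()) {
  inc <- tracer_increment(s)
  halves <- seq(0, 180 - inc / 2, by = inc)
  mw_fwd <- vapply(halves, function(a)
    directional_mean_width(wm, p, a, 2 * s$l_str), numeric(1))
  mw_bwd <- vapply(halves, function(a)
    directional_mean_width(wm, p, a + 180, 2 * s$l_str), numeric(1))
  tot <- mw_fwd + mw_bwd
  k <- which.max(tot)  # which.max takes the first maximum: smallest angle
  list(angle_a = halves[k], angle_b = halves[k] + 180,
       mean_width_a = mw_fwd[k], mean_width_b = mw_bwd[k])
}

#' Create a gatherer
#'
#' The growing half-curve: accumulated vertex points, their width-map values
#' (score = sum), and the current growth direction.
#'
#' @param p (x, y) start pixel.
#' @param direction initial direction in degrees.
#' @param wm width-map matrix.
#' @return list of class `fs_gatherer`.
#' @export
new_gatherer <- function(p, direction, wm) {
  structure(list(points = matrix(p, ncol = 2), direction = direction,
                 score = px_values(wm, matrix(p, ncol = 2)),
                 stopped = FALSE),
            class = "fs_gatherer")
}

#' Extend a gatherer by one probe step
#'
#' From the current endpoint, the mean width over an `l_str` ray is evaluated
#' for the previous direction and its two neighbors (+/- one increment); the
#' best direction is stepped if its mean width is at least 1, otherwise the
#' gatherer stops. Trailing points of the new piece whose pointwise width is
#' below 1 are trimmed back to the last sufficient point.
#'
#' @param g `fs_gatherer`.
#' @param wm width-map matrix.
#' @param s `fs_tracer_settings`.
#' @return updated gatherer; `$stopped` is `TRUE` once no direction remains.
#' @export
extend_gatherer <- function(g, wm, s = tracer_settings()) {
  if (g$stopped) return(g)
  inc <- tracer_increment(s)
  e <- g$points[nrow(g$points), ]
  cand <- g$direction + c(-inc, 0, inc)
  mw <- vapply(cand, function(a) {
    pts <- ray_samples(e + angle_dir(a), a, s$l_str)
    mean(px_values(wm, pts, fill = 0))
  }, numeric(1))
  best <- which.max(mw)  # tie: smaller turn first in cand order (-,0,+)
  ord <- c(2L, 1L, 3L)   # prefer straight on exact ties
  best <- ord[which.max(mw[ord])]
  if (mw[best] < 1) { g$stopped <- TRUE; return(g) }
  theta <- cand[best]
  step_pts <- ray_samples(e + angle_dir(theta), theta, s$l_str)
  vals <- px_values(wm, step_pts, fill = 0)
  suff <- which(vals >= 1)
  if (length(suff) == 0L) { g$stopped <- TRUE; return(g) }
  keep <- max(suff)  # trim trailing insufficient-width points
  new_end <- step_pts[keep, ]
  if (all(new_end == e)) { g$stopped <- TRUE; return(g) }
  g$points <- rbind(g$points, new_end)
  g$score <- g$score + sum(vals[seq_len(keep)])
  g$direction <- theta
  g  # a trimmed step just sets a new endpoint; only insufficient width stops
}

## Grow a gatherer until STOP; cap guards against pathological loops.
grow_gatherer <- function(g, wm, s, max_steps = 10000L) {
  for (i in seq_len(max_steps)) {
    g <- extend_gatherer(g, wm, s)
    if (g$stopped) break
  }
  g
}

## Join two opposite-direction gatherers sharing the seed into one filament.
join_gatherers <- function(g_a, g_b, wm) {
  pts <- rbind(g_a$points[rev(seq_len(nrow(g_a$points))), , drop = FALSE],
               g_b$points[-1L, , drop = FALSE])
  if (nrow(unique_pixels(round(pts))) < 2L) return(NULL)
  widths <- px_values(wm, round(pts))
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  if (sum(keep) < 2L) return(NULL)
  seed_w <- px_values(wm, matrix(g_a$points[1, ], ncol = 2))
  fs_filament(pts[keep, , drop = FALSE], widths = widths[keep],
              score = g_a$score + g_b$score - seed_w)  # seed counted once
}

#' Trace curved filaments in a binary mask
#'
#' Seeds are processed in decreasing width-map diameter order (row-major
#' within a diameter). Each seed grows two opposite gatherers which are
#' joined; candidates of length at least `l_min` provisionally claim their
#' covered pixels so stroke interiors do not re-seed. Candidates are then
#' ranked by (length, score, first point) and validated longest-first
#' against the orientation field ([validate_filament()]): accepted filaments
#' mark the field and claim their pixels, shortened ones re-enter the queue
#' at their new length, and a candidate mostly (> 50%) on already-claimed
#' pixels is dropped as a duplicate.
#'
#' @param mask logical matrix.
#' @param s `fs_tracer_settings`.
#' @param wm optional precomputed width map for `mask`.
#' @return list of accepted `fs_filament`, longest first.
#' @export
trace_filaments <- function(mask, s = tracer_settings(), wm = NULL) {
  h <- nrow(mask); w <- ncol(mask)
  if (is.null(wm)) wm <- compute_width_map(mask, tolerance = s$tolerance)
  if (!any(wm >= 1L)) return(list())
  seeded <- matrix(FALSE, h, w)  # provisional claims: suppress re-seeding
  candidates <- list()
  for (d in sort(unique(wm[wm >= 1L]), decreasing = TRUE)) {
    idx <- which(t(wm) == d)  # row-major order within the diameter
    xs <- (idx - 1L) %% w + 1L
    ys <- (idx - 1L) %/% w + 1L
    for (i in seq_along(idx)) {
      p <- c(xs[i], ys[i])
      if (seeded[p[2], p[1]]) next
      pair <- seed_direction_pair(wm, p, s)
      g_a <- grow_gatherer(new_gatherer(p, pair$angle_a, wm), wm, s)
      g_b <- grow_gatherer(new_gatherer(p, pair$angle_b, wm), wm, s)
      f <- join_gatherers(g_a, g_b, wm)
      if (is.null(f)) next
      if (filament_length(f) < s$l_min) next
      candidates[[length(candidates) + 1L]] <- f
      seeded <- claim_filament(seeded, f, extra = 1)
    }
  }
  mark_lines(candidates, h, w, s)
}

## Claim the pixels covered by a filament: centerline raster dilated to the
## filament width plus `extra` slack.  Seed suppression uses a narrow claim
## (candidates traced later must still be able to start from nearby
## structures); accepted filaments claim wider so ragged stroke edges cannot
## survive as sliver duplicates.
claim_filament <- function(mask, f, extra = 1) {
  d <- max(1, round(max(f$widths))) + extra
  for (seg in filament_pieces(f)) {
    mask <- stamp_disks(mask, seg$pixels, d)
  }
  mask
}

## Ranked acceptance: longest first, orientation-field validation, duplicate
## suppression via accepted-pixel claims.
mark_lines <- function(candidates, h, w, s) {
  of <- orientation_field(h, w)
  claimed <- matrix(FALSE, h, w)
  accepted <- list()
  rank_key <- function(f) c(-filament_length(f), -f$score,
                            f$points[1, 2], f$points[1, 1])
  queue <- candidates
  while (length(queue) > 0L) {
    keys <- t(vapply(queue, rank_key, numeric(4)))
    ord <- do.call(order, as.data.frame(keys))
    i <- ord[1]
    f <- queue[[i]]
    queue <- queue[-i]
    px <- filament_pixels(f)
    inb <- px[, 1] >= 1 & px[, 1] <= w & px[, 2] >= 1 & px[, 2] <= h
    px <- px[inb, , drop = FALSE]
    if (nrow(px) == 0L) next
    if (mean(!claimed[cbind(px[, 2], px[, 1])]) <= 0.5) next  # duplicate
    v <- validate_filament(f, of, s)
    if (v$decision == "ACCEPT") {
      of <- mark_orientation(of, f)
      claimed <- claim_filament(claimed, f, extra = 2)
      accepted[[length(accepted) + 1L]] <- f
    } else if (v$decision == "SHORTENED") {
      if (filament_length(v$filament) >= s$l_min)
        queue[[length(queue) + 1L]] <- v$filament
    }
  }
  len <- vapply(accepted, filament_length, numeric(1))
  accepted[order(-len)]
}

#' Validate a filament against the orientation field
#'
#' A pixel conflicts iff the field is set there and the undirected angular
#' difference to its straight piece's orientation exceeds `alpha_tol`. With
#' conflict fraction strictly below `conflict_fraction_limit` the filament is
#' accepted (exactly at the limit it is not). Otherwise, if an endpoint
#' carries a conflict the filament is shortened from the conflicting ends
#' inward to the first conflict-free points; with conflict-free endpoints it
#' is discarded.
#'
#' @param f `fs_filament`.
#' @param of orientation field built from previously accepted filaments.
#' @param s `fs_tracer_settings`.
#' @return `list(decision = "ACCEPT"|"SHORTENED"|"DISCARD",
#'   filament = <fs_filament or NULL>, conflict_fraction = <real>)`.
#' @export
validate_filament <- function(f, of, s = tracer_settings()) {
  pieces <- filament_pieces(f)
  px <- do.call(rbind, lapply(pieces, `[[`, "pixels"))
  ang <- unlist(lapply(pieces, function(sg) rep(sg$angle, nrow(sg$pixels))))
  dup <- duplicated(paste(px[, 1], px[, 2]))
  px <- px[!dup, , drop = FALSE]; ang <- ang[!dup]
  inb <- px[, 1] >= 1 & px[, 1] <= ncol(of) & px[, 2] >= 1 & px[, 2] <= nrow(of)
  px <- px[inb, , drop = FALSE]; ang <- ang[inb]
  field <- of[cbind(px[, 2], px[, 1])]
  conflict <- !is.na(field) & angle_diff(field, ang) > s$alpha_tol
  frac <- if (length(conflict) == 0L) 0 else mean(conflict)
  if (frac < s$conflict_fraction_limit)
    return(list(decision = "ACCEPT", filament = f, conflict_fraction = frac))
  n <- length(conflict)
  if (!conflict[1] && !conflict[n])
    return(list(decision = "DISCARD", filament = NULL, conflict_fraction = frac))
  first <- if (conflict[1]) which(!conflict)[1] else 1L
  last <- if (conflict[n]) rev(which(!conflict))[1] else n
  if (is.na(first) || is.na(last) || last - first < 1L)
    return(list(decision = "DISCARD", filament = NULL, conflict_fraction = frac))
  sub <- px[first:last, , drop = FALSE]
  short <- fs_filament(sub[c(1L, nrow(sub)), , drop = FALSE],
                       widths = mean(f$widths), score = f$score)
  ## keep interior vertices that survived the cut
  keep_v <- apply(f$points, 1, function(pt)
    any(abs(sub[, 1] - pt[1]) < 1 & abs(sub[, 2] - pt[2]) < 1))
  verts <- rbind(sub[1, ], f$points[keep_v, , drop = FALSE], sub[nrow(sub), ])
  short <- fs_filament(verts, widths = mean(f$widths), score = f$score)
  list(decision = "SHORTENED", filament = short, conflict_fraction = frac)
}
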