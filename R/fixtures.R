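## Ground-truthed synthetic fixtures: stroke images (lines, circular arcs,
## quadratic Beziers) and blob movies with scripted cell events.  Truth
## tables are computed analytically from the specs before rasterization —
## never measured back from pixels — so they can serve as independent
## oracles for detection, tracking, and event monitoring.
##
## Default world: 8-bit canvas, background 10, foreground 200, additive
## Gaussian noise with sigma in {0, 5, 15}, chosen so that the default
## tracer settings (l_min = 30, l_str = 10) operate in-regime.

#' Specify a stroke
#'
#' Kinds: `"line"` (p0 -> p1), `"arc"` (circle center, radius, start/end
#' angle in degrees, counter-clockwise in display space), `"bezier"`
#' (quadratic, control points p0, p1, p2). Arc length is closed-form for
#' lines (chord) and arcs (R * theta) and Gauss-Legendre quadrature to 1e-6
#' for Beziers; mean curvature is 0, 1/R, and arc-length-averaged analytic
#' curvature respectively.
#'
#' @param kind `"line"`, `"arc"` or `"bezier"`.
#' @param width stroke width in pixels (odd widths rasterize symmetrically).
#' @param intensity foreground intensity.
#' @param ... kind parameters: `p0`, `p1` (line); `center`, `radius`,
#'   `theta0`, `theta1` (arc); `p0`, `p1`, `p2` (bezier).
#' @return list of class `fs_stroke` with `length` and `curvature` truth.
#' @export
stroke_spec <- function(kind = c("line", "arc", "bezier"), width = 3,
                        intensity = 200, ...) {
  kind <- match.arg(kind)
  args <- list(...)
  spec <- c(list(kind = kind, width = width, intensity = intensity), args)
  if (kind == "line") {
    spec$length <- sqrt(sum((args$p1 - args$p0)^2))
    spec$curvature <- 0
    spec$angle <- vec_angle(args$p1[1] - args$p0[1], args$p1[2] - args$p0[2])
  } else if (kind == "arc") {
    span <- abs(deg2rad(args$theta1 - args$theta0))
    spec$length <- args$radius * span
    spec$curvature <- 1 / args$radius
    spec$angle <- NA_real_
  } else {
    gl <- gauss_legendre_32()
    deriv <- function(t) {
      d <- 2 * (1 - t) %o% (args$p1 - args$p0) + 2 * t %o% (args$p2 - args$p1)
      sqrt(rowSums(d^2))
    }
    spec$length <- sum(gl$w * deriv((gl$x + 1) / 2)) / 2
    spec$curvature <- bezier_mean_curvature(args$p0, args$p1, args$p2, gl)
    spec$angle <- NA_real_
  }
  structure(spec, class = "fs_stroke")
}

gauss_legendre_32 <- function() {
  ## nodes/weights on [-1, 1] from the Golub-Welsch eigen construction
  k <- seq_len(31)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, 32, 32)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

## arc-length-weighted mean of |kappa(t)| for a quadratic Bezier
bezier_mean_curvature <- function(p0, p1, p2, gl = gauss_legendre_32()) {
  t <- (gl$x + 1) / 2
  d1 <- 2 * (1 - t) %o% (p1 - p0) + 2 * t %o% (p2 - p1)
  d2 <- matrix(rep(2 * (p2 - 2 * p1 + p0), each = length(t)), ncol = 2)
  speed <- sqrt(rowSums(d1^2))
  kappa <- abs(d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / speed^3
  sum(gl$w * kappa * speed) / sum(gl$w * speed)
}

## Dense centerline sample of a stroke (sub-pixel spacing).
stroke_centerline <- function(spec, step = 0.25) {
  n <- max(8L, ceiling(spec$length / step))
  t <- seq(0, 1, length.out = n)
  if (spec$kind == "line") {
    cbind(spec$p0[1] + t * (spec$p1[1] - spec$p0[1]),
          spec$p0[2] + t * (spec$p1[2] - spec$p0[2]))
  } else if (spec$kind == "arc") {
    th <- deg2rad(spec$theta0 + t * (spec$theta1 - spec$theta0))
    cbind(spec$center[1] + spec$radius * cos(th),
          spec$center[2] - spec$radius * sin(th))
  } else {
    cbind((1 - t)^2 * spec$p0[1] + 2 * (1 - t) * t * spec$p1[1] + t^2 * spec$p2[1],
          (1 - t)^2 * spec$p0[2] + 2 * (1 - t) * t * spec$p1[2] + t^2 * spec$p2[2])
  }
}

#' Render strokes to an image with ground truth
#'
#' Hard (non-antialiased) rendering: a pixel is foreground iff its center
#' lies within `width / 2` of the stroke centerline — with `sigma = 0` the
#' foreground is exactly the dilated rasterized centerline. Additive
#' Gaussian noise is clipped to \[0, 255\]; a fixed seed reproduces the image
#' bit-identically.
#'
#' @param specs list of `fs_stroke`.
#' @param shape canvas `c(h, w)` (default 256 x 256).
#' @param background background level (default 10).
#' @param sigma Gaussian noise standard deviation (default 0).
#' @param seed RNG seed (required when `sigma > 0`).
#' @return `list(image = <matrix>, truth = <data.frame id, kind, length,
#'   width, angle, curvature>)`.
#' @export
render_strokes <- function(specs, shape = c(256, 256), background = 10,
                           sigma = 0, seed = NULL) {
  img <- matrix(background, shape[1], shape[2])
  for (spec in specs) {
    ctr <- stroke_centerline(spec)
    if (any(ctr[, 1] < 1 | ctr[, 1] > shape[2] |
            ctr[, 2] < 1 | ctr[, 2] > shape[1]))
      stop("stroke extends outside the canvas")
    mask <- matrix(FALSE, shape[1], shape[2])
    mask <- stamp_disks(mask, cbind(round(ctr[, 1]), round(ctr[, 2])),
                        d = spec$width)
    img[mask] <- spec$intensity
  }
  if (sigma > 0) {
    if (is.null(seed)) stop("noisy rendering requires a seed")
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), 0, sigma),
                        nrow(img), ncol(img))
    img <- pmin(pmax(round(img), 0), 255)
  }
  truth <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(id = i, kind = s$kind, length = s$length, width = s$width,
               angle = s$angle, curvature = s$curvature)
  }))
  list(image = img, truth = truth)
}

#' Specify a blob/stroke movie
#'
#' @param n_frames number of frames.
#' @param shape canvas `c(h, w)`.
#' @param blobs list of blob scripts, each
#'   `list(center, radius, drift = c(dx, dy), appear = 1, vanish = Inf,
#'   split_at = NA, merge_into = NA, merge_at = NA)`; `split_at` makes the
#'   blob divide into two half-radius blobs drifting apart; `merge_at` moves
#'   the blob onto blob `merge_into` from that frame on.
#' @param sigma,background,intensity noise and intensity model.
#' @param seed RNG seed.
#' @return list of class `fs_movie_spec`.
#' @export
movie_spec <- function(n_frames, shape = c(128, 128), blobs = list(),
                       sigma = 0, background = 10, intensity = 200,
                       seed = 1L) {
  structure(list(n_frames = n_frames, shape = shape, blobs = blobs,
                 sigma = sigma, background = background,
                 intensity = intensity, seed = seed),
            class = "fs_movie_spec")
}

#' Render a blob movie with truth tracks and events
#'
#' Deterministic given the spec's seed. Truth events are derived from the
#' script (split/merge frames), truth tracks from the analytic blob centers.
#'
#' @param spec `fs_movie_spec`.
#' @return `list(frames = <list of matrices>, masks = <list of logical
#'   matrices>, tracks = <data.frame frame, blob, x, y, present>,
#'   events = <data.frame kind, frame>)`.
#' @export
render_movie <- function(spec) {
  frames <- masks <- vector("list", spec$n_frames)
  tracks <- list()
  events <- list()
  for (t in seq_len(spec$n_frames)) {
    img <- matrix(spec$background, spec$shape[1], spec$shape[2])
    mask <- matrix(FALSE, spec$shape[1], spec$shape[2])
    for (b in seq_along(spec$blobs)) {
      bl <- spec$blobs[[b]]
      appear <- if (is.null(bl$appear)) 1L else bl$appear
      vanish <- if (is.null(bl$vanish)) Inf else bl$vanish
      if (t < appear || t > vanish) next
      drift <- if (is.null(bl$drift)) c(0, 0) else bl$drift
      base <- function(tt) bl$center + (tt - appear) * drift
      ctr <- base(t)
      m_at <- if (is.null(bl$merge_at)) NA else bl$merge_at
      u_at <- if (is.null(bl$unmerge_at)) NA else bl$unmerge_at
      if (!is.na(m_at) && t >= m_at) {
        if (is.na(u_at) || t < u_at) {
          ## merged episode: hold the position reached at the merge frame
          ## (the script must route the trajectory onto the target by then)
          ctr <- base(m_at)
        } else {
          ## de-touch: retreat back along the approach direction
          ctr <- base(m_at) - (t - u_at + 1L) * drift
        }
      }
      if (!is.null(bl$split_at) && !is.na(bl$split_at) && t >= bl$split_at) {
        ## children of half radius, initially just disjoint, drifting apart
        ## slowly enough that consecutive frames overlap
        off <- c(0, bl$radius / 2 + 1 + 3 * (t - bl$split_at))
        for (sgn in c(-1, 1)) {
          c2 <- ctr + sgn * off
          mask <- stamp_disks(mask, matrix(round(c2), ncol = 2),
                              d = bl$radius)
          tracks[[length(tracks) + 1L]] <- data.frame(
            frame = t, blob = paste0(b, if (sgn < 0) "a" else "b"),
            x = c2[1], y = c2[2], present = TRUE)
        }
      } else {
        mask <- stamp_disks(mask, matrix(round(ctr), ncol = 2),
                            d = 2 * bl$radius)
        tracks[[length(tracks) + 1L]] <- data.frame(
          frame = t, blob = as.character(b), x = ctr[1], y = ctr[2],
          present = TRUE)
      }
    }
    img[mask] <- spec$intensity
    if (spec$sigma > 0) {
      set.seed(spec$seed + t)
      img <- pmin(pmax(round(img + stats::rnorm(length(img), 0, spec$sigma)),
                       0), 255)
    }
    frames[[t]] <- img
    masks[[t]] <- mask
  }
  for (b in seq_along(spec$blobs)) {
    bl <- spec$blobs[[b]]
    if (!is.null(bl$split_at) && !is.na(bl$split_at))
      events[[length(events) + 1L]] <- data.frame(kind = "Split",
                                                  frame = bl$split_at)
    if (!is.null(bl$merge_at) && !is.na(bl$merge_at)) {
      if (!is.null(bl$unmerge_at) && !is.na(bl$unmerge_at)) {
        events[[length(events) + 1L]] <- data.frame(kind = "Touch",
                                                    frame = bl$merge_at)
        events[[length(events) + 1L]] <- data.frame(kind = "DeTouch",
                                                    frame = bl$unmerge_at)
      } else {
        events[[length(events) + 1L]] <- data.frame(kind = "Fusion",
                                                    frame = bl$merge_at)
      }
    }
  }
  list(frames = frames, masks = masks,
       tracks = if (length(tracks)) do.call(rbind, tracks) else
         data.frame(frame = integer(0), blob = character(0), x = numeric(0),
                    y = numeric(0), present = logical(0)),
       events = if (length(events)) do.call(rbind, events) else
         data.frame(kind = character(0), frame = integer(0)))
}

#' Render a filament movie: strokes under per-frame rigid motion
#'
#' Moves a stroke set by `drift` pixels per frame (and optional per-frame
#' rotation about the canvas center), returning both images and the true
#' per-frame filament polylines — the tracking oracle.
#'
#' @param specs list of `fs_stroke`.
#' @param n_frames frame count.
#' @param drift per-frame translation `c(dx, dy)`.
#' @param rotation per-frame rotation in degrees.
#' @param shape canvas.
#' @param present optional list: for each stroke, the frames it exists in
#'   (default all frames).
#' @param sigma,seed noise model.
#' @return `list(frames, filaments = <list over frames of lists of
#'   fs_filament>, truth = <per-frame truth tables>)`.
#' @export
render_filament_movie <- function(specs, n_frames, drift = c(0, 0),
                                  rotation = 0, shape = c(256, 256),
                                  present = NULL, sigma = 0, seed = 1L) {
  if (is.null(present)) present <- rep(list(seq_len(n_frames)), length(specs))
  ctr_canvas <- rev(shape) / 2
  frames <- vector("list", n_frames)
  filaments <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    move <- function(p) {
      th <- deg2rad(rotation * (t - 1L))
      rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      as.vector(rot %*% (p - ctr_canvas)) + ctr_canvas + (t - 1L) * drift
    }
    sp_t <- list()
    fil_t <- list()
    for (k in seq_along(specs)) {
      if (!(t %in% present[[k]])) next
      s <- specs[[k]]
      s2 <- s
      if (s$kind == "line") { s2$p0 <- move(s$p0); s2$p1 <- move(s$p1) }
      else if (s$kind == "arc") { s2$center <- move(s$center) }
      else { s2$p0 <- move(s$p0); s2$p1 <- move(s$p1); s2$p2 <- move(s$p2) }
      sp_t[[length(sp_t) + 1L]] <- s2
      ctrl <- stroke_centerline(s2, step = 2)
      fil_t[[length(fil_t) + 1L]] <- fs_filament(ctrl, widths = s$width)
    }
    rend <- render_strokes(sp_t, shape = shape, sigma = sigma,
                           seed = seed + t)
    frames[[t]] <- rend$image
    filaments[[t]] <- fil_t
    truth[[t]] <- rend$truth
  }
  list(frames = frames, filaments = filaments, truth = truth)
}
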