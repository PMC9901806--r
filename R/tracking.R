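## Frame-to-frame single-filament tracking by unbalanced optimal transport.
##
## Filaments are cut into arc-length fragments (roughly 10 px); fragments of
## frame t are producers, fragments of frame t+1 consumers, weights are
## fragment lengths in pixels.  The base cost between two fragments is
## factor_length * d_l^2 + factor_angle * d_phi^2 (d_l: closest point
## distance in pixels, d_phi: undirected orientation difference in degrees).
## A dummy producer/consumer with cost d_max^2 against everything (the dummy
## pair included) absorbs unmatched mass, which makes the transport local:
## with the default factors (4, 1), flow between true fragments requires
## d_l <= d_max/2 and d_phi <= d_max.  The plan is consolidated per filament
## pair and linked into lifelines with birth, death, and persistence.

#' Tracking settings
#'
#' @param max_dist locality scale `d_max` (mixed pixel/degree unit,
#'   default 20): dummy cost is `d_max^2`.
#' @param factor_angle pre-factor of the squared angle difference (default 1).
#' @param factor_length pre-factor of the squared line distance (default 4).
#' @param fragment_length target fragment length in pixels (default 10;
#'   shorter fragments raise both accuracy and processing time).
#' @param min_valid minimal matched fraction of a filament for it not to be
#'   discarded as solitary.
#' @param min_matched matched-mass fraction at which successor accumulation
#'   stops.
#' @param min_rel_size minimal successor length relative to the filament.
#' @param min_abs_size minimal successor length in pixels.
#' @return list of class `fs_tracking_settings`.
#' @export
tracking_settings <- function(max_dist = 20, factor_angle = 1,
                              factor_length = 4, fragment_length = 10,
                              min_valid = 0.3, min_matched = 0.6,
                              min_rel_size = 0.25, min_abs_size = 10) {
  stopifnot(max_dist > 0, fragment_length >= 2,
            min_valid >= 0, min_valid <= 1, min_matched >= 0,
            min_matched <= 1, min_rel_size >= 0, min_rel_size <= 1)
  structure(list(max_dist = max_dist, factor_angle = factor_angle,
                 factor_length = factor_length,
                 fragment_length = fragment_length, min_valid = min_valid,
                 min_matched = min_matched, min_rel_size = min_rel_size,
                 min_abs_size = min_abs_size),
            class = "fs_tracking_settings")
}

#' Cut a filament into arc-length fragments
#'
#' Consecutive slices of the polyline of length `fragment_length`; the final
#' remainder is merged into the previous piece when it is at most half a
#' fragment, so weights sum exactly to the filament length.
#'
#' @param f `fs_filament`.
#' @param fragment_length target length in pixels (>= 2).
#' @param filament_id parent id stored on each segment.
#' @return list of segments: `list(filament_id, points, weight, orientation)`.
#' @export
fragment_filament <- function(f, fragment_length = 10, filament_id = 1L) {
  stopifnot(fragment_length >= 2)
  total <- filament_length(f)
  if (total <= 0) return(list())
  n_full <- floor(total / fragment_length)
  rem <- total - n_full * fragment_length
  cuts <- if (n_full == 0L) c(0, total)
          else if (rem <= fragment_length / 2 && rem > 0)
            c(seq(0, (n_full - 1) * fragment_length, by = fragment_length), total)
          else if (rem == 0) seq(0, total, by = fragment_length)
          else c(seq(0, n_full * fragment_length, by = fragment_length), total)
  lapply(seq_len(length(cuts) - 1L), function(i) {
    pts <- polyline_slice(f$points, cuts[i], cuts[i + 1L])
    n <- nrow(pts)
    list(filament_id = filament_id, points = pts,
         weight = cuts[i + 1L] - cuts[i],
         orientation = vec_angle(pts[n, 1] - pts[1, 1], pts[n, 2] - pts[1, 2]))
  })
}

## Sub-polyline between arc lengths a and b (interpolated endpoints).
polyline_slice <- function(pts, a, b) {
  seg_len <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  point_at <- function(t) {
    t <- min(max(t, 0), cum[length(cum)])
    i <- findInterval(t, cum, rightmost.closed = TRUE)
    i <- min(i, length(seg_len))
    frac <- if (seg_len[i] == 0) 0 else (t - cum[i]) / seg_len[i]
    pts[i, ] + frac * (pts[i + 1L, ] - pts[i, ])
  }
  inner <- which(cum > a & cum < b)
  rbind(point_at(a),
        pts[inner, , drop = FALSE],
        point_at(b))
}

#' Base transport cost between two segments
#'
#' `cost = factor_length * d_l^2 + factor_angle * d_phi^2` with `d_l` the
#' minimum distance between the two polyline pieces sampled at 1-px spacing
#' and `d_phi` the undirected orientation difference in degrees (in
#' \[0, 90\]).
#'
#' @param p,c segments as produced by [fragment_filament()].
#' @param s `fs_tracking_settings`.
#' @return non-negative cost.
#' @export
base_distance <- function(p, c, s = tracking_settings()) {
  dl <- min_segment_distance(p$points, c$points)
  dphi <- angle_diff(p$orientation, c$orientation)
  s$factor_length * dl^2 + s$factor_angle * dphi^2
}

## Minimum point-pair distance between two polylines sampled at <= 1 px.
min_segment_distance <- function(a, b) {
  sa <- densify_polyline(a); sb <- densify_polyline(b)
  d2 <- outer(sa[, 1], sb[, 1], "-")^2 + outer(sa[, 2], sb[, 2], "-")^2
  sqrt(min(d2))
}

densify_polyline <- function(pts) {
  if (nrow(pts) == 1L) return(pts)
  out <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    n <- max(1L, ceiling(sqrt(sum((b - a)^2))))
    t <- seq(0, 1, length.out = n + 1L)
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Solve the unbalanced transport between two fragment sets
#'
#' Builds the balanced transportation problem with one dummy producer and
#' one dummy consumer: dummy costs are `d_max^2` everywhere (dummy pair
#' included) and dummy weights equal the opposite side's total mass. Solved
#' exactly by the transportation simplex; the plan satisfies the marginal
#' constraints exactly and, as a consequence of the dummy costs, a true pair
#' with cost above `d_max^2` receives zero flow.
#'
#' @param producers,consumers segment lists (see [fragment_filament()]).
#' @param s `fs_tracking_settings`.
#' @param cost optional precomputed true-pair cost matrix
#'   (`length(producers) x length(consumers)`).
#' @return list of class `fs_transport_plan`: `plan` (matrix with dummy row 1
#'   and dummy column 1), `cost`, `objective`, `producer_weights`,
#'   `consumer_weights`.
#' @export
solve_transport <- function(producers, consumers, s = tracking_settings(),
                            cost = NULL) {
  wp <- vapply(producers, `[[`, numeric(1), "weight")
  wc <- vapply(consumers, `[[`, numeric(1), "weight")
  stopifnot(all(wp > 0), all(wc > 0))
  if (is.null(cost)) {
    cost <- matrix(0, length(producers), length(consumers))
    for (j in seq_along(producers)) for (k in seq_along(consumers))
      cost[j, k] <- base_distance(producers[[j]], consumers[[k]], s)
  }
  dmax2 <- s$max_dist^2
  full_cost <- rbind(c(dmax2, rep(dmax2, length(wc))),
                     cbind(rep(dmax2, length(wp)), cost))
  supply <- c(sum(wc), wp)   # dummy producer absorbs all consumer mass
  demand <- c(sum(wp), wc)   # dummy consumer absorbs all producer mass
  plan <- transport_simplex(full_cost, supply, demand)
  structure(list(plan = plan, cost = full_cost,
                 objective = sum(full_cost * plan),
                 producer_weights = supply, consumer_weights = demand),
            class = "fs_transport_plan")
}

## ---------------------------------------------------------------------------
## Transportation simplex (MODI / u-v method) with degenerate-basis support.

transport_simplex <- function(cost, supply, demand, tol = 1e-9,
                              max_iter = 100000L) {
  m <- length(supply); n <- length(demand)
  stopifnot(abs(sum(supply) - sum(demand)) < 1e-6)
  x <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  ## northwest-corner start; zero allocations keep the basis a spanning tree
  i <- 1L; j <- 1L
  s_rem <- supply; d_rem <- demand
  while (i <= m && j <= n) {
    q <- min(s_rem[i], d_rem[j])
    x[i, j] <- q
    basis[i, j] <- TRUE
    s_rem[i] <- s_rem[i] - q
    d_rem[j] <- d_rem[j] - q
    if (i == m && j == n) break
    if (s_rem[i] <= d_rem[j] && i < m) i <- i + 1L else j <- j + 1L
  }
  for (it in seq_len(max_iter)) {
    uv <- transport_duals(cost, basis, m, n)
    rc <- cost - outer(uv$u, rep(1, n)) - outer(rep(1, m), uv$v)
    rc[basis] <- 0
    ent <- which.min(rc)
    if (rc[ent] >= -tol) break
    ei <- (ent - 1L) %% m + 1L
    ej <- (ent - 1L) %/% m + 1L
    cyc <- transport_cycle(basis, ei, ej, m, n)
    ## odd positions gain, even positions lose
    lose <- cyc[seq(2L, nrow(cyc), by = 2L), , drop = FALSE]
    theta <- min(x[lose])
    leave_k <- which(x[lose] == theta)[1]
    sgn <- rep_len(c(1, -1), nrow(cyc))
    x[cyc] <- x[cyc] + sgn * theta
    basis[ei, ej] <- TRUE
    basis[lose[leave_k, 1], lose[leave_k, 2]] <- FALSE
    x[lose[leave_k, 1], lose[leave_k, 2]] <- 0
  }
  x
}

## Duals u, v with u[1] = 0, solved by traversing the basis spanning tree.
transport_duals <- function(cost, basis, m, n) {
  u <- rep(NA_real_, m); v <- rep(NA_real_, n)
  u[1] <- 0
  repeat {
    progress <- FALSE
    for (i in seq_len(m)) {
      if (is.na(u[i])) next
      js <- which(basis[i, ] & is.na(v))
      if (length(js)) { v[js] <- cost[i, js] - u[i]; progress <- TRUE }
    }
    for (j in seq_len(n)) {
      if (is.na(v[j])) next
      is <- which(basis[, j] & is.na(u))
      if (length(is)) { u[is] <- cost[is, j] - v[j]; progress <- TRUE }
    }
    if (!anyNA(u) && !anyNA(v)) break
    if (!progress) stop("degenerate transport basis: disconnected tree")
  }
  list(u = u, v = v)
}

## Unique alternating cycle created by adding cell (ei, ej) to the basis
## tree: path in the bipartite basis graph from column-node ej back to
## row-node ei, found by BFS.
transport_cycle <- function(basis, ei, ej, m, n) {
  ## nodes: rows 1..m, cols m+1..m+n
  prev <- rep(NA_integer_, m + n)
  start <- ei; target <- m + ej
  prev[start] <- 0L
  frontier <- start
  while (length(frontier) > 0L && is.na(prev[target])) {
    nxt <- integer(0)
    for (node in frontier) {
      if (node <= m) {
        nbrs <- m + which(basis[node, ])
      } else {
        nbrs <- which(basis[, node - m])
      }
      nbrs <- nbrs[is.na(prev[nbrs])]
      prev[nbrs] <- node
      nxt <- c(nxt, nbrs)
    }
    frontier <- nxt
  }
  if (is.na(prev[target])) stop("no cycle found: basis is not spanning")
  path <- target
  while (prev[path[1]] != 0L) path <- c(prev[path[1]], path)
  ## path alternates row, col, row, ... from ei to m+ej; cells are
  ## consecutive (row, col) pairs, cycle starts with the entering cell
  cells <- matrix(0L, 0L, 2L)
  for (k in seq_len(length(path) - 1L)) {
    a <- path[k]; b <- path[k + 1L]
    cell <- if (a <= m) c(a, b - m) else c(b, a - m)
    cells <- rbind(cells, cell)
  }
  rbind(c(ei, ej), cells[rev(seq_len(nrow(cells))), , drop = FALSE])
}

#' Consolidate a transport plan to a filament correlation matrix
#'
#' `M[a, b]` is the transported mass between the fragments of filament `a`
#' (previous frame) and filament `b` (next frame); block sums over the plan.
#'
#' @param tp `fs_transport_plan` from [solve_transport()].
#' @param producers,consumers the segment lists the plan was solved on.
#' @param n_a,n_b filament counts in the two frames.
#' @return `n_a x n_b` matrix.
#' @export
consolidate <- function(tp, producers, consumers, n_a, n_b) {
  M <- matrix(0, n_a, n_b)
  pid <- as.integer(vapply(producers, `[[`, numeric(1), "filament_id"))
  cid <- as.integer(vapply(consumers, `[[`, numeric(1), "filament_id"))
  true_plan <- tp$plan[-1L, -1L, drop = FALSE]
  for (j in seq_along(pid)) for (k in seq_along(cid))
    M[pid[j], cid[k]] <- M[pid[j], cid[k]] + true_plan[j, k]
  M
}

#' Link filaments across one frame pair
#'
#' For each previous-frame filament `a`, successor candidates are filtered to
#' length at least `min_abs_size` and `min_rel_size * length(a)`, then
#' accumulated in decreasing `M[a, ]` order (ties by smaller id) until the
#' matched mass reaches `min_matched * length(a)`. If the total matched mass
#' stays below `min_valid * length(a)` the filament is solitary.
#'
#' @param M consolidated correlation matrix.
#' @param len_a,len_b filament lengths (pixels) in the two frames.
#' @param s `fs_tracking_settings`.
#' @return list over A-filaments, each an integer vector of successor ids in
#'   B (possibly empty), with the primary (largest-mass) successor first.
#' @export
link_filaments <- function(M, len_a, len_b, s = tracking_settings()) {
  lapply(seq_along(len_a), function(a) {
    cand <- which(len_b >= s$min_abs_size & len_b >= s$min_rel_size * len_a[a])
    cand <- cand[M[a, cand] > 1e-9]
    if (length(cand) == 0L) return(integer(0))
    cand <- cand[order(-M[a, cand], cand)]
    acc <- cumsum(M[a, cand])
    stop_at <- which(acc >= s$min_matched * len_a[a])[1]
    take <- if (is.na(stop_at)) cand else cand[seq_len(stop_at)]
    if (sum(M[a, take]) < s$min_valid * len_a[a]) return(integer(0))
    take
  })
}

#' Track filaments through a time-lapse stack
#'
#' Runs fragmentation, transport, consolidation and linking for every
#' consecutive frame pair, then chains primary successors into
#' DynamicFilament lifelines. A filament claimed by no predecessor starts a
#' new lifeline; when two lifelines claim the same successor the larger
#' transported mass wins (tie: older lifeline) and the loser dies.
#'
#' @param frames list (length >= 2) of per-frame filament lists.
#' @param s `fs_tracking_settings`.
#' @param min_persistence,max_persistence inclusive lifeline-length filter in
#'   frames.
#' @return list of lifelines, each
#'   `list(id, birth, death, persistence, frame_ids)` where `frame_ids` maps
#'   frame index to the filament index within that frame.
#' @export
track_stack <- function(frames, s = tracking_settings(),
                        min_persistence = 1L, max_persistence = Inf) {
  if (length(frames) < 2L) stop("track_stack needs at least 2 frames")
  nf <- length(frames)
  lens <- lapply(frames, function(fl) vapply(fl, filament_length, numeric(1)))
  succ <- vector("list", nf - 1L)
  mass <- vector("list", nf - 1L)
  for (t in seq_len(nf - 1L)) {
    A <- frames[[t]]; B <- frames[[t + 1L]]
    if (length(A) == 0L || length(B) == 0L) {
      succ[[t]] <- rep(list(integer(0)), length(A))
      mass[[t]] <- matrix(0, length(A), length(B))
      next
    }
    P <- unlist(lapply(seq_along(A), function(i)
      fragment_filament(A[[i]], s$fragment_length, i)), recursive = FALSE)
    C <- unlist(lapply(seq_along(B), function(i)
      fragment_filament(B[[i]], s$fragment_length, i)), recursive = FALSE)
    tp <- solve_transport(P, C, s)
    M <- consolidate(tp, P, C, length(A), length(B))
    mass[[t]] <- M
    succ[[t]] <- link_filaments(M, lens[[t]], lens[[t + 1L]], s)
  }
  ## chain primary successors into lifelines
  lifelines <- list()
  owner <- lapply(frames, function(fl) rep(NA_integer_, length(fl)))
  new_lifeline <- function(t, i) {
    id <- length(lifelines) + 1L
    lifelines[[id]] <<- list(id = id, birth = t, death = t,
                             frame_ids = stats::setNames(i, t))
    owner[[t]][i] <<- id
    id
  }
  for (i in seq_along(frames[[1L]])) new_lifeline(1L, i)
  for (t in seq_len(nf - 1L)) {
    claim <- rep(NA_integer_, length(frames[[t + 1L]]))  # lifeline claiming b
    claim_mass <- rep(-Inf, length(frames[[t + 1L]]))
    for (a in seq_along(frames[[t]])) {
      lid <- owner[[t]][a]
      if (is.na(lid)) next
      sc <- succ[[t]][[a]]
      if (length(sc) == 0L) next
      b <- sc[1L]  # primary successor continues the identity
      if (mass[[t]][a, b] > claim_mass[b] + 1e-12) {
        claim[b] <- lid
        claim_mass[b] <- mass[[t]][a, b]
      }
    }
    for (b in seq_along(frames[[t + 1L]])) {
      lid <- claim[b]
      if (!is.na(lid)) {
        lifelines[[lid]]$death <- t + 1L
        lifelines[[lid]]$frame_ids <- c(lifelines[[lid]]$frame_ids,
                                        stats::setNames(b, t + 1L))
        owner[[t + 1L]][b] <- lid
      } else {
        new_lifeline(t + 1L, b)
      }
    }
  }
  lifelines <- lapply(lifelines, function(L) {
    L$persistence <- L$death - L$birth + 1L
    L
  })
  keep <- vapply(lifelines, function(L)
    L$persistence >= min_persistence && L$persistence <= max_persistence,
    logical(1))
  lifelines[keep]
}

#' Export tracking lifelines as CSV
#'
#' Layout `"by_frame"`: one row per (frame, filament) occurrence ordered by
#' frame; `"by_filament"`: ordered by lifeline id. Columns: lifeline id,
#' frame, filament index, birth, death, persistence plus the filament
#' descriptors of that frame.
#'
#' @param lifelines result of [track_stack()].
#' @param frames the per-frame filament lists that were tracked.
#' @param path output path.
#' @param layout `"by_frame"` or `"by_filament"`.
#' @return the exported data.frame, invisibly.
#' @export
write_tracking_csv <- function(lifelines, frames, path,
                               layout = c("by_frame", "by_filament")) {
  layout <- match.arg(layout)
  rows <- list()
  for (L in lifelines) {
    for (k in seq_along(L$frame_ids)) {
      t <- as.integer(names(L$frame_ids)[k])
      i <- L$frame_ids[[k]]
      desc <- filament_descriptors(frames[[t]][[i]], id = i)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(lifeline = L$id, frame = t, filament = i,
                   birth = L$birth, death = L$death,
                   persistence = L$persistence), desc[, -1])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lifeline = integer(0), frame = integer(0),
               filament = integer(0), birth = integer(0), death = integer(0),
               persistence = integer(0))
  if (nrow(df)) {
    df <- if (layout == "by_frame") df[order(df$frame, df$lifeline), ]
          else df[order(df$lifeline, df$frame), ]
  }
  write_csv_atomic(df, path)
  invisible(df)
}
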