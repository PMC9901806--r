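## Bounding-box area tracking and cell-event monitoring over a stack.
##
## Connected foreground components per frame are matched across consecutive
## frames by the overlap score |a .. b| / min(|a|, |b|) (bounding boxes serve
## only as a pre-filter).  Predecessor counts classify events (Start, Alive,
## Split, Fusion); a Fusion later followed by a Split on the fused lifeline
## is post-corrected to Touch/DeTouch with the pre-fusion lifelines
## reconnected by best matching score, and terminal lifelines get an End
## event.

#' Detect cell areas in a binary mask
#'
#' 8-connected components with at least `min_area` pixels, each with its
#' tight axis-aligned bounding box.
#'
#' @param mask logical matrix.
#' @param min_area minimal component size in pixels^2.
#' @param frame frame index stored on each region.
#' @return list of regions:
#'   `list(frame, pixels = <(x, y) matrix>, bbox = c(xmin, xmax, ymin, ymax),
#'   area)`.
#' @export
detect_areas <- function(mask, min_area = 1, frame = 1L) {
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(list())
  out <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    pts <- cbind(x = idx[, 2], y = idx[, 1])
    out[[length(out) + 1L]] <- list(
      frame = frame, pixels = pts,
      bbox = c(xmin = min(pts[, 1]), xmax = max(pts[, 1]),
               ymin = min(pts[, 2]), ymax = max(pts[, 2])),
      area = nrow(pts))
  }
  out
}

bbox_intersects <- function(a, b) {
  a["xmin"] <= b["xmax"] && b["xmin"] <= a["xmax"] &&
    a["ymin"] <= b["ymax"] && b["ymin"] <= a["ymax"]
}

#' Overlap score between two regions
#'
#' Proportion of the exact pixel intersection to the smaller of the two
#' areas, capped at 1 (with exact pixel sets the ratio cannot exceed 1; the
#' cap guards approximate callers).
#'
#' @param a,b regions from [detect_areas()].
#' @return fraction in \[0, 1\].
#' @export
matching_score <- function(a, b) {
  ka <- paste(a$pixels[, 1], a$pixels[, 2])
  kb <- paste(b$pixels[, 1], b$pixels[, 2])
  inter <- length(intersect(ka, kb))
  min(1, inter / min(a$area, b$area))
}

#' Build the matching map over a stack of frame area lists
#'
#' Scores every consecutive-frame region pair whose bounding boxes intersect
#' (the box test is a pure pre-filter: a disjoint box pair has zero pixel
#' overlap, so no overlapping pair is dropped).
#'
#' @param frame_areas list over frames, each a list from [detect_areas()].
#' @return data.frame: frame, i (region in frame), j (region in frame + 1),
#'   score.
#' @export
build_matching_map <- function(frame_areas) {
  stopifnot(length(frame_areas) >= 2L)
  rows <- list()
  for (t in seq_len(length(frame_areas) - 1L)) {
    A <- frame_areas[[t]]; B <- frame_areas[[t + 1L]]
    for (i in seq_along(A)) for (j in seq_along(B)) {
      if (!bbox_intersects(A[[i]]$bbox, B[[j]]$bbox)) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, i = i, j = j, score = matching_score(A[[i]], B[[j]]))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(0), i = integer(0), j = integer(0),
                      score = numeric(0)))
  do.call(rbind, rows)
}

#' Classify cell events and assemble lifelines
#'
#' Predecessors of a region are the previous-frame regions whose matching
#' score exceeds `intersect_tolerance`. Regions without predecessor open a
#' lifeline (Start); exactly one predecessor with one successor extends it
#' (Alive); one predecessor with several successors closes it and opens new
#' lifelines (Split); several predecessors close them all and open a fused
#' lifeline (Fusion).
#'
#' @param frame_areas list over frames of region lists.
#' @param map matching map from [build_matching_map()].
#' @param intersect_tolerance minimal score in \[0, 1) for two regions to
#'   count as the same cell (default 0.2).
#' @return `list(lifelines = <list>, events = <data.frame kind, frame,
#'   lifelines>)`; each lifeline is `list(id, birth, death, frames =
#'   <named list frame -> region index>)`.
#' @export
classify_events <- function(frame_areas, map, intersect_tolerance = 0.2) {
  stopifnot(intersect_tolerance >= 0, intersect_tolerance < 1)
  nf <- length(frame_areas)
  lifelines <- list()
  events <- list()
  owner <- lapply(frame_areas, function(a) rep(NA_integer_, length(a)))
  add_event <- function(kind, frame, lids)
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, frame = frame, lifelines = paste(lids, collapse = "+"))
  open_lifeline <- function(t, j) {
    id <- length(lifelines) + 1L
    lifelines[[id]] <<- list(id = id, birth = t, death = t,
                             frames = stats::setNames(list(j), t))
    owner[[t]][j] <<- id
    id
  }
  extend_lifeline <- function(id, t, j) {
    lifelines[[id]]$death <<- t
    lifelines[[id]]$frames[[as.character(t)]] <<- j
    owner[[t]][j] <<- id
  }
  for (j in seq_along(frame_areas[[1L]]))
    add_event("Start", 1L, open_lifeline(1L, j))
  if (nf >= 2L) for (t in 2:nf) {
    sub <- map[map$frame == t - 1L & map$score > intersect_tolerance, ,
               drop = FALSE]
    preds <- lapply(seq_along(frame_areas[[t]]), function(j)
      sub$i[sub$j == j])
    succ_count <- vapply(seq_along(frame_areas[[t - 1L]]), function(i)
      sum(sub$i == i), integer(1))
    split_children <- list()  # predecessor i -> new lifeline ids
    for (j in seq_along(frame_areas[[t]])) {
      pr <- preds[[j]]
      if (length(pr) == 0L) {
        add_event("Start", t, open_lifeline(t, j))
      } else if (length(pr) > 1L) {
        closing <- unique(stats::na.omit(vapply(pr, function(i)
          owner[[t - 1L]][i], integer(1))))
        id <- open_lifeline(t, j)
        add_event("Fusion", t, c(closing, id))
      } else {
        i <- pr
        pid <- owner[[t - 1L]][i]
        if (succ_count[i] > 1L) {
          id <- open_lifeline(t, j)
          key <- as.character(i)
          split_children[[key]] <- c(split_children[[key]], id)
        } else if (is.na(pid)) {
          add_event("Start", t, open_lifeline(t, j))
        } else {
          extend_lifeline(pid, t, j)
          add_event("Alive", t, pid)
        }
      }
    }
    for (key in names(split_children)) {
      pid <- owner[[t - 1L]][as.integer(key)]
      add_event("Split", t, c(pid, split_children[[key]]))
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), frame = integer(0),
               lifelines = character(0))
  list(lifelines = lifelines, events = ev, owner = owner)
}

#' Post-process lifelines: Touch/DeTouch correction and End events
#'
#' A Fusion whose fused lifeline later undergoes a Split is rewritten to a
#' Touch (at the fusion frame) and DeTouch (at the split frame): the
#' pre-fusion lifelines continue unbroken, reconnected to the post-split
#' regions by best matching score between their last own region and each
#' post-split region (ties by larger area, then smaller lifeline id); the
#' merged-episode regions are owned by the best-matching lifeline. A fusion
#' never followed by a split stands (the end-of-stack caveat). Finally every
#' lifeline without successor gets an End event, and birth/death/lifespan
#' are finalized.
#'
#' @param classified result of [classify_events()].
#' @param frame_areas the region stack.
#' @return `list(lifelines, events)`; each lifeline additionally carries
#'   `lifespan = death - birth + 1`.
#' @export
postprocess_lifelines <- function(classified, frame_areas) {
  lifelines <- classified$lifelines
  ev <- classified$events
  drop_ll <- integer(0)
  if (nrow(ev)) for (r in which(ev$kind == "Fusion")) {
    ids <- as.integer(strsplit(ev$lifelines[r], "\\+")[[1]])
    fused_id <- ids[length(ids)]
    parents <- ids[-length(ids)]
    split_rows <- which(ev$kind == "Split" & ev$frame > ev$frame[r])
    split_row <- NA_integer_
    for (sr in split_rows) {
      sids <- as.integer(strsplit(ev$lifelines[sr], "\\+")[[1]])
      if (sids[1] == fused_id) { split_row <- sr; break }
    }
    if (is.na(split_row)) next  # fusion stands (e.g. merge at end of stack)
    sids <- as.integer(strsplit(ev$lifelines[split_row], "\\+")[[1]])
    children <- sids[-1]
    ## reconnect: parent lifelines continue to post-split regions by best
    ## matching score between the parent's last own region and each child's
    ## first region
    tf <- ev$frame[r]; ts <- ev$frame[split_row]
    score_pc <- matrix(0, length(parents), length(children))
    for (a in seq_along(parents)) for (b in seq_along(children)) {
      pl <- lifelines[[parents[a]]]
      last_t <- max(as.integer(names(pl$frames)))
      pa <- frame_areas[[last_t]][[pl$frames[[as.character(last_t)]]]]
      cl <- lifelines[[children[b]]]
      first_t <- min(as.integer(names(cl$frames)))
      ca <- frame_areas[[first_t]][[cl$frames[[as.character(first_t)]]]]
      score_pc[a, b] <- matching_score(pa, ca)
    }
    assigned_child <- rep(NA_integer_, length(parents))
    areas_c <- vapply(children, function(cid) {
      cl <- lifelines[[cid]]
      first_t <- min(as.integer(names(cl$frames)))
      frame_areas[[first_t]][[cl$frames[[as.character(first_t)]]]]$area
    }, numeric(1))
    free_c <- rep(TRUE, length(children))
    for (a in order(-apply(score_pc, 1, max), parents)) {
      ord <- order(-score_pc[a, ], -areas_c, children)
      pick <- ord[free_c[ord]][1]
      if (is.na(pick)) next
      assigned_child[a] <- pick
      free_c[pick] <- FALSE
    }
    fused <- lifelines[[fused_id]]
    merged_frames <- fused$frames
    best_parent <- parents[which.max(vapply(seq_along(parents), function(a)
      max(score_pc[a, ]), numeric(1)))]
    for (a in seq_along(parents)) {
      pid <- parents[a]
      if (pid == best_parent) {
        ## best-matching parent owns the merged-episode regions
        for (k in seq_along(merged_frames))
          lifelines[[pid]]$frames[[names(merged_frames)[k]]] <-
            merged_frames[[k]]
      }
      cb <- assigned_child[a]
      if (!is.na(cb)) {
        child <- lifelines[[children[cb]]]
        for (k in seq_along(child$frames))
          lifelines[[pid]]$frames[[names(child$frames)[k]]] <- child$frames[[k]]
        lifelines[[pid]]$death <- child$death
        drop_ll <- c(drop_ll, children[cb])
      } else {
        lifelines[[pid]]$death <- ev$frame[r] - 1L
      }
    }
    drop_ll <- c(drop_ll, fused_id)
    ev$kind[r] <- "Touch"
    ev$lifelines[r] <- paste(parents, collapse = "+")
    ev$kind[split_row] <- "DeTouch"
    ev$lifelines[split_row] <- paste(parents, collapse = "+")
    ## remap stale Alive references: fused episode -> best parent, each
    ## absorbed child -> its assigned parent
    remap <- c(stats::setNames(best_parent, fused_id),
               stats::setNames(parents[!is.na(assigned_child)],
                               children[assigned_child[!is.na(assigned_child)]]))
    for (q in seq_len(nrow(ev))) {
      old <- ev$lifelines[q]
      if (ev$kind[q] %in% c("Alive", "Start") && old %in% names(remap))
        ev$lifelines[q] <- as.character(remap[[old]])
    }
  }
  keep <- setdiff(seq_along(lifelines), drop_ll)
  lifelines <- lifelines[keep]
  lifelines <- lapply(lifelines, function(L) {
    ts <- as.integer(names(L$frames))
    L$birth <- min(ts); L$death <- max(ts)
    L$lifespan <- L$death - L$birth + 1L
    L
  })
  for (L in lifelines) {
    ev <- rbind(ev, data.frame(kind = "End", frame = L$death,
                               lifelines = as.character(L$id)))
  }
  ev <- ev[order(ev$frame, ev$kind), ]
  rownames(ev) <- NULL
  list(lifelines = lifelines, events = ev)
}

#' Run the full cell-event pipeline on a mask stack
#'
#' @param masks list of logical matrices (frames).
#' @param min_area minimal region size.
#' @param intersect_tolerance matching-score tolerance.
#' @return `list(lifelines, events, areas)`.
#' @export
monitor_cell_events <- function(masks, min_area = 1,
                                intersect_tolerance = 0.2) {
  areas <- lapply(seq_along(masks), function(t)
    detect_areas(masks[[t]], min_area = min_area, frame = t))
  map <- build_matching_map(areas)
  cls <- classify_events(areas, map, intersect_tolerance)
  post <- postprocess_lifelines(cls, areas)
  c(post, list(areas = areas))
}

#' Export cell events and lifelines as CSV
#'
#' Two files: `<stem>_events.csv` (one row per event) and
#' `<stem>_lifelines.csv` (one row per lifeline: id, birth, death, lifespan).
#'
#' @param result output of [monitor_cell_events()] or
#'   [postprocess_lifelines()].
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
write_event_csv <- function(result, stem) {
  ev_path <- paste0(stem, "_events.csv")
  ll_path <- paste0(stem, "_lifelines.csv")
  write_csv_atomic(result$events, ev_path)
  ll <- if (length(result$lifelines))
    do.call(rbind, lapply(result$lifelines, function(L)
      data.frame(id = L$id, birth = L$birth, death = L$death,
                 lifespan = L$lifespan)))
  else data.frame(id = integer(0), birth = integer(0), death = integer(0),
                  lifespan = integer(0))
  write_csv_atomic(ll, ll_path)
  invisible(c(ev_path, ll_path))
}
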