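blob_mask <- function(centers, radii, shape = c(96, 96)) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_along(radii))
    m <- filamentr:::stamp_disks(m, matrix(centers[[i]], ncol = 2),
                                 d = 2 * radii[i])
  m
}

test_that("detect_areas filters by size and computes tight boxes", {
  m <- blob_mask(list(c(30, 30), c(70, 70)), c(12, 3))
  areas <- detect_areas(m, min_area = 100)
  expect_length(areas, 1L)
  expect_length(detect_areas(matrix(FALSE, 10, 10)), 0L)

  ## L-shaped blob: box equals the min/max coordinate oracle
  L <- matrix(FALSE, 40, 40)
  L[10:30, 10:14] <- TRUE
  L[26:30, 10:28] <- TRUE
  a <- detect_areas(L, min_area = 1)[[1]]
  idx <- which(L, arr.ind = TRUE)
  expect_equal(unname(a$bbox),
               c(min(idx[, 2]), max(idx[, 2]), min(idx[, 1]), max(idx[, 1])))
  expect_equal(a$area, sum(L))
})

test_that("matching score is intersection over smaller area, capped", {
  m1 <- blob_mask(list(c(40, 40)), 10)
  a <- detect_areas(m1)[[1]]
  expect_equal(matching_score(a, a), 1.0)
  m2 <- blob_mask(list(c(80, 40)), 10)
  b <- detect_areas(m2)[[1]]
  expect_equal(matching_score(a, b), 0.0)
  ## constructed 100 px and 60 px regions overlapping on 30 px
  r1 <- list(pixels = cbind(rep(1:20, 5), rep(1:5, each = 20)), area = 100)
  r2 <- list(pixels = cbind(rep(15:20, 10), rep(1:10, each = 6)), area = 60)
  inter <- length(intersect(paste(r1$pixels[, 1], r1$pixels[, 2]),
                            paste(r2$pixels[, 1], r2$pixels[, 2])))
  expect_equal(inter, 30L)
  expect_equal(matching_score(r1, r2), 0.5)
})

test_that("matching map scores all overlapping consecutive pairs", {
  mv <- render_movie(movie_spec(4, blobs = list(
    list(center = c(48, 48), radius = 10))))
  areas <- lapply(seq_len(4), function(t)
    detect_areas(mv$masks[[t]], min_area = 20, frame = t))
  map <- build_matching_map(areas)
  expect_equal(nrow(map), 3L)
  expect_true(all(map$score == 1.0))

  ## blob disappearing at frame 3: no entries from frame 2 -> 3
  mv2 <- render_movie(movie_spec(4, blobs = list(
    list(center = c(48, 48), radius = 10, vanish = 2))))
  areas2 <- lapply(seq_len(4), function(t)
    detect_areas(mv2$masks[[t]], min_area = 20, frame = t))
  map2 <- build_matching_map(areas2)
  expect_true(all(map2$frame == 1L))

  ## drifting blob: the bbox pre-filter must not drop any overlapping pair
  mv3 <- render_movie(movie_spec(5, blobs = list(
    list(center = c(20, 48), radius = 10, drift = c(8, 0)))))
  areas3 <- lapply(seq_len(5), function(t)
    detect_areas(mv3$masks[[t]], min_area = 20, frame = t))
  map3 <- build_matching_map(areas3)
  for (t in 1:4) {
    oracle <- matching_score(areas3[[t]][[1]], areas3[[t + 1]][[1]])
    got <- map3$score[map3$frame == t]
    if (oracle > 0) expect_equal(got, oracle) else expect_length(got, 0L)
  }
})

test_that("static movie: one lifeline, Start + Alives + End", {
  mv <- render_movie(movie_spec(4, blobs = list(
    list(center = c(48, 48), radius = 10))))
  res <- monitor_cell_events(mv$masks, min_area = 20)
  expect_length(res$lifelines, 1L)
  expect_equal(res$lifelines[[1]]$lifespan, 4L)
  expect_equal(sum(res$events$kind == "Start"), 1L)
  expect_equal(sum(res$events$kind == "Alive"), 3L)
  expect_equal(sum(res$events$kind == "End"), 1L)
})

test_that("split movie: Split event, three lifelines", {
  mv <- render_movie(movie_spec(6, blobs = list(
    list(center = c(60, 60), radius = 12, split_at = 4))))
  res <- monitor_cell_events(mv$masks, min_area = 20)
  expect_length(res$lifelines, 3L)
  expect_equal(res$events$frame[res$events$kind == "Split"], 4L)
  expect_equal(sum(res$events$kind == "Fusion"), 0L)
})

test_that("merge with no later split stays a Fusion (end-of-stack caveat)", {
  mv <- render_movie(movie_spec(6, shape = c(128, 128), blobs = list(
    list(center = c(40, 60), radius = 10),
    list(center = c(88, 60), radius = 10, drift = c(-10, 0),
         merge_into = 1L, merge_at = 4L))))
  res <- monitor_cell_events(mv$masks, min_area = 20)
  expect_equal(res$events$frame[res$events$kind == "Fusion"], 4L)
  expect_equal(sum(res$events$kind %in% c("Touch", "DeTouch")), 0L)
  fused <- res$lifelines[[3]]
  expect_equal(fused$death, 6L)
})

test_that("merge then split becomes Touch/DeTouch with unbroken lifelines", {
  mv <- render_movie(movie_spec(8, shape = c(128, 128), blobs = list(
    list(center = c(40, 60), radius = 10),
    list(center = c(84, 60), radius = 13, drift = c(-13, 0),
         merge_into = 1L, merge_at = 3L, unmerge_at = 6L))))
  res <- monitor_cell_events(mv$masks, min_area = 20)
  expect_equal(res$events$frame[res$events$kind == "Touch"], 3L)
  expect_equal(res$events$frame[res$events$kind == "DeTouch"], 6L)
  expect_equal(sum(res$events$kind %in% c("Fusion", "Split")), 0L)
  expect_length(res$lifelines, 2L)
  for (L in res$lifelines) {
    expect_equal(L$birth, 1L)
    expect_equal(L$death, 8L)
    expect_equal(L$lifespan, 8L)
  }
})

test_that("single blob postprocessing is the identity on lifelines", {
  mv <- render_movie(movie_spec(3, blobs = list(
    list(center = c(48, 48), radius = 10))))
  areas <- lapply(1:3, function(t)
    detect_areas(mv$masks[[t]], min_area = 20, frame = t))
  cls <- classify_events(areas, build_matching_map(areas), 0.2)
  post <- postprocess_lifelines(cls, areas)
  expect_equal(length(post$lifelines), length(cls$lifelines))
  expect_equal(post$lifelines[[1]]$frames, cls$lifelines[[1]]$frames)
})

test_that("lifeline bookkeeping invariants hold on a busy movie", {
  mv <- render_movie(movie_spec(7, shape = c(160, 160), blobs = list(
    list(center = c(40, 40), radius = 10, drift = c(2, 0)),
    list(center = c(110, 110), radius = 12, split_at = 4),
    list(center = c(40, 120), radius = 8, appear = 3))))
  res <- monitor_cell_events(mv$masks, min_area = 20)
  ## every area in every frame belongs to exactly one lifeline
  for (t in 1:7) {
    n_areas <- length(res$areas[[t]])
    owners <- unlist(lapply(res$lifelines, function(L)
      if (as.character(t) %in% names(L$frames)) L$frames[[as.character(t)]]))
    expect_equal(sort(owners), seq_len(n_areas))
  }
  ## lifespan consistency
  for (L in res$lifelines)
    expect_equal(L$lifespan, L$death - L$birth + 1L)
  ## bookkeeping balance: starts + split children = lifelines (no fusion here)
  n_start <- sum(res$events$kind == "Start")
  n_split_children <- sum(vapply(which(res$events$kind == "Split"),
    function(r) length(strsplit(res$events$lifelines[r], "\\+")[[1]]) - 1L,
    integer(1)))
  expect_equal(n_start + n_split_children, length(res$lifelines))
})

test_that("time reversal turns a split movie into a fusion movie", {
  mv <- render_movie(movie_spec(6, blobs = list(
    list(center = c(60, 60), radius = 12, split_at = 4))))
  fwd <- monitor_cell_events(mv$masks, min_area = 20)
  rev_res <- monitor_cell_events(rev(mv$masks), min_area = 20)
  expect_equal(sum(fwd$events$kind == "Split"), 1L)
  expect_equal(sum(rev_res$events$kind == "Fusion"), 1L)
  expect_equal(sum(rev_res$events$kind == "Split"), 0L)
})

test_that("event CSV export writes events and lifelines", {
  mv <- render_movie(movie_spec(4, blobs = list(
    list(center = c(48, 48), radius = 10))))
  res <- monitor_cell_events(mv$masks, min_area = 20)
  stem <- file.path(withr::local_tempdir(), "mv")
  paths <- write_event_csv(res, stem)
  expect_true(all(file.exists(paths)))
  ll <- read.csv(paths[2])
  expect_equal(ll$lifespan, 4L)
})
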