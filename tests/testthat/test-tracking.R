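test_that("fragmentation: remainder rule and exact mass", {
  f <- straight_filament(0, 0, 35, 0)
  segs <- fragment_filament(f, 10)
  expect_equal(vapply(segs, `[[`, numeric(1), "weight"), c(10, 10, 15))

  f2 <- straight_filament(0, 0, 8, 0)
  segs2 <- fragment_filament(f2, 10)
  expect_length(segs2, 1L)
  expect_equal(segs2[[1]]$weight, 8)

  ## length 36: remainder 6 >= fl/2 stays its own piece
  segs3 <- fragment_filament(straight_filament(0, 0, 36, 0), 10)
  expect_equal(vapply(segs3, `[[`, numeric(1), "weight"), c(10, 10, 10, 6))

  set.seed(31)
  pts <- cbind(cumsum(runif(12, 1, 9)), cumsum(rnorm(12, 0, 3)))
  fr <- fs_filament(pts)
  segs4 <- fragment_filament(fr, 10)
  expect_equal(sum(vapply(segs4, `[[`, numeric(1), "weight")),
               filament_length(fr), tolerance = 1e-9)
})

test_that("base distance follows the squared form with undirected wrap", {
  s <- tracking_settings()  # factor_length 4, factor_angle 1
  a <- toy_segment(0, 0, 10, 0)
  expect_equal(base_distance(a, a, s), 0)
  b <- toy_segment(13, 0, 10, 4)   # d_l = 3 (gap), d_phi = 4
  expect_equal(base_distance(a, b, s), 4 * 9 + 16)
  c1 <- toy_segment(0, 0, 10, 10)
  c2 <- toy_segment(0, 0, 10, 170)
  d <- base_distance(c1, c2, s)
  expect_equal(d %% 400, 0)  # includes 20^2 * factor_angle
  expect_equal(filamentr:::angle_diff(10, 170), 20)
})

test_that("transport: marginal arithmetic on tiny instances", {
  s <- tracking_settings(max_dist = 20)
  p1 <- toy_segment(0, 0, 5, 0)
  c1 <- toy_segment(2, 0, 5, 0)   # cost 4*4 = 16 << 400
  tp <- solve_transport(list(p1), list(c1), s)
  expect_equal(tp$plan[2, 2], 5)
  expect_equal(tp$plan[2, 1], 0)
  expect_equal(tp$plan[1, 2], 0)

  c2 <- toy_segment(2, 0, 3, 0)
  tp2 <- solve_transport(list(p1), list(c2), s)
  expect_equal(tp2$plan[2, 2], 3)
  expect_equal(tp2$plan[2, 1], 2)  # leftover producer mass to dummy
})

test_that("transport equals the dense LP oracle and is local and conservative", {
  set.seed(77)
  s <- tracking_settings(max_dist = 20)
  dmax2 <- 400
  for (rep in 1:40) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    cost <- matrix(runif(m * n, 0, 3 * dmax2), m, n)
    wp <- runif(m, 1, 15); wc <- runif(n, 1, 15)
    full <- rbind(c(dmax2, rep(dmax2, n)), cbind(rep(dmax2, m), cost))
    supply <- c(sum(wc), wp); demand <- c(sum(wp), wc)
    plan <- filamentr:::transport_simplex(full, supply, demand)
    ## mass conservation: exact marginals
    expect_equal(rowSums(plan), supply, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(colSums(plan), demand, tolerance = 1e-8,
                 ignore_attr = TRUE)
    ## objective equals the independently formulated LP
    oracle <- lp_transport_oracle(full, supply, demand)
    expect_equal(sum(full * plan), oracle$objective, tolerance = 1e-6)
    ## locality: cost above dmax^2 receives no flow
    expect_true(all(plan[-1, -1][cost > dmax2 + 1e-9] < 1e-9))
  }
})

test_that("locality in segment terms: far or twisted fragments never join", {
  set.seed(78)
  s <- tracking_settings(max_dist = 20)
  for (rep in 1:10) {
    P <- lapply(1:3, function(i)
      toy_segment(runif(1, 0, 60), runif(1, 0, 60), runif(1, 5, 12),
                  runif(1, 0, 180), id = i))
    C <- lapply(1:3, function(i)
      toy_segment(runif(1, 0, 60), runif(1, 0, 60), runif(1, 5, 12),
                  runif(1, 0, 180), id = i))
    tp <- solve_transport(P, C, s)
    for (j in 1:3) for (k in 1:3) {
      dl <- filamentr:::min_segment_distance(P[[j]]$points, C[[k]]$points)
      dphi <- filamentr:::angle_diff(P[[j]]$orientation, C[[k]]$orientation)
      if (dl > s$max_dist / 2 || dphi > s$max_dist)
        expect_lt(tp$plan[j + 1, k + 1], 1e-9)
    }
  }
})

test_that("consolidation sums plan blocks per filament pair", {
  s <- tracking_settings()
  A <- list(straight_filament(0, 0, 30, 0), straight_filament(0, 20, 25, 20))
  P <- c(fragment_filament(A[[1]], 10, 1L), fragment_filament(A[[2]], 10, 2L))
  tp <- solve_transport(P, P, s)
  M <- consolidate(tp, P, P, 2, 2)
  ## identity tracking: the diagonal carries each filament's full length
  expect_equal(M[1, 1], 30, tolerance = 1e-8)
  expect_equal(M[2, 2], 25, tolerance = 1e-8)
  expect_equal(M[1, 2] + M[2, 1], 0, tolerance = 1e-8)
  ## manual block sum oracle
  pid <- vapply(P, `[[`, numeric(1), "filament_id")
  hand <- sum(tp$plan[-1, -1][pid == 1, pid == 1])
  expect_equal(M[1, 1], hand)
})

test_that("link_filaments follows the accumulation and validity rules", {
  s <- tracking_settings(min_valid = 0.3, min_matched = 0.6,
                         min_rel_size = 0.25, min_abs_size = 10)
  ## full-mass single successor
  M <- matrix(c(40, 0), 1, 2)
  expect_equal(link_filaments(M, 40, c(40, 40), s)[[1]], 1L)
  ## nothing matched: solitary
  expect_length(link_filaments(matrix(0, 1, 2), 40, c(40, 40), s)[[1]], 0L)
  ## two partial successors: accumulate largest-first until min_matched
  M2 <- matrix(c(18, 10, 3), 1, 3)
  links <- link_filaments(M2, 40, c(40, 40, 40), s)[[1]]
  expect_equal(links, c(1L, 2L))  # 18 < 24, 18+10 = 28 >= 0.6*40
  ## below min_valid in total: solitary
  M3 <- matrix(c(6, 5), 1, 2)
  expect_length(link_filaments(M3, 40, c(40, 40), s)[[1]], 0L)
  ## candidates shorter than min_abs_size are never considered
  M4 <- matrix(c(40), 1, 1)
  expect_length(link_filaments(M4, 40, 5, s)[[1]], 0L)
})

test_that("track_stack: static stack gives full-length lifelines", {
  fl <- list(straight_filament(10, 10, 60, 14),
             straight_filament(20, 40, 80, 40))
  frames <- rep(list(fl), 5)
  lls <- track_stack(frames, tracking_settings())
  expect_length(lls, 2L)
  expect_true(all(vapply(lls, `[[`, integer(1), "persistence") == 5L))
  expect_error(track_stack(frames[1], tracking_settings()), "at least 2")
})

test_that("palindromic stacks yield time-symmetric lifelines", {
  fl1 <- list(straight_filament(10, 10, 60, 14))
  fl2 <- list(straight_filament(13, 10, 63, 14))
  fl3 <- list(straight_filament(16, 10, 66, 14))
  frames <- list(fl1, fl2, fl3, fl2, fl1)
  lls <- track_stack(frames, tracking_settings())
  expect_length(lls, 1L)
  expect_equal(lls[[1]]$persistence, 5L)
})

test_that("doubling fragment length changes matched mass by < 10%", {
  fl_a <- list(straight_filament(10, 30, 150, 40),
               straight_filament(30, 80, 170, 70))
  fl_b <- lapply(fl_a, function(f)
    fs_filament(f$points + 3, widths = f$widths))
  total_mass <- function(fragment_length) {
    s <- tracking_settings(fragment_length = fragment_length)
    P <- unlist(lapply(seq_along(fl_a), function(i)
      fragment_filament(fl_a[[i]], fragment_length, i)), recursive = FALSE)
    C <- unlist(lapply(seq_along(fl_b), function(i)
      fragment_filament(fl_b[[i]], fragment_length, i)), recursive = FALSE)
    tp <- solve_transport(P, C, s)
    sum(tp$plan[-1, -1])
  }
  m10 <- total_mass(10); m20 <- total_mass(20)
  expect_lt(abs(m20 - m10) / m10, 0.1)
})

test_that("tracking CSV export round-trips both layouts", {
  fl <- list(straight_filament(10, 10, 60, 14))
  frames <- rep(list(fl), 3)
  lls <- track_stack(frames, tracking_settings())
  p <- withr::local_tempfile(fileext = ".csv")
  df <- write_tracking_csv(lls, frames, p, layout = "by_frame")
  expect_equal(nrow(df), 3L)
  expect_equal(read.csv(p)$persistence, rep(3L, 3))
  df2 <- write_tracking_csv(lls, frames, p, layout = "by_filament")
  expect_equal(df2$lifeline, rep(1L, 3))
})
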