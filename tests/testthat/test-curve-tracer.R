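test_that("seed probing finds the stroke axis and breaks ties low", {
  m <- stripe_mask(40, 120, rows = 19:21, cols = 5:115)
  wm <- compute_width_map(m)
  s <- tracer_settings()
  pr <- seed_direction_pair(wm, c(60, 20), s)
  expect_equal(pr$angle_a, 0)
  expect_equal(pr$angle_b, 180)
  expect_gte(pr$mean_width_a, 2.5)

  ## isolated pixel: all directions tie -> smallest angle pair
  m2 <- matrix(FALSE, 21, 21); m2[11, 11] <- TRUE
  pr2 <- seed_direction_pair(compute_width_map(m2), c(11, 11), s)
  expect_equal(pr2$angle_a, 0)
  expect_equal(pr2$angle_b, 180)

  ## 45-degree stroke: pair within one increment of {45, 225}
  m3 <- matrix(FALSE, 80, 80)
  pts <- bresenham(c(10, 70), c(70, 10))
  for (i in seq_len(nrow(pts))) {
    m3 <- filamentr:::stamp_disks(m3, pts[i, , drop = FALSE], 3)
  }
  pr3 <- seed_direction_pair(compute_width_map(m3), c(40, 40), s)
  expect_lte(filamentr:::angle_diff(pr3$angle_a, 45), 3)
})

test_that("gatherer extension steps, trims at stroke ends, and stops", {
  m <- stripe_mask(40, 100, rows = 19:21, cols = 10:60)
  wm <- compute_width_map(m)
  s <- tracer_settings(l_min = 20, l_str = 10)
  ## mid-stripe, stroke continues: full step, direction unchanged
  g <- new_gatherer(c(20, 20), 0, wm)
  g <- extend_gatherer(g, wm, s)
  expect_false(g$stopped)
  expect_equal(g$direction, 0)
  expect_equal(g$points[2, ], c(30, 20), ignore_attr = TRUE)
  ## stroke ends 3 px ahead: step trimmed, then STOP facing background
  g2 <- new_gatherer(c(57, 20), 0, wm)
  g2 <- extend_gatherer(g2, wm, s)
  expect_lte(g2$points[nrow(g2$points), 1], 61)
  g2 <- extend_gatherer(g2, wm, s)
  expect_true(g2$stopped)
  ## facing background directly: STOP with points unchanged
  g3 <- new_gatherer(c(60, 20), 0, wm)
  g3 <- extend_gatherer(g3, wm, s)
  expect_true(g3$stopped)
  expect_equal(nrow(g3$points), 1L)
})

test_that("trace_filaments: blank, bezier stroke, parallel strokes", {
  expect_length(trace_filaments(matrix(FALSE, 64, 64), tracer_settings()), 0L)

  sp <- stroke_spec("bezier", width = 3, p0 = c(30, 200), p1 = c(128, 60),
                    p2 = c(226, 200))
  r <- render_strokes(list(sp), shape = c(256, 256))
  tr <- trace_filaments(r$image > 100,
                        tracer_settings(l_min = 40, l_str = 10, phi_diff = 4))
  expect_length(tr, 1L)
  d <- filament_descriptors(tr[[1]])
  expect_lt(abs(d$length - sp$length) / sp$length, 0.1)
  expect_lt(abs(d$mean_width - 3), 1)

  r2 <- render_strokes(list(
    stroke_spec("line", width = 3, p0 = c(30, 100), p1 = c(220, 100)),
    stroke_spec("line", width = 3, p0 = c(30, 120), p1 = c(220, 120))),
    shape = c(256, 256))
  tr2 <- trace_filaments(r2$image > 100, tracer_settings())
  expect_length(tr2, 2L)
  k1 <- paste(filament_pixels(tr2[[1]])[, 1], filament_pixels(tr2[[1]])[, 2])
  k2 <- paste(filament_pixels(tr2[[2]])[, 1], filament_pixels(tr2[[2]])[, 2])
  expect_length(intersect(k1, k2), 0L)
})

test_that("every accepted filament observes l_min and l_str bounds", {
  s <- tracer_settings(l_min = 30, l_str = 10)
  r <- render_strokes(list(
    stroke_spec("line", width = 3, p0 = c(20, 40), p1 = c(200, 80)),
    stroke_spec("arc", width = 3, center = c(120, 160), radius = 60,
                theta0 = 190, theta1 = 320)), shape = c(256, 256))
  tr <- trace_filaments(r$image > 100, s)
  for (f in tr) {
    expect_gte(filament_length(f), s$l_min)
    steps <- sqrt(rowSums(diff(f$points)^2))
    expect_true(all(steps <= s$l_str + 1))  # +1: pixel-rounded step endpoints
  }
})

test_that("rotating the image by 90 degrees rotates recovered orientations", {
  r <- render_strokes(list(
    stroke_spec("line", width = 3, p0 = c(30, 60), p1 = c(190, 100))),
    shape = c(220, 220))
  mask <- r$image > 100
  rot <- t(mask)[, rev(seq_len(nrow(mask)))]  # 90 deg rotation
  s <- tracer_settings()
  a <- trace_filaments(mask, s)
  b <- trace_filaments(rot, s)
  expect_equal(length(a), length(b))
  ang_a <- filament_descriptors(a[[1]])$angle
  ang_b <- filament_descriptors(b[[1]])$angle
  expect_lte(filamentr:::angle_diff(ang_a + 90, ang_b), 3 * s$phi_diff)
})

test_that("on straight strokes curve and straight modes agree", {
  m <- matrix(FALSE, 140, 220)
  m[69:71, 21:200] <- TRUE
  wm <- compute_width_map(m)
  straight <- scan_straight_filaments(wm, sensor_settings(minimal_length = 30))
  curved <- trace_filaments(m, tracer_settings(), wm = wm)
  expect_equal(length(straight$filaments), length(curved))
  ls <- filament_length(straight$filaments[[1]])
  lc <- filament_length(curved[[1]])
  expect_lt(abs(ls - lc) / ls, 0.05)
})

test_that("orientation-field validation: accept, discard, boundary, shorten", {
  s <- tracer_settings(alpha_tol = 20, conflict_fraction_limit = 0.30)
  of <- orientation_field(100, 100)
  f <- straight_filament(10, 50, 90, 50)
  ## unset field: accept with zero conflicts
  v <- validate_filament(f, of, s)
  expect_equal(v$decision, "ACCEPT")
  expect_equal(v$conflict_fraction, 0)

  ## interior 40% conflicting (perpendicular marks), clean endpoints: DISCARD
  of2 <- orientation_field(100, 100)
  of2[50, 30:62] <- 90  # 33 of 81 pixels ~ 40.7%
  v2 <- validate_filament(f, of2, s)
  expect_equal(v2$decision, "DISCARD")
  expect_gt(v2$conflict_fraction, 0.39)

  ## exactly 30% conflicts: NOT accepted (strict less-than rule)
  f3 <- straight_filament(1, 20, 100, 20)  # 100 pixels
  of3 <- orientation_field(100, 100)
  of3[20, 36:65] <- 90  # exactly 30 of 100
  v3 <- validate_filament(f3, of3, s)
  expect_false(v3$decision == "ACCEPT")
  expect_equal(v3$conflict_fraction, 0.30)

  ## conflicts at one endpoint: SHORTEN from that end inward
  of4 <- orientation_field(100, 100)
  of4[50, 10:45] <- 90  # 36 of 81 ~ 44%, includes the left endpoint
  v4 <- validate_filament(f, of4, s)
  expect_equal(v4$decision, "SHORTENED")
  expect_gte(min(v4$filament$points[, 1]), 46)

  ## 20% conflicts: ACCEPT
  of5 <- orientation_field(100, 100)
  of5[50, 30:45] <- 90  # 16 of 81 ~ 19.7%
  expect_equal(validate_filament(f, of5, s)$decision, "ACCEPT")

  ## conflicting orientation within alpha_tol is no conflict
  of6 <- orientation_field(100, 100)
  of6[50, 10:90] <- 15  # within 20 deg of 0
  expect_equal(validate_filament(f, of6, s)$decision, "ACCEPT")
})
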