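test_that("filament descriptors: straight, right angle, semicircle", {
  f <- fs_filament(rbind(c(0, 0), c(10, 0), c(20, 0)), widths = 3)
  d <- filament_descriptors(f)
  expect_equal(d$length, 20)
  expect_equal(d$mean_width, 3)
  expect_equal(d$angle, 0)
  expect_equal(d$curvature, 0)

  f2 <- fs_filament(rbind(c(0, 0), c(10, 0), c(10, 10)))
  d2 <- filament_descriptors(f2)
  expect_equal(d2$length, 20)
  expect_equal(d2$curvature, (pi / 2) / 20, tolerance = 1e-9)

  ## discretized semicircle radius 50: curvature within 10% of 0.02
  th <- seq(0, pi, length.out = 40)
  pts <- cbind(60 + 50 * cos(th), 60 - 50 * sin(th))
  d3 <- filament_descriptors(fs_filament(pts))
  expect_lt(abs(d3$curvature - 0.02) / 0.02, 0.1)
})

test_that("order parameter: alignment, symmetry, direct-sum oracle, rotation", {
  rec <- function(angles, lengths = 1) data.frame(length = rep_len(lengths,
    length(angles)), angle = angles)
  expect_equal(order_parameter(rec(rep(30, 5))), 1.0)
  expect_equal(order_parameter(rec(c(0, 90))), 0.0, tolerance = 1e-12)
  set.seed(21)
  ang <- runif(100, 0, 180)
  oracle <- Mod(sum(exp(2i * ang * pi / 180))) / 100
  expect_equal(order_parameter(rec(ang)), oracle, tolerance = 1e-12)
  ## rotation invariance
  for (rot in c(13, 77, 160)) {
    expect_equal(order_parameter(rec((ang + rot) %% 180)),
                 order_parameter(rec(ang)), tolerance = 1e-9)
  }
  expect_error(order_parameter(rec(numeric(0))), "at least one")
})

test_that("cell shape descriptors: rectangle, disk, brightness", {
  m <- matrix(FALSE, 60, 80); m[21:40, 21:60] <- TRUE  # 40 x 20 rectangle
  rec <- cell_shape_descriptors(m)
  expect_equal(rec$area, 800)
  expect_equal(rec$aspect_ratio, 2, tolerance = 0.05)
  expect_equal(unname(rec$centroid), c(40.5, 30.5))

  disk <- matrix(FALSE, 60, 60)
  off <- expand.grid(dx = -20:20, dy = -20:20)
  off <- off[off$dx^2 + off$dy^2 <= 400, ]
  disk[cbind(30 + off$dy, 30 + off$dx)] <- TRUE
  rec2 <- cell_shape_descriptors(disk)
  expect_equal(rec2$aspect_ratio, 1, tolerance = 0.05)
  expect_equal(rec2$long_half_axis, 20, tolerance = 1)

  img <- matrix(7, 60, 60)
  rec3 <- cell_shape_descriptors(matrix(TRUE, 60, 60), img)
  expect_equal(rec3$mean_brightness, 7)
  expect_error(cell_shape_descriptors(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("pixel-wise comparison partitions exactly", {
  A <- list(straight_filament(10, 10, 60, 10))
  expect_equal(compare_pixelwise(A, A, c(80, 80)),
               list(only_A = 0L, only_B = 0L, both = 51L))
  B <- list(straight_filament(10, 40, 60, 40))
  r <- compare_pixelwise(A, B, c(80, 80))
  expect_equal(r$both, 0L)
  expect_equal(r$only_A, 51L)
  ## constructed half overlap: set-arithmetic oracle
  C <- list(straight_filament(35, 10, 85, 10))
  r2 <- compare_pixelwise(A, C, c(100, 100))
  expect_equal(r2$both, 26L)       # columns 35..60
  expect_equal(r2$only_A, 25L)     # columns 10..34
  expect_equal(r2$only_B, 25L)     # columns 61..85
  expect_equal(r2$only_A + r2$only_B + r2$both, 76L)
})

test_that("object-wise matching honors the threshold and equals brute force", {
  A <- list(straight_filament(10, 10, 60, 10))
  r <- compare_objectwise(A, A, c(80, 80))
  expect_equal(nrow(r$matched), 1L)
  ## 60% coverage at threshold 0.75: unmatched
  B <- list(straight_filament(10, 10, 40, 10))  # covers 31/51 of A
  r2 <- compare_objectwise(A, B, c(80, 80), match_fraction = 0.75)
  expect_equal(nrow(r2$matched), 0L)
  expect_equal(r2$only_A, 1L)
  expect_equal(r2$only_B, 1L)

  ## 3-vs-3 constructed overlap vs exhaustive-search oracle
  A3 <- list(straight_filament(1, 10, 40, 10),
             straight_filament(1, 20, 40, 20),
             straight_filament(1, 30, 40, 30))
  B3 <- list(straight_filament(5, 10, 44, 10),
             straight_filament(3, 20, 42, 20),
             straight_filament(30, 30, 69, 30))
  shape <- c(80, 80)
  r3 <- compare_objectwise(A3, B3, shape, match_fraction = 0.75)
  ov <- matrix(0, 3, 3); fr <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    pa <- paste(filament_pixels(A3[[i]])[, 1], filament_pixels(A3[[i]])[, 2])
    pb <- paste(filament_pixels(B3[[j]])[, 1], filament_pixels(B3[[j]])[, 2])
    ov[i, j] <- length(intersect(pa, pb))
    fr[i, j] <- ov[i, j] / length(pa)
  }
  oracle <- brute_assignment(ov, fr, 0.75)
  expect_equal(nrow(r3$matched), oracle$n)
  expect_equal(sort(r3$matched[, 1]), sort(oracle$pairs[, 1]))
})

test_that("filament CSV export writes one row per filament plus summary", {
  fl <- list(straight_filament(5, 5, 50, 5), straight_filament(5, 20, 50, 50))
  p <- withr::local_tempfile(fileext = ".csv")
  write_filament_csv(fl, p)
  df <- read.csv(p)
  expect_equal(nrow(df), 3L)
  expect_equal(sum(df$row_type == "filament"), 2L)
  expect_true(all(c("length", "mean_width", "angle", "curvature") %in%
                    names(df)))
  write_filament_csv(list(), p)
  expect_equal(nrow(read.csv(p)), 0L)
})
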