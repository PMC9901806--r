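## Independent oracles, written separately from the package implementations.

## Brute-force width map: per-pixel disk growing with explicit pixel checks.
brute_width_map <- function(mask, tolerance = 0) {
  h <- nrow(mask); w <- ncol(mask)
  wm <- matrix(0L, h, w)
  max_d <- min(h, w)
  offs <- lapply(seq_len(max_d), function(d) {
    r <- d / 2
    k <- ceiling(r)
    g <- expand.grid(dx = -k:k, dy = -k:k)
    as.matrix(g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, , drop = FALSE])
  })
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!mask[y, x]) next
    d <- 0L
    repeat {
      if (d + 1L > max_d) break
      off <- offs[[d + 1L]]
      xs <- x + off[, 1]; ys <- y + off[, 2]
      inside <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
      hits <- sum(mask[cbind(ys[inside], xs[inside])])
      miss_frac <- (nrow(off) - hits) / nrow(off)
      if (miss_frac > tolerance + 1e-12) break
      d <- d + 1L
    }
    wm[y, x] <- d
  }
  wm
}

## Independent ray rasterization for directional means.
brute_ray_mean <- function(wm, start, angle, length) {
  n <- max(1L, round(length))
  th <- angle * pi / 180
  vals <- numeric(n)
  for (i in seq_len(n)) {
    x <- round(start[1] + (i - 1) * cos(th))
    y <- round(start[2] - (i - 1) * sin(th))
    vals[i] <- if (x >= 1 && x <= ncol(wm) && y >= 1 && y <= nrow(wm))
      wm[y, x] else 0
  }
  mean(vals)
}

## Exhaustive-search one-to-one assignment maximizing matched pairs (then
## total overlap) for the object-wise comparison oracle.
brute_assignment <- function(overlap, frac_a, match_fraction) {
  ## overlap[i, j] = |a_i intersect b_j|; frac_a[i, j] = overlap / |a_i|
  ok <- frac_a >= match_fraction
  na <- nrow(overlap); nb <- ncol(overlap)
  best <- list(n = -1, total = -Inf, pairs = NULL)
  recurse <- function(i, used_b, pairs, total) {
    if (i > na) {
      n <- if (is.null(pairs)) 0 else nrow(pairs)
      if (n > best$n || (n == best$n && total > best$total))
        best <<- list(n = n, total = total, pairs = pairs)
      return()
    }
    recurse(i + 1L, used_b, pairs, total)  # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (used_b[j] || !ok[i, j]) next
      recurse(i + 1L, `[<-`(used_b, j, TRUE), rbind(pairs, c(i, j)),
              total + overlap[i, j])
    }
  }
  recurse(1L, logical(nb), NULL, 0)
  best
}
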