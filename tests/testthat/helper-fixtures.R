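## Shared fixture builders (all generated in code; nothing on disk).

stripe_mask <- function(h = 40, w = 100, rows = 19:21, cols = 10:90) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

## A filament-like straight polyline for tracking tests.
straight_filament <- function(x0, y0, x1, y1, width = 3) {
  fs_filament(rbind(c(x0, y0), c(x1, y1)), widths = width)
}

## Tracking segments without going through filaments.
toy_segment <- function(x, y, w = 10, ang = 0, id = 1L) {
  th <- ang * pi / 180
  list(filament_id = as.integer(id),
       points = rbind(c(x, y), c(x + w * cos(th), y - w * sin(th))),
       weight = w, orientation = ang %% 180)
}

## Arc-class tracer settings: probing increment and step length sized to the
## target curvature (inc/l_str >= 1/R) and to the pixel grid
## (l_str * sin(inc) >= 1 so a turned probe actually changes pixels).
arc_settings <- function(R) {
  if (R <= 40) tracer_settings(l_min = 30, l_str = 5, phi_diff = 4)
  else if (R <= 80) tracer_settings(l_min = 30, l_str = 7, phi_diff = 3)
  else tracer_settings(l_min = 30, l_str = 10, phi_diff = 2)
}
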