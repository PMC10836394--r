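# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive re-derivation kept separate from the package code.

# Brute-force radial average: explicit double loop grouping pixels by
# rounded radius (half away from zero), mean per radius, frequencies
# r / (n * pixel_size), bins beyond Nyquist dropped.
oracle_radial_average <- function(spectrum, pixel_size) {
  n <- nrow(spectrum)
  ctr <- n %/% 2 + 1
  groups <- list()
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      d <- sqrt((i - ctr)^2 + (j - ctr)^2)
      r <- trunc(d + 0.5)
      if (r >= 1 && r <= n %/% 2) {
        key <- as.character(r)
        groups[[key]] <- c(groups[[key]], spectrum[i, j])
      }
    }
  }
  radii <- sort(as.integer(names(groups)))
  list(frequencies = radii / (n * pixel_size),
       values = vapply(as.character(radii),
                       function(k) mean(groups[[k]]), numeric(1),
                       USE.NAMES = FALSE))
}

# Winding-number point-in-polygon (Sunday's signed-crossing formulation),
# independent of the package's ray-casting code. Boundary points are
# undefined; callers use points off the boundary.
oracle_winding_inside <- function(px, py, v) {
  n <- nrow(v)
  wn <- 0L
  for (i in seq_len(n)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]
    j <- if (i == n) 1L else i + 1L
    x2 <- v[j, 1]; y2 <- v[j, 2]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    if (y1 <= py) {
      if (y2 > py && is_left > 0) wn <- wn + 1L
    } else {
      if (y2 <= py && is_left < 0) wn <- wn - 1L
    }
  }
  wn != 0L
}

# Per-row threshold scan: literal re-reading of the keep rule.
oracle_threshold_keep <- function(table, rules) {
  keep <- logical(nrow(table))
  for (r in seq_len(nrow(table))) {
    ok <- TRUE
    for (k in seq_len(nrow(rules))) {
      v <- table[[rules$label[k]]][r]
      if (is.na(v)) { ok <- FALSE; next }
      if (!is.na(rules$min[k]) && v < rules$min[k]) ok <- FALSE
      if (!is.na(rules$max[k]) && v > rules$max[k]) ok <- FALSE
    }
    keep[r] <- ok
  }
  keep
}

# Brute-force 2D angle binning with last-bin-closed edges.
oracle_angle_counts <- function(rot, tilt, n_rot, n_tilt) {
  re <- seq(-180, 180, length.out = n_rot + 1)
  te <- seq(0, 180, length.out = n_tilt + 1)
  counts <- matrix(0L, n_rot, n_tilt)
  for (k in seq_along(rot)) {
    ri <- NA
    for (b in seq_len(n_rot)) {
      hi_ok <- if (b == n_rot) rot[k] <= re[b + 1] else rot[k] < re[b + 1]
      if (rot[k] >= re[b] && hi_ok) { ri <- b; break }
    }
    ti <- NA
    for (b in seq_len(n_tilt)) {
      hi_ok <- if (b == n_tilt) tilt[k] <= te[b + 1] else tilt[k] < te[b + 1]
      if (tilt[k] >= te[b] && hi_ok) { ti <- b; break }
    }
    counts[ri, ti] <- counts[ri, ti] + 1L
  }
  counts
}

# Random simple polygon: vertices at jittered regular angles around a
# center. Consecutive angular gaps stay below pi (for n >= 4), which
# guarantees simplicity for any positive radii.
random_simple_polygon <- function(seed, n_vertices = 8, center = c(0.5, 0.5),
                                  r_range = c(0.1, 0.45)) {
  set.seed(seed)
  ang <- 2 * pi * (seq_len(n_vertices) - 1 +
                     runif(n_vertices, 0.05, 0.95)) / n_vertices
  rad <- runif(n_vertices, r_range[1], r_range[2])
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

local_project <- function(spec, envir = parent.frame()) {
  root <- file.path(withr::local_tempdir(.local_envir = envir), "proj")
  make_project(spec, root)
}
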