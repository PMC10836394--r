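#' Declarative threshold rules
#'
#' A threshold set is a list of per-label `[min, max]` rules used for live
#' filtering of micrograph (or particle) metadata. Both bounds are
#' inclusive and either may be absent (unbounded): with a rule
#' `max = 50` on accumulated motion, micrographs *over* 50 Angstrom are
#' discarded and one at exactly 50 is kept.
#'
#' @param ... rules given as `label = c(min, max)`, with `NA` for an absent
#'   bound, or a single `data.frame` with columns `label`, `min`, `max`.
#' @return an object of class `threshold_set`.
#' @examples
#' threshold_set(rlnAccumMotionTotal = c(NA, 50),
#'               rlnCtfMaxResolution = c(2, 6))
#' @export
threshold_set <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.data.frame(args[[1]]) &&
      is.null(names(args))) {
    df <- args[[1]]
    stopifnot(all(c("label", "min", "max") %in% names(df)))
    rules <- data.frame(label = as.character(df$label),
                        min = as.numeric(df$min), max = as.numeric(df$max),
                        stringsAsFactors = FALSE)
  } else {
    labs <- names(args)
    if (length(args) && (is.null(labs) || any(!nzchar(labs)))) {
      relmeta_stop("threshold rules must be named (label = c(min, max))",
                   class = "relmeta_validation_error")
    }
    rules <- data.frame(
      label = labs,
      min = vapply(args, function(r) as.numeric(r[1]), numeric(1)),
      max = vapply(args, function(r) as.numeric(r[2]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  bad <- !is.na(rules$min) & !is.na(rules$max) & rules$min > rules$max
  if (any(bad)) {
    relmeta_stop("rule on '%s' has min > max", rules$label[bad][1],
                 class = "relmeta_validation_error")
  }
  structure(list(rules = rules), class = "threshold_set")
}

#' Load a threshold set from a config file
#'
#' One rule per line: `label  min  max`, with `-` (or `NA`) for an absent
#' bound; `#` comments and blank lines are ignored.
#'
#' @param path config file path.
#' @return a [threshold_set()].
#' @export
read_threshold_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    relmeta_stop("threshold config %s: each line needs 'label min max'",
                 path, class = "relmeta_format_error")
  }
  num <- function(s) ifelse(s %in% c("-", "NA", "na"), NA_real_,
                            suppressWarnings(as.numeric(s)))
  threshold_set(data.frame(
    label = vapply(parts, `[`, character(1), 1),
    min = num(vapply(parts, `[`, character(1), 2)),
    max = num(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE))
}

#' Partition a table by threshold rules
#'
#' A row is kept iff every rule is satisfied (`min <= value <= max`, absent
#' bound unbounded, both bounds inclusive). Rows with `NA`/`NaN` in a
#' thresholded column are discarded with a warning (fail-safe for partially
#' processed micrographs). Inputs are never mutated; row order is preserved
#' in both outputs, which partition the input exactly.
#'
#' @param table loop table (`data.frame`).
#' @param thresholds a [threshold_set()].
#' @return list with elements `kept` and `discarded`.
#' @export
apply_thresholds <- function(table, thresholds) {
  stopifnot(is.data.frame(table), inherits(thresholds, "threshold_set"))
  keep <- rep(TRUE, nrow(table))
  n_na <- 0L
  for (i in seq_len(nrow(thresholds$rules))) {
    rule <- thresholds$rules[i, ]
    lab <- resolve_label(names(table), rule$label, "table")
    v <- table[[lab]]
    if (!is.numeric(v)) {
      relmeta_stop("column '%s' is not numeric and cannot be thresholded",
                   lab, class = "relmeta_type_error")
    }
    ok <- rep(TRUE, length(v))
    if (!is.na(rule$min)) ok <- ok & v >= rule$min
    if (!is.na(rule$max)) ok <- ok & v <= rule$max
    nas <- is.na(v)
    n_na <- n_na + sum(nas & keep)
    ok[nas] <- FALSE
    keep <- keep & ok
  }
  if (n_na > 0L) {
    warning(sprintf("%d row(s) with missing values in thresholded columns %s",
                    n_na, "were discarded"), call. = FALSE)
  }
  kept <- table[keep, , drop = FALSE]
  discarded <- table[!keep, , drop = FALSE]
  rownames(kept) <- NULL
  rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Polygon ("lasso") selection
#'
#' A closed simple polygon over two metadata axes, emulating in-plot lasso
#' selection of micrographs or particles.
#'
#' @param x_label,y_label labels of the two numeric columns spanning the
#'   selection plane.
#' @param vertices matrix (or two-column data.frame) of at least 3 `(x, y)`
#'   vertices; the polygon is implicitly closed. Must be simple
#'   (non-self-intersecting) with nonzero area.
#' @return an object of class `polygon_selection`.
#' @export
polygon_selection <- function(x_label, y_label, vertices) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2L, is.numeric(v))
  if (nrow(v) < 3L) {
    relmeta_stop("polygon needs at least 3 vertices (got %d)", nrow(v),
                 class = "relmeta_validation_error")
  }
  if (abs(polygon_area(v)) < 1e-12) {
    relmeta_stop("degenerate polygon: zero area",
                 class = "relmeta_validation_error")
  }
  if (!polygon_is_simple(v)) {
    relmeta_stop("polygon is self-intersecting",
                 class = "relmeta_validation_error")
  }
  structure(list(x_label = x_label, y_label = y_label, vertices = v),
            class = "polygon_selection")
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Proper-intersection test between non-adjacent edges; shared endpoints of
# adjacent edges are allowed.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  intersects <- function(s1, s2) {
    d1 <- orient(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
    d2 <- orient(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
    d3 <- orient(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
    d4 <- orient(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
    d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (intersects(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test
#'
#' Ray-casting with an explicit boundary check: points strictly inside or
#' on the boundary count as selected (circling a point on the polygon edge
#' selects it).
#'
#' @param p numeric `(x, y)` pair, or a two-column matrix of points.
#' @param polygon a [polygon_selection()].
#' @return logical, one element per point.
#' @export
point_in_polygon <- function(p, polygon) {
  stopifnot(inherits(polygon, "polygon_selection"))
  pts <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  v <- polygon$vertices
  n <- nrow(v)
  nxt <- c(2:n, 1)
  out <- logical(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    x <- pts[k, 1]; y <- pts[k, 2]
    inside <- FALSE
    on_edge <- FALSE
    for (i in seq_len(n)) {
      x1 <- v[i, 1]; y1 <- v[i, 2]
      x2 <- v[nxt[i], 1]; y2 <- v[nxt[i], 2]
      # boundary: collinear and within the segment's bounding box
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) {
        on_edge <- TRUE
        break
      }
      if ((y1 > y) != (y2 > y)) {
        x_at <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < x_at) inside <- !inside
      }
    }
    out[k] <- on_edge || inside
  }
  out
}

#' Select table rows inside a lasso polygon
#'
#' @param table loop table with numeric columns for the polygon's axes.
#' @param sel a [polygon_selection()].
#' @return the selected rows, original order preserved.
#' @export
lasso_select <- function(table, sel) {
  stopifnot(is.data.frame(table), inherits(sel, "polygon_selection"))
  xl <- resolve_label(names(table), sel$x_label, "table")
  yl <- resolve_label(names(table), sel$y_label, "table")
  x <- table[[xl]]; y <- table[[yl]]
  if (!is.numeric(x) || !is.numeric(y)) {
    relmeta_stop("lasso axes '%s'/'%s' must be numeric", xl, yl,
                 class = "relmeta_type_error")
  }
  keep <- if (nrow(table)) point_in_polygon(cbind(x, y), sel) else logical(0)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a selection as a STAR file for RELION re-import
#'
#' Writes the selected table (block `data_micrographs`, or
#' `data_particles` when an optics block is supplied, which is emitted
#' first). Re-parsing the file yields the identical table.
#'
#' @param table selected loop table.
#' @param path output STAR path.
#' @param optics optional [star_block()] (typically `data_optics`) to
#'   prepend, as RELION particle files require.
#' @param block_name name for the data block; default depends on `optics`.
#' @return `path`, invisibly.
#' @export
export_selection <- function(table, path, optics = NULL,
                             block_name = if (is.null(optics))
                               "micrographs" else "particles") {
  stopifnot(is.data.frame(table))
  blocks <- list()
  if (!is.null(optics)) {
    stopifnot(inherits(optics, "star_block"))
    blocks <- c(blocks, list(optics))
  }
  blocks <- c(blocks, list(star_block(block_name, table = table)))
  write_star(star_document(blocks), path)
  invisible(path)
}

#' Extract aligned plotting columns for a three-variable view
#'
#' The dashboards plot any two numeric metadata labels against each other
#' with an optional third label as color; each rendered point must map back
#' to its micrograph or particle row.
#'
#' @param table loop table.
#' @param x_label,y_label numeric metadata labels.
#' @param color_label optional third label (any type).
#' @return `data.frame` with columns `row_id`, `x`, `y` and (when
#'   requested) `color`.
#' @export
three_variable_view <- function(table, x_label, y_label, color_label = NULL) {
  stopifnot(is.data.frame(table))
  xl <- resolve_label(names(table), x_label, "table")
  yl <- resolve_label(names(table), y_label, "table")
  if (!is.numeric(table[[xl]]) || !is.numeric(table[[yl]])) {
    relmeta_stop("x/y labels '%s'/'%s' must be numeric columns", xl, yl,
                 class = "relmeta_type_error")
  }
  out <- data.frame(row_id = seq_len(nrow(table)),
                    x = table[[xl]], y = table[[yl]])
  if (!is.null(color_label)) {
    cl <- resolve_label(names(table), color_label, "table")
    out$color <- table[[cl]]
  }
  out
}
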