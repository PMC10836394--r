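test_that("threshold bounds are inclusive: motion over 50 A is discarded", {
  tab <- data.frame(rlnMicrographName = c("a", "b", "c"),
                    rlnAccumMotionTotal = c(30, 50, 70))
  parts <- apply_thresholds(tab, threshold_set(AccumMotionTotal = c(NA, 50)))
  expect_identical(parts$kept$rlnAccumMotionTotal, c(30, 50))
  expect_identical(parts$discarded$rlnAccumMotionTotal, 70)
  # empty threshold set keeps everything
  all_kept <- apply_thresholds(tab, threshold_set())
  expect_identical(all_kept$kept, tab)
  expect_identical(nrow(all_kept$discarded), 0L)
})

test_that("threshold partitions match the brute-force row scan", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:40, 1)
    tab <- data.frame(rlnA = runif(n, 0, 100), rlnB = rnorm(n),
                      rlnC = sample(letters, n, replace = TRUE))
    rules <- data.frame(
      label = c("rlnA", "rlnB"),
      min = c(sample(c(NA, runif(1, 0, 50)), 1), -1),
      max = c(sample(c(NA, runif(1, 50, 100)), 1), 1))
    parts <- apply_thresholds(tab, threshold_set(rules))
    keep <- oracle_threshold_keep(tab, rules)
    expect_identical(parts$kept, {
      k <- tab[keep, , drop = FALSE]; rownames(k) <- NULL; k
    })
    expect_identical(parts$discarded, {
      d <- tab[!keep, , drop = FALSE]; rownames(d) <- NULL; d
    })
    # partition: sizes add up, no row duplicated
    expect_identical(nrow(parts$kept) + nrow(parts$discarded), n)
  }
})

test_that("thresholds reject non-numeric columns and discard NaN rows", {
  tab <- data.frame(rlnName = c("a", "b"), rlnV = c(1, NaN))
  expect_error(apply_thresholds(tab, threshold_set(rlnName = c(0, 1))),
               "rlnName", class = "relmeta_type_error")
  expect_warning(parts <- apply_thresholds(tab,
                                           threshold_set(rlnV = c(0, 10))),
                 "missing values")
  expect_identical(parts$kept$rlnName, "a")
  expect_identical(parts$discarded$rlnName, "b")
})

test_that("point-in-polygon handles interior, exterior and boundary", {
  sq <- polygon_selection("x", "y", rbind(c(0, 0), c(1, 0), c(1, 1),
                                          c(0, 1)))
  expect_true(point_in_polygon(c(0.5, 0.5), sq))
  expect_false(point_in_polygon(c(2, 2), sq))
  # boundary counts as selected (edge and vertex)
  expect_true(point_in_polygon(c(0.5, 0), sq))
  expect_true(point_in_polygon(c(1, 1), sq))
  expect_error(polygon_selection("x", "y", rbind(c(0, 0), c(1, 1),
                                                 c(2, 2))),
               "zero area", class = "relmeta_validation_error")
  expect_error(polygon_selection("x", "y", rbind(c(0, 0), c(4, 0),
                                                 c(4, 2), c(2, -1),
                                                 c(0, 2))),
               "self-intersecting", class = "relmeta_validation_error")
})

test_that("ray casting agrees with the winding-number oracle", {
  for (s in 1:10) {
    v <- random_simple_polygon(s, n_vertices = 5 + s)
    poly <- polygon_selection("x", "y", v)
    set.seed(1000 + s)
    pts <- cbind(runif(300), runif(300))
    got <- point_in_polygon(pts, poly)
    ora <- vapply(seq_len(nrow(pts)),
                  function(i) oracle_winding_inside(pts[i, 1], pts[i, 2], v),
                  logical(1))
    expect_identical(got, ora)
  }
})

test_that("ray casting agrees with mgcv's independent implementation", {
  skip_if_not_installed("mgcv")
  v <- random_simple_polygon(99, n_vertices = 9)
  poly <- polygon_selection("x", "y", v)
  set.seed(7)
  pts <- cbind(runif(500), runif(500))
  got <- point_in_polygon(pts, poly)
  ora <- mgcv::in.out(rbind(v, v[1, ]), pts)
  expect_identical(got, as.logical(ora))
})

test_that("lasso selection picks exactly the enclosed cluster", {
  set.seed(5)
  blob1 <- cbind(rnorm(40, 3.2, 0.15), rnorm(40, 0.10, 0.01))
  blob2 <- cbind(rnorm(40, 6.5, 0.15), rnorm(40, 0.25, 0.01))
  tab <- data.frame(rlnCtfMaxResolution = c(blob1[, 1], blob2[, 1]),
                    rlnCtfFigureOfMerit = c(blob1[, 2], blob2[, 2]))
  box <- polygon_selection("CtfMaxResolution", "CtfFigureOfMerit",
                           rbind(c(2, 0.0), c(5, 0.0), c(5, 0.2),
                                 c(2, 0.2)))
  sel <- lasso_select(tab, box)
  ora <- point_in_polygon(cbind(tab[[1]], tab[[2]]), box)
  expect_identical(nrow(sel), sum(ora))
  expect_identical(sel, {
    k <- tab[ora, , drop = FALSE]; rownames(k) <- NULL; k
  })
  expect_true(all(sel$rlnCtfMaxResolution < 5))

  # polygon enclosing all points / none
  all_box <- polygon_selection("CtfMaxResolution", "CtfFigureOfMerit",
                               rbind(c(0, -1), c(10, -1), c(10, 1),
                                     c(0, 1)))
  expect_identical(lasso_select(tab, all_box), tab)
  none_box <- polygon_selection("CtfMaxResolution", "CtfFigureOfMerit",
                                rbind(c(90, 90), c(91, 90), c(91, 91)))
  none <- lasso_select(tab, none_box)
  expect_identical(nrow(none), 0L)
  expect_identical(names(none), names(tab))
})

test_that("thresholds and lasso commute on the same table", {
  set.seed(13)
  tab <- data.frame(rlnA = runif(60, 0, 10), rlnB = runif(60, 0, 10))
  th <- threshold_set(rlnA = c(2, 9))
  poly <- polygon_selection("rlnA", "rlnB",
                            rbind(c(1, 1), c(8, 2), c(9, 9), c(2, 8)))
  a <- lasso_select(apply_thresholds(tab, th)$kept, poly)
  b <- apply_thresholds(lasso_select(tab, poly), th)$kept
  expect_identical(a, b)
})

test_that("exported selections re-import losslessly", {
  dir <- withr::local_tempdir()
  optics <- star_block("optics", table = data.frame(
    rlnOpticsGroup = 1L, rlnOpticsGroupName = "opticsGroup1",
    rlnMicrographPixelSize = 1.25, check.names = FALSE))
  tab <- data.frame(rlnAngleRot = c(-12.5, 30.25), rlnAngleTilt = c(45.5, 90),
                    rlnOpticsGroup = c(1L, 1L), check.names = FALSE)
  p <- file.path(dir, "sel.star")
  export_selection(tab, p, optics = optics)
  doc <- read_star(p)
  expect_identical(names(doc$blocks), c("optics", "particles"))
  expect_identical(get_table(doc, "particles"), tab)
  expect_identical(get_table(doc, "optics"), optics$table)

  # micrographs subset: single block; 0-row selection still valid STAR
  export_selection(tab[0, ], file.path(dir, "empty.star"))
  doc0 <- read_star(file.path(dir, "empty.star"))
  expect_identical(names(doc0$blocks), "micrographs")
  expect_identical(nrow(get_table(doc0)), 0L)
  expect_identical(names(get_table(doc0)), names(tab))
})

test_that("three-variable views stay aligned and map back to rows", {
  tab <- data.frame(rlnCtfMaxResolution = c(3, 4, 5),
                    rlnCtfFigureOfMerit = c(0.1, 0.2, 0.3),
                    rlnMicrographIceThickness = c(7, 8, 9))
  v <- three_variable_view(tab, "CtfMaxResolution", "CtfFigureOfMerit",
                           "MicrographIceThickness")
  expect_identical(v$row_id, 1:3)
  expect_identical(v$x, tab[[1]])
  expect_identical(v$y, tab[[2]])
  expect_identical(v$color, tab[[3]])
  # color omitted -> no color column
  v2 <- three_variable_view(tab, "CtfMaxResolution", "CtfFigureOfMerit")
  expect_false("color" %in% names(v2))
  err <- expect_error(three_variable_view(tab, "Nope", "CtfFigureOfMerit"),
                      class = "relmeta_lookup_error")
  expect_match(conditionMessage(err), "rlnCtfMaxResolution")
})
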