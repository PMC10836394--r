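run_project <- function(kind = "class3d", k = 3L, iters = 6L, seed = 41L) {
  make_project(
    fixture_spec(seed = seed, n_micrographs = 2, image_size = 64,
                 run_plan = list(kind = kind, n_classes = k,
                                 n_iter = iters)),
    file.path(withr::local_tempdir(.local_envir = parent.frame()), "proj"))
}

test_that("iteration discovery finds pairs, skips incomplete ones", {
  proj <- run_project(iters = 6L)
  iters <- discover_iterations(proj$run$job_dir)
  expect_identical(iters$iteration, 0:5)
  expect_true(all(file.exists(iters$model)))
  expect_true(all(file.exists(iters$optimiser)))
  # break one pair: the iteration is dropped with a warning
  file.remove(file.path(proj$run$job_dir, "run_it003_model.star"))
  expect_warning(left <- discover_iterations(proj$run$job_dir),
                 "3 incomplete")
  expect_identical(left$iteration, c(0:2, 4:5))
  # empty/missing directory -> zero rows
  expect_identical(nrow(discover_iterations(file.path(proj$root, "nope"))),
                   0L)
})

test_that("planted convergence series are recovered bit-exactly", {
  proj <- run_project(kind = "class3d", iters = 5L)
  s <- extract_series(proj$run$job_dir, "ChangesOptimalClasses")
  expect_identical(s$values, proj$run$changes)
  expect_identical(s$iterations, proj$run$iterations)

  ref <- run_project(kind = "refine3d", k = 1L, iters = 4L, seed = 43L)
  r <- extract_series(ref$run$job_dir, "CurrentResolution")
  expect_identical(r$values, ref$run$resolution)

  err <- expect_error(extract_series(proj$run$job_dir, "NoSuchLabel"),
                      class = "relmeta_lookup_error")
  expect_match(conditionMessage(err), "rlnChangesOptimalClasses")
})

test_that("class distributions are recovered and rows sum to one", {
  proj <- run_project(k = 3L, iters = 6L)
  cd <- class_distribution(proj$run$job_dir)
  expect_identical(cd$fractions, proj$run$fractions)
  expect_identical(cd$classes, 1:3)
  expect_true(all(abs(rowSums(cd$fractions) - 1) <= 1e-6))
  expect_true(all(cd$fractions >= 0))

  # K = 1: all-ones column
  one <- run_project(k = 1L, iters = 3L, seed = 47L)
  cd1 <- class_distribution(one$run$job_dir)
  expect_identical(dim(cd1$fractions), c(3L, 1L))
  expect_true(all(cd1$fractions == 1))
})

test_that("per-class model spectra come back point for point", {
  proj <- run_project(k = 2L, iters = 4L)
  model <- file.path(proj$run$job_dir, "run_it003_model.star")
  fsc <- model_spectra(model, "GoldStandardFsc")
  expect_length(fsc, 2L)
  for (cls in 1:2) {
    expect_identical(fsc[[cls]]$resolution, proj$run$spectra[[cls]]$freq)
    expect_identical(fsc[[cls]]$value, proj$run$spectra[[cls]]$fsc)
  }
  orient <- model_spectra(model, "SpectralOrientabilityContribution")
  expect_length(orient, 2L)
  expect_identical(orient[[1]]$value, proj$run$spectra[[1]]$orient)
  expect_error(model_spectra(model, "NoSuchSpectrum"),
               class = "relmeta_lookup_error")
})

test_that("fsc crossing interpolates linearly and flags at-Nyquist", {
  lin <- list(frequency = seq(0, 0.5, length.out = 1001),
              fsc = seq(1, 0, length.out = 1001))
  res <- fsc_crossing(lin, 0.143)
  expect_false(res$at_nyquist)
  expect_equal(res$frequency, 0.5 * (1 - 0.143), tolerance = 1e-12)
  expect_equal(res$resolution, 1 / 0.4285, tolerance = 1e-9)

  # constant 1.0 never crosses
  flat <- list(frequency = c(0.1, 0.2, 0.3), fsc = c(1, 1, 1))
  r2 <- fsc_crossing(flat, 0.143)
  expect_true(r2$at_nyquist)
  expect_equal(r2$resolution, 1 / 0.3)

  # threshold met exactly at a sample point
  exact <- list(frequency = c(0.1, 0.25, 0.4), fsc = c(1, 0.143, 0.05))
  expect_equal(fsc_crossing(exact, 0.143)$resolution, 1 / 0.25)

  expect_error(fsc_crossing(list(frequency = c(0.2, 0.1), fsc = c(1, 0)),
                            0.143),
               "increasing", class = "relmeta_validation_error")
  expect_error(fsc_crossing(lin, 1.5), class = "relmeta_validation_error")
})

test_that("angular histograms conserve counts and match brute binning", {
  one <- data.frame(rlnAngleRot = 0, rlnAngleTilt = 90)
  h1 <- angular_histogram(one, 8L, 4L)
  expect_identical(sum(h1$counts), 1L)
  expect_identical(sum(h1$counts > 0), 1L)

  parts <- make_particles(2000, seed = 3)
  h <- angular_histogram(parts, 36L, 18L)
  expect_identical(sum(h$counts), 2000L)
  expect_identical(h$counts,
                   oracle_angle_counts(parts$rlnAngleRot,
                                       parts$rlnAngleTilt, 36L, 18L))
  # right/top edges land in the last bin
  edge <- data.frame(rlnAngleRot = c(180, -180), rlnAngleTilt = c(180, 0))
  he <- angular_histogram(edge, 4L, 4L)
  expect_identical(he$counts[4, 4], 1L)
  expect_identical(he$counts[1, 1], 1L)

  bad <- data.frame(rlnAngleRot = c(0, 200), rlnAngleTilt = c(90, 90))
  expect_error(angular_histogram(bad), "row",
               class = "relmeta_validation_error")
})

test_that("tilted optics groups occupy different tilt bands", {
  parts <- make_particles(4000, optics_groups = list(
    list(fraction = 0.5, tilt_center = 90, spread = 5),
    list(fraction = 0.5, tilt_center = 50, spread = 5)), seed = 8)
  g1 <- parts[parts$rlnOpticsGroup == 1L, ]
  g2 <- parts[parts$rlnOpticsGroup == 2L, ]
  h1 <- angular_histogram(g1, 12L, 18L)
  h2 <- angular_histogram(g2, 12L, 18L)
  occ1 <- which(colSums(h1$counts) > 0)   # tilt bins (10 degrees each)
  occ2 <- which(colSums(h2$counts) > 0)
  expect_gt(min(occ1), max(occ2) - 2)     # bands centred 40 degrees apart
  expect_equal(mean(g1$rlnAngleTilt), 90, tolerance = 0.01)
  expect_equal(mean(g2$rlnAngleTilt), 50, tolerance = 0.01)
})

test_that("job backlog counts done vs pending and clamps races", {
  proj <- make_project(
    fixture_spec(seed = 51, n_micrographs = 10, n_corrected = 7,
                 image_size = 64),
    file.path(withr::local_tempdir(), "proj"))
  jobs <- data.frame(
    name = c("MotionCorr/job002/", "CtfFind/job003/"),
    input_star = c("Import/job001/movies.star",
                   "MotionCorr/job002/corrected_micrographs.star"),
    output_star = c("MotionCorr/job002/corrected_micrographs.star",
                    "CtfFind/job003/micrographs_ctf.star"))
  bl <- job_backlog(proj$root, jobs)
  expect_identical(bl$done, c(7L, 7L))
  expect_identical(bl$pending, c(3L, 0L))

  # missing output: nothing done yet
  jobs$output_star[2] <- "CtfFind/job003/does_not_exist.star"
  bl2 <- job_backlog(proj$root, jobs)
  expect_identical(bl2$done[2], 0L)
  expect_identical(bl2$pending[2], 7L)

  # output ahead of a stale input listing: clamped with a warning
  ahead <- data.frame(name = "CtfFind/job003/",
                      input_star = "CtfFind/job003/does_not_exist.star",
                      output_star = "CtfFind/job003/micrographs_ctf.star")
  expect_warning(bl3 <- job_backlog(proj$root, ahead), "clamped")
  expect_identical(bl3$pending, 0L)
  expect_identical(bl3$done, 7L)
})
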