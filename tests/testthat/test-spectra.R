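test_that("power spectrum satisfies the basic Fourier identities", {
  # constant image: all power at DC
  img <- matrix(3, 32, 32)
  sp <- power_spectrum(img, 1)
  ctr <- 17L
  expect_equal(sp[ctr, ctr], (3 * 32 * 32)^2)
  off <- sp; off[ctr, ctr] <- 0
  expect_lt(max(off), 1e-12 * sp[ctr, ctr])

  # cosine grating of period 4 px at 1 A/px: maxima at radius n/4 = 0.25 1/A
  n <- 64
  img <- matrix(cos(2 * pi * (seq_len(n) - 1) / 4), n, n, byrow = TRUE)
  sp <- power_spectrum(img, 1)
  sp[33, 33] <- 0
  peak <- which(sp >= max(sp) * (1 - 1e-9), arr.ind = TRUE)
  r_peak <- sqrt((peak[, 1] - 33)^2 + (peak[, 2] - 33)^2)
  expect_equal(unname(r_peak) / n, rep(0.25, nrow(peak)))
  expect_gte(nrow(peak), 2L)

  # Parseval for the unnormalized DFT
  set.seed(42)
  img <- matrix(rnorm(48 * 48), 48, 48)
  expect_equal(sum(power_spectrum(img, 1)), 48^2 * sum(img^2))
})

test_that("power spectrum validates input and crops non-square images", {
  expect_error(power_spectrum(matrix(c(NA, 1:255), 16, 16), 1),
               "non-finite", class = "relmeta_validation_error")
  expect_error(power_spectrum(matrix(1, 32, 32), 0), "pixel_size",
               class = "relmeta_validation_error")
  expect_error(power_spectrum(matrix(1, 8, 8), 1), "too small",
               class = "relmeta_validation_error")
  sp <- power_spectrum(matrix(rnorm(32 * 48), 32, 48), 1)
  expect_identical(dim(sp), c(32L, 32L))
})

test_that("radial average matches the brute-force grouping oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(c(32L, 48L, 64L), 1)
    sp <- matrix(runif(n * n), n, n)
    got <- radial_average(sp, pixel_size = 2)
    ora <- oracle_radial_average(sp, pixel_size = 2)
    expect_identical(got$frequencies, ora$frequencies)
    expect_identical(got$values, ora$values)
  }
  # radially constant spectrum: all-c profile
  p <- radial_average(matrix(7, 32, 32), 1)
  expect_true(all(p$values == 7))
  # frequency axis of a 64x64 spectrum at 1 A/px: step 1/64 up to 0.5
  p <- radial_average(matrix(1, 64, 64), 1)
  expect_equal(p$frequencies, (1:32) / 64)
  expect_error(radial_average(matrix(1, 32, 48), 1), "square",
               class = "relmeta_validation_error")
})

test_that("band mean averages exactly the in-band samples", {
  freq <- (1:50) / 100           # 0.01 .. 0.5
  prof <- radial_profile(freq, as.numeric(1:50))
  band <- ice_band()             # 0.25 .. 1/3.6
  # index-scan oracle
  idx <- which(freq >= band$f_lo & freq <= band$f_hi)
  expect_identical(band_mean(prof, band), mean(as.numeric(idx)))
  # invariant to out-of-band samples
  prof2 <- radial_profile(freq, c(rep(-99, min(idx) - 1), as.numeric(idx),
                                  rep(99, 50 - max(idx))))
  expect_identical(band_mean(prof2, band), band_mean(prof, band))
  # constant 2.0 across the band
  expect_equal(band_mean(radial_profile(freq, rep(2, 50)), band), 2)
  # default edges are 1/4 and 1/3.6
  expect_equal(band$f_lo, 0.25)
  expect_equal(band$f_hi, 1 / 3.6)
  # band edges are inclusive on both sides
  p_edges <- radial_profile(c(band$f_lo, band$f_hi), c(10, 20))
  expect_equal(band_mean(p_edges, band), 15)
  # Nyquist below the band: coarse pixels cannot see the ice ring
  coarse <- radial_profile((1:10) / 100, rep(1, 10))
  expect_error(band_mean(coarse, band), "2 Angstrom",
               class = "relmeta_band_error")
})

test_that("ctffind avrot files round trip and honor the signal row", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "mic_avrot.txt")
  freq <- seq(0, 0.5, by = 0.05)
  rows <- lapply(1:5, function(k) k * seq_along(freq) / 10)
  written <- make_ctffind_profile(f, freq, rows)
  # row 3 (background-subtracted) is the default signal
  prof <- read_ctffind_radial_profile(f)
  expect_identical(prof$frequencies, written[[1]][-1])
  expect_identical(prof$values, written[[3]][-1])
  # any other row selectable by index
  prof5 <- read_ctffind_radial_profile(f, signal_row = 5L)
  expect_identical(prof5$values, written[[5]][-1])

  writeLines(c("# only", "# comments"), f)
  expect_error(read_ctffind_radial_profile(f), "2 numeric rows",
               class = "relmeta_format_error")
  writeLines(c("0 0.1 0.2", "1 2"), f)
  expect_error(read_ctffind_radial_profile(f), "unequal",
               class = "relmeta_format_error")
  expect_error(make_ctffind_profile(f, freq, list(1:3)),
               "do not match", class = "relmeta_validation_error")
})

test_that("ice score rises with planted ring amplitude and scales as k^2", {
  scores <- vapply(c(0, 1, 4), function(a) {
    ice_score(make_micrograph(64, 1, seed = 9, ring_amplitude = a)$pixels, 1)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  # unnormalized score is homogeneous of degree 2 in image intensity
  img <- make_micrograph(64, 1, seed = 9, ring_amplitude = 1)$pixels
  s1 <- ice_score(img, 1, normalize = FALSE)
  s3 <- ice_score(3 * img, 1, normalize = FALSE)
  expect_equal(s3, 9 * s1)
  # normalized score is invariant to intensity
  expect_equal(ice_score(3 * img, 1), ice_score(img, 1))
})

test_that("score_micrographs appends the ice column for both sources", {
  proj <- local_project(fixture_spec(seed = 21, n_micrographs = 4,
                                     image_size = 64))
  tab <- get_table(read_star(file.path(proj$root,
                                       "CtfFind/job003/micrographs_ctf.star")))
  nat <- score_micrographs(tab, "native", root = proj$root)
  expect_identical(names(nat)[ncol(nat)], "rlnMicrographIceThickness")
  expect_identical(nrow(nat), nrow(tab))
  prof <- score_micrographs(tab, "ctffind-profile", root = proj$root)
  expect_true(all(is.finite(prof$rlnMicrographIceThickness)))
  # the two routes rank micrographs the same way
  expect_equal(order(nat$rlnMicrographIceThickness),
               order(prof$rlnMicrographIceThickness))

  # empty table: unchanged, plus the empty new column
  empty <- tab[0, , drop = FALSE]
  out <- score_micrographs(empty, "native", root = proj$root)
  expect_identical(nrow(out), 0L)
  expect_true("rlnMicrographIceThickness" %in% names(out))

  # unreadable file: abort by default, sentinel + warning when skipping
  tab$rlnCtfPowerSpectrum[2] <- "missing/file.txt"
  expect_error(score_micrographs(tab, "ctffind-profile", root = proj$root))
  expect_warning(
    skipped <- score_micrographs(tab, "ctffind-profile", root = proj$root,
                                 on_error = "skip"),
    "could not be scored")
  expect_true(is.nan(skipped$rlnMicrographIceThickness[2]))
  expect_false(anyNA(skipped$rlnMicrographIceThickness[-2]))
})
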