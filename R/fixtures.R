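# Deterministic synthetic-project generator.
#
# Every generator is a pure function of its arguments: the RNG is seeded
# locally and restored, so identical specs yield byte-identical files.
# Planted numeric values are snapped to the STAR writer's 6-decimal
# serialization precision *before* being returned, so what a reader
# recovers after one round trip compares bit-exactly with what the
# generator reports having planted.

snap <- function(x) as.numeric(format_real(x))

#' Synthetic micrograph with a controllable ice ring
#'
#' White Gaussian noise plus an isotropic oscillatory component
#' concentrated at the spatial frequency `1/ring_center`: the Fourier
#' transform of the noise field is scaled by `1 + amplitude * annulus(f)`,
#' where `annulus` is a Gaussian ring of width `ring_width` (1/Angstrom)
#' centered on `1/ring_center`. This emulates the spectral intensity
#' maximum that vitreous and crystalline ice produce near 3.6-4 Angstrom;
#' band power is strictly increasing in `amplitude`, and amplitude 0 gives
#' the untouched noise field.
#'
#' @param size image side in pixels.
#' @param pixel_size Angstrom per pixel.
#' @param seed RNG seed.
#' @param ring_amplitude ring strength, >= 0.
#' @param ring_center ring position in Angstrom (default 3.8, inside the
#'   3.6-4.0 ice band); must lie below Nyquist, i.e. exceed
#'   `2 * pixel_size`.
#' @param ring_width Gaussian annulus sigma in 1/Angstrom.
#' @return an `image2d`.
#' @export
make_micrograph <- function(size = 128L, pixel_size = 1.0, seed = 1L,
                            ring_amplitude = 0, ring_center = 3.8,
                            ring_width = 0.01) {
  stopifnot(size >= 16L, pixel_size > 0, ring_amplitude >= 0)
  if (ring_center <= 2 * pixel_size) {
    relmeta_stop(
      "ring at %g Angstrom is beyond Nyquist for pixel size %g (need > %g)",
      ring_center, pixel_size, 2 * pixel_size,
      class = "relmeta_validation_error")
  }
  noise <- with_seed(seed, matrix(stats::rnorm(size * size), size, size))
  if (ring_amplitude > 0) {
    k <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1))
    f <- sqrt(outer(k^2, k^2, `+`)) / (size * pixel_size)
    mask <- exp(-(f - 1 / ring_center)^2 / (2 * ring_width^2))
    g <- stats::fft(noise) * (1 + ring_amplitude * mask)
    noise <- Re(stats::fft(g, inverse = TRUE)) / (size * size)
  }
  structure(list(pixels = noise, pixel_size = pixel_size),
            class = "image2d")
}

#' Write a CTFFIND4-style avrot profile file
#'
#' Emits the six-row plain-text layout (comments, then spatial frequency,
#' raw rotational average, background-subtracted rotational average,
#' fitted CTF, fit correlation, significance threshold) that
#' [read_ctffind_radial_profile()] parses. Rows are serialized at
#' 6-decimal precision; the rows actually written (post-rounding) are
#' returned invisibly.
#'
#' @param path output path.
#' @param frequencies spatial-frequency row (1/Angstrom).
#' @param signal_rows list (or matrix, one row each) of the remaining
#'   rows, each the same length as `frequencies`.
#' @return invisibly, the list of written rows (frequency first).
#' @export
make_ctffind_profile <- function(path, frequencies, signal_rows) {
  if (is.matrix(signal_rows)) {
    signal_rows <- lapply(seq_len(nrow(signal_rows)),
                          function(i) signal_rows[i, ])
  }
  lens <- vapply(signal_rows, length, integer(1))
  if (any(lens != length(frequencies))) {
    relmeta_stop("signal rows (%s) do not match frequency row length %d",
                 paste(lens, collapse = ", "), length(frequencies),
                 class = "relmeta_validation_error")
  }
  rows <- c(list(frequencies), signal_rows)
  out <- c("# Output radial profile (synthetic)",
           "# 1 - spatial frequency (1/Angstroms); 2 - 1D rotational average",
           "# 3 - background-subtracted average; 4 - CTF fit;",
           "# 5 - cross-correlation; 6 - 2sigma threshold",
           vapply(rows, function(r) paste(format_real(r), collapse = " "),
                  character(1)))
  writeLines(out, path)
  invisible(lapply(rows, snap))
}

#' Synthetic particle table with optics groups
#'
#' Particle orientations for preferential-orientation fixtures: rotation
#' uniform in `[-180, 180]`, tilt normal around each optics group's center
#' (truncated to `[0, 180]`), emulating data sets collected at different
#' stage tilts and merged.
#'
#' @param n number of particles.
#' @param optics_groups list of groups, each
#'   `list(fraction =, tilt_center =, spread =)`; fractions must sum to 1.
#' @param seed RNG seed.
#' @return particle loop table with `rlnAngleRot`, `rlnAngleTilt`,
#'   `rlnOpticsGroup`.
#' @export
make_particles <- function(n,
                           optics_groups = list(
                             list(fraction = 1, tilt_center = 90,
                                  spread = 30)),
                           seed = 1L) {
  fr <- vapply(optics_groups, function(g) g$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9 || any(fr < 0)) {
    relmeta_stop("optics group fractions must be nonnegative and sum to 1",
                 class = "relmeta_validation_error")
  }
  counts <- floor(fr * n)
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  with_seed(seed, {
    rot <- numeric(0); tilt <- numeric(0); grp <- integer(0)
    for (g in seq_along(optics_groups)) {
      ng <- counts[g]
      if (ng == 0L) next
      ti <- stats::rnorm(ng, optics_groups[[g]]$tilt_center,
                         optics_groups[[g]]$spread)
      # truncate by resampling so the group mean stays near its center
      bad <- which(ti < 0 | ti > 180)
      while (length(bad)) {
        ti[bad] <- stats::rnorm(length(bad),
                                optics_groups[[g]]$tilt_center,
                                optics_groups[[g]]$spread)
        bad <- which(ti < 0 | ti > 180)
      }
      rot <- c(rot, stats::runif(ng, -180, 180))
      tilt <- c(tilt, ti)
      grp <- c(grp, rep(g, ng))
    }
    data.frame(rlnAngleRot = snap(rot), rlnAngleTilt = snap(tilt),
               rlnOpticsGroup = as.integer(grp),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
}

#' Specification of a synthetic RELION project
#'
#' Bundles the knobs of [make_project()]. Defaults describe a small but
#' complete pre-processing session: 10 micrographs of 128 x 128 pixels at
#' 1 Angstrom per pixel, ice-ring amplitudes drawn uniformly from
#' `[0, 2]` with the ring at 3.8 Angstrom.
#'
#' @param seed master RNG seed; every derived file is a pure function of
#'   it.
#' @param n_micrographs number of movies imported.
#' @param n_corrected number that have completed motion correction + CTF
#'   (defaults to all; lower it to emulate a live session with backlog).
#' @param image_size,pixel_size micrograph geometry.
#' @param ring_amplitudes per-micrograph ring strengths (`NULL` = drawn
#'   from the seed).
#' @param ring_center ice ring position in Angstrom.
#' @param run_plan optional classification/refinement run:
#'   `list(kind = "class2d"|"class3d"|"refine3d", n_classes =, n_iter =)`.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_micrographs = 10L,
                         n_corrected = n_micrographs,
                         image_size = 128L, pixel_size = 1.0,
                         ring_amplitudes = NULL, ring_center = 3.8,
                         run_plan = NULL) {
  stopifnot(n_corrected <= n_micrographs)
  if (is.null(ring_amplitudes)) {
    ring_amplitudes <- with_seed(seed + 1000L,
                                 stats::runif(n_micrographs, 0, 2))
  }
  stopifnot(length(ring_amplitudes) == n_micrographs)
  structure(list(seed = as.integer(seed),
                 n_micrographs = as.integer(n_micrographs),
                 n_corrected = as.integer(n_corrected),
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size,
                 ring_amplitudes = ring_amplitudes,
                 ring_center = ring_center,
                 run_plan = run_plan),
            class = "fixture_spec")
}

write_job_star <- function(job_dir, type, params) {
  doc <- star_document(list(
    star_block("job", pairs = list(rlnJobTypeLabel = type,
                                   rlnJobIsContinue = 0L)),
    star_block("joboptions_values", table = data.frame(
      rlnJobOptionVariable = names(params),
      rlnJobOptionValue = unname(params),
      check.names = FALSE, stringsAsFactors = FALSE))))
  write_star(doc, file.path(job_dir, "job.star"))
}

# Planted per-iteration values for a classification/refinement run;
# everything snapped to serialization precision.
plan_run_values <- function(plan, seed, pixel_size) {
  k <- plan$n_classes
  n_iter <- plan$n_iter
  refine <- identical(plan$kind, "refine3d")
  with_seed(seed + 2000L, {
    it <- 0:(n_iter - 1L)
    changes <- snap(0.9 * exp(-0.6 * it) *
                      (1 + 0.05 * stats::runif(n_iter)))
    res <- snap(4 + 16 * exp(-0.5 * it) * (1 + 0.03 * stats::runif(n_iter)))
    final <- stats::runif(k, 0.5, 1.5)
    final <- final / sum(final)
    start <- rep(1 / k, k)
    fractions <- matrix(0, n_iter, k)
    for (i in seq_len(n_iter)) {
      w <- (i - 1) / max(1, n_iter - 1)
      row <- (1 - w) * start + w * final
      row <- snap(row)
      row[k] <- snap(1 - sum(row[-k]))  # rows sum to 1 at 6 decimals
      fractions[i, ] <- row
    }
    n_shell <- 24L
    freq <- snap(seq_len(n_shell) / (2 * n_shell * pixel_size))
    spectra <- list()
    for (cls in seq_len(k)) {
      half <- stats::runif(1, 0.15, 0.35)
      fsc <- snap(1 / (1 + (freq / half)^4))
      ssnr <- snap(pmax(0, 30 * exp(-freq / half) *
                          (1 + 0.1 * stats::runif(n_shell))))
      complete <- snap(pmin(1, 1.05 - 0.3 * freq))
      orient <- snap(stats::runif(n_shell, 0, 1))
      spectra[[cls]] <- data.frame(freq = freq, fsc = fsc, ssnr = ssnr,
                                   complete = complete, orient = orient)
    }
    list(iterations = it, changes = changes, resolution = res,
         fractions = fractions, spectra = spectra, refine = refine,
         n_classes = k)
  })
}

write_run_files <- function(job_dir, vals) {
  k <- vals$n_classes
  for (i in seq_along(vals$iterations)) {
    it <- vals$iterations[i]
    opt_pairs <- list(
      rlnCurrentIteration = as.integer(it),
      rlnChangesOptimalClasses = vals$changes[i])
    if (vals$refine) opt_pairs$rlnCurrentResolution <- vals$resolution[i]
    write_star(star_document(list(
      star_block("optimiser_general", pairs = opt_pairs))),
      file.path(job_dir, sprintf("run_it%03d_optimiser.star", it)))
    blocks <- list(
      star_block("model_general", pairs = list(
        rlnNrClasses = as.integer(k),
        rlnCurrentResolution = vals$resolution[i])),
      star_block("model_classes", table = data.frame(
        rlnReferenceImage = sprintf("it%03d_class%03d.mrc", it, seq_len(k)),
        rlnClassDistribution = vals$fractions[i, ],
        check.names = FALSE, stringsAsFactors = FALSE)))
    for (cls in seq_len(k)) {
      sp <- vals$spectra[[cls]]
      blocks <- c(blocks, list(star_block(
        sprintf("model_class_%d", cls),
        table = data.frame(
          rlnSpectralIndex = seq_len(nrow(sp)) - 1L,
          rlnResolution = sp$freq,
          rlnGoldStandardFsc = sp$fsc,
          rlnSsnrMap = sp$ssnr,
          rlnFourierCompleteness = sp$complete,
          rlnSpectralOrientabilityContribution = sp$orient,
          check.names = FALSE, stringsAsFactors = FALSE))))
    }
    write_star(star_document(blocks),
               file.path(job_dir, sprintf("run_it%03d_model.star", it)))
  }
}

#' Materialize a miniature RELION project tree
#'
#' Writes a complete, internally consistent project under `root`:
#' `pipeline.star` with an Import -> MotionCorr -> CtfFind -> External
#' (ice scoring) chain, per-job `job.star` files, MRC micrographs with
#' planted ice-ring amplitudes, CTFFIND-style avrot profiles whose
#' background-subtracted row is the micrograph's actual normalized radial
#' average, micrograph metadata tables with planted values
#' (AccumMotionTotal, DefocusU/V, CtfAstigmatism, CtfMaxResolution,
#' CtfFigureOfMerit), and, when `spec$run_plan` is set, a
#' classification/refinement job with per-iteration
#' `run_itNNN_model/optimiser.star` files carrying planted convergence,
#' class-distribution and spectral values.
#'
#' @param spec a [fixture_spec()].
#' @param root target directory; must be empty or absent.
#' @return list with the planted ground truth: `root`, `spec`,
#'   `micrographs` (metadata table as written), `jobs`, `job_edges`, and
#'   `run` (planted run values, when a run plan was given; its job
#'   directory in `run$job_dir`).
#' @export
make_project <- function(spec, root) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE))) {
    relmeta_stop("refusing to write fixture project into non-empty %s",
                 root, class = "relmeta_validation_error")
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  n <- spec$n_micrographs
  nc <- spec$n_corrected
  jobs <- c("Import/job001/", "MotionCorr/job002/", "CtfFind/job003/",
            "External/job004/")
  types <- c("relion.import.movies", "relion.motioncorr.own",
             "relion.ctffind.ctffind4", "relion.external")
  for (j in jobs) dir.create(file.path(root, j), recursive = TRUE)
  dir.create(file.path(root, "MotionCorr/job002/Movies"), recursive = TRUE)
  dir.create(file.path(root, "CtfFind/job003/Movies"), recursive = TRUE)

  mic_ids <- sprintf("mic_%03d", seq_len(n))
  movie_names <- sprintf("Movies/%s.tiff", mic_ids)
  mrc_rel <- sprintf("MotionCorr/job002/Movies/%s.mrc", mic_ids)
  avrot_rel <- sprintf("CtfFind/job003/Movies/%s_avrot.txt", mic_ids)

  meta <- with_seed(spec$seed + 3000L, data.frame(
    rlnMicrographName = mrc_rel,
    rlnCtfPowerSpectrum = avrot_rel,
    rlnAccumMotionTotal = snap(stats::rgamma(n, shape = 4, scale = 8)),
    rlnDefocusU = snap(stats::runif(n, 8000, 25000)),
    rlnDefocusV = NA_real_,
    rlnCtfAstigmatism = snap(stats::runif(n, 50, 600)),
    rlnCtfMaxResolution = snap(stats::runif(n, 2.8, 7.5)),
    rlnCtfFigureOfMerit = snap(stats::runif(n, 0.05, 0.3)),
    check.names = FALSE, stringsAsFactors = FALSE))
  meta$rlnDefocusV <- snap(meta$rlnDefocusU + meta$rlnCtfAstigmatism)

  # Import: all movies
  write_job_star(file.path(root, jobs[1]), types[1],
                 c(fn_in_raw = "Movies/*.tiff", kV = "300",
                   Cs = "2.7", angpix = format_real(spec$pixel_size)))
  write_star(star_document(list(star_block("movies", table = data.frame(
    rlnMicrographMovieName = movie_names,
    check.names = FALSE, stringsAsFactors = FALSE)))),
    file.path(root, "Import/job001/movies.star"))

  # MotionCorr + CtfFind outputs cover the first n_corrected micrographs
  done <- seq_len(nc)
  for (i in done) {
    img <- make_micrograph(spec$image_size, spec$pixel_size,
                           seed = spec$seed + 100L + i,
                           ring_amplitude = spec$ring_amplitudes[i],
                           ring_center = spec$ring_center)
    write_mrc(img$pixels, file.path(root, mrc_rel[i]), spec$pixel_size)
    prof <- radial_average(local({
      sp <- power_spectrum(img$pixels, spec$pixel_size)
      ctr <- nrow(sp) %/% 2L + 1L
      sp / (sum(sp) - sp[ctr, ctr])
    }), spec$pixel_size)
    freq <- c(0, prof$frequencies)
    raw <- c(prof$values[1], prof$values)
    make_ctffind_profile(
      file.path(root, avrot_rel[i]), freq,
      list(raw * 2,                      # raw rotational average
           raw,                          # background-subtracted average
           abs(sin(freq * 40))^2,        # fitted CTF
           pmax(0, 1 - 2 * freq),        # fit correlation
           rep(0.05, length(freq))))     # significance threshold
  }
  write_job_star(file.path(root, jobs[2]), types[2],
                 c(fn_in = "Import/job001/movies.star", bin_factor = "1",
                   dose_per_frame = "1.2", do_dose_weighting = "Yes"))
  mc_tab <- meta[done, c("rlnMicrographName", "rlnAccumMotionTotal")]
  write_star(star_document(list(star_block("micrographs", table = mc_tab))),
             file.path(root, "MotionCorr/job002/corrected_micrographs.star"))

  write_job_star(file.path(root, jobs[3]), types[3],
                 c(fn_input = "MotionCorr/job002/corrected_micrographs.star",
                   box = "512", dfmin = "5000", dfmax = "50000",
                   use_given_ps = "No"))
  ctf_tab <- meta[done, , drop = FALSE]
  rownames(ctf_tab) <- NULL
  write_star(star_document(list(star_block("micrographs", table = ctf_tab))),
             file.path(root, "CtfFind/job003/micrographs_ctf.star"))

  # External ice-scoring job: band mean of the avrot profiles
  write_job_star(file.path(root, jobs[4]), types[4],
                 c(fn_exe = "ice-score",
                   in_mics = "CtfFind/job003/micrographs_ctf.star"))
  ice_tab <- score_micrographs(ctf_tab, source = "ctffind-profile",
                               root = root)
  ice_tab$rlnMicrographIceThickness <-
    snap(ice_tab$rlnMicrographIceThickness)
  write_star(star_document(list(star_block("micrographs",
                                           table = ice_tab))),
             file.path(root, "External/job004/micrographs_ice.star"))

  out_nodes <- c("Import/job001/movies.star",
                 "MotionCorr/job002/corrected_micrographs.star",
                 "CtfFind/job003/micrographs_ctf.star",
                 "External/job004/micrographs_ice.star")
  run <- NULL
  if (!is.null(spec$run_plan)) {
    plan <- spec$run_plan
    run_job <- switch(plan$kind,
                      class2d = "Class2D/job005/",
                      class3d = "Class3D/job005/",
                      refine3d = "Refine3D/job005/",
                      relmeta_stop("unknown run kind '%s'", plan$kind))
    run_type <- switch(plan$kind, class2d = "relion.class2d",
                       class3d = "relion.class3d",
                       refine3d = "relion.refine3d")
    dir.create(file.path(root, run_job), recursive = TRUE)
    write_job_star(file.path(root, run_job), run_type,
                   c(fn_img = "External/job004/micrographs_ice.star",
                     nr_classes = as.character(plan$n_classes),
                     nr_iter = as.character(plan$n_iter)))
    vals <- plan_run_values(plan, spec$seed, spec$pixel_size)
    write_run_files(file.path(root, run_job), vals)
    jobs <- c(jobs, run_job)
    types <- c(types, run_type)
    run_out <- sprintf("%srun_it%03d_model.star", run_job,
                       max(vals$iterations))
    out_nodes <- c(out_nodes, run_out)
    run <- c(vals, list(job_dir = file.path(root, run_job),
                        job_name = run_job))
  }

  # pipeline.star: each job outputs its node; job i+1 consumes node i
  n_jobs <- length(jobs)
  procs <- data.frame(
    rlnPipeLineProcessName = jobs,
    rlnPipeLineProcessAlias = rep("None", n_jobs),
    rlnPipeLineProcessTypeLabel = types,
    rlnPipeLineProcessStatusLabel = c(rep("Succeeded", n_jobs - 1),
                                      "Running"),
    check.names = FALSE, stringsAsFactors = FALSE)
  nodes <- data.frame(rlnPipeLineNodeName = out_nodes,
                      rlnPipeLineNodeTypeLabel = "MicrographsData.star.relion",
                      check.names = FALSE, stringsAsFactors = FALSE)
  oe <- data.frame(rlnPipeLineEdgeProcess = jobs,
                   rlnPipeLineEdgeToNode = out_nodes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ie <- data.frame(rlnPipeLineEdgeFromNode = out_nodes[-n_jobs],
                   rlnPipeLineEdgeProcess = jobs[-1],
                   check.names = FALSE, stringsAsFactors = FALSE)
  pipeline <- star_document(list(
    star_block("pipeline_general",
               pairs = list(rlnPipeLineJobCounter = n_jobs + 1L)),
    star_block("pipeline_processes", table = procs),
    star_block("pipeline_nodes", table = nodes),
    star_block("pipeline_input_edges", table = ie),
    star_block("pipeline_output_edges", table = oe)))
  write_star(pipeline, file.path(root, "pipeline.star"))

  planted_edges <- data.frame(from = jobs[-n_jobs], to = jobs[-1],
                              stringsAsFactors = FALSE)
  list(root = root, spec = spec, micrographs = ctf_tab,
       ice = ice_tab, jobs = jobs, job_edges = planted_edges, run = run)
}

#' Random STAR document generator
#'
#' Draws a document of 1-4 blocks mixing simple pairs and loop tables with
#' integer, real and text columns; all reals are pre-snapped to the
#' writer's serialization precision, so
#' `parse_star(write_star(d))` recovers the document exactly. Used for
#' round-trip property testing.
#'
#' @param seed RNG seed.
#' @return a `star_document`.
#' @export
make_random_star_document <- function(seed = 1L) {
  words <- c("mic_001.mrc", "Movies/stack.tiff", "Yes", "No", "ctf_fit",
             "job005", "d2_symmetry", "path/with/slashes.star",
             "quoted value", "K3-detector")
  with_seed(seed, {
    n_blocks <- sample(1:4, 1)
    blocks <- list()
    for (b in seq_len(n_blocks)) {
      name <- sprintf("block_%s_%d", paste(sample(letters, 4), collapse = ""),
                      b)
      pairs <- list()
      for (p in seq_len(sample(0:4, 1))) {
        lab <- sprintf("rlnPair%s%d", paste(sample(LETTERS, 3),
                                            collapse = ""), p)
        pairs[[lab]] <- switch(sample(3, 1),
                               sample.int(1000, 1),
                               snap(stats::runif(1, -1000, 1000)),
                               sample(words, 1))
      }
      tab <- NULL
      if (stats::runif(1) < 0.8) {
        n_cols <- sample(1:5, 1)
        n_rows <- sample(1:8, 1)
        cols <- list()
        for (cc in seq_len(n_cols)) {
          lab <- sprintf("rlnCol%s%d", paste(sample(LETTERS, 3),
                                             collapse = ""), cc)
          cols[[lab]] <- switch(
            sample(3, 1),
            sample.int(10000, n_rows, replace = TRUE),
            snap(stats::runif(n_rows, -100, 100)),
            sample(words, n_rows, replace = TRUE))
        }
        tab <- data.frame(cols, check.names = FALSE,
                          stringsAsFactors = FALSE)
      }
      if (is.null(tab) && !length(pairs)) {
        pairs <- list(rlnLonePair = 1L)
      }
      blocks[[b]] <- star_block(name, pairs, tab)
    }
    star_document(blocks)
  })
}

#' Random planted pipeline DAG
#'
#' Draws a random job DAG, serializes it in pipeline.star form and
#' returns both the document and the planted truth, for topology-recovery
#' property tests.
#'
#' @param seed RNG seed.
#' @param n_jobs number of jobs.
#' @param edge_prob probability that job `j` consumes the output of any
#'   given earlier job `i`.
#' @return list with `doc` (a `star_document`), `jobs` (character) and
#'   `edges` (`data.frame(from, to)` sorted by producer then consumer).
#' @export
make_random_pipeline <- function(seed = 1L, n_jobs = 6L, edge_prob = 0.4) {
  with_seed(seed, {
    types <- c("Import", "MotionCorr", "CtfFind", "External", "Select",
               "Class2D", "Class3D", "Refine3D")
    jobs <- sprintf("%s/job%03d/",
                    sample(types, n_jobs, replace = TRUE), seq_len(n_jobs))
    out_nodes <- sprintf("%sout.star", jobs)
    from <- character(0); to <- character(0)
    for (j in seq_len(n_jobs)[-1]) {
      parents <- which(stats::runif(j - 1) < edge_prob)
      from <- c(from, jobs[parents])
      to <- c(to, rep(jobs[j], length(parents)))
    }
    edges <- unique(data.frame(from = from, to = to,
                               stringsAsFactors = FALSE))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    oe <- data.frame(rlnPipeLineEdgeProcess = jobs,
                     rlnPipeLineEdgeToNode = out_nodes,
                     check.names = FALSE, stringsAsFactors = FALSE)
    ie <- data.frame(
      rlnPipeLineEdgeFromNode = out_nodes[match(edges$from, jobs)],
      rlnPipeLineEdgeProcess = edges$to,
      check.names = FALSE, stringsAsFactors = FALSE)
    doc <- star_document(list(
      star_block("pipeline_processes", table = data.frame(
        rlnPipeLineProcessName = jobs,
        rlnPipeLineProcessAlias = "None",
        rlnPipeLineProcessTypeLabel = sub("/.*", "", jobs),
        rlnPipeLineProcessStatusLabel = "Succeeded",
        check.names = FALSE, stringsAsFactors = FALSE)),
      star_block("pipeline_nodes", table = data.frame(
        rlnPipeLineNodeName = out_nodes,
        rlnPipeLineNodeTypeLabel = "out",
        check.names = FALSE, stringsAsFactors = FALSE)),
      star_block("pipeline_input_edges", table = ie),
      star_block("pipeline_output_edges", table = oe)))
    list(doc = doc, jobs = jobs, edges = edges)
  })
}
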