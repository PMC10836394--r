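# Per-iteration tracking of classification and refinement jobs.
#
# RELION writes a run_itNNN_optimiser.star / run_itNNN_model.star pair at
# the end of every expectation-maximization cycle, so a running job can be
# followed live by re-scanning its directory (polling; no filesystem-event
# subscription, to keep the contract portable).

model_dialect <- list(
  optimiser_block = "optimiser_general",
  model_block = "model_general",
  classes_block = "model_classes",
  class_block_prefix = "model_class_",
  class_distribution = "rlnClassDistribution",
  resolution = "rlnResolution"
)

#' Discover the iterations of a classification/refinement job
#'
#' Scans `job_dir` for `run_itNNN_model.star` / `run_itNNN_optimiser.star`
#' pairs, sorted by iteration number. Iterations with one file of the pair
#' missing are skipped with a warning.
#'
#' @param job_dir job directory.
#' @return `data.frame` with columns `iteration`, `model`, `optimiser`
#'   (absolute paths); zero rows for an empty or missing directory.
#' @export
discover_iterations <- function(job_dir) {
  empty <- data.frame(iteration = integer(0), model = character(0),
                      optimiser = character(0), stringsAsFactors = FALSE)
  if (!dir.exists(job_dir)) return(empty)
  files <- list.files(job_dir, pattern = "^run_it[0-9]{3}_(model|optimiser)\\.star$")
  if (!length(files)) return(empty)
  it <- as.integer(sub("^run_it([0-9]{3})_.*$", "\\1", files))
  kind <- sub("^run_it[0-9]{3}_(model|optimiser)\\.star$", "\\1", files)
  its <- sort(unique(it))
  keep <- logical(length(its))
  for (k in seq_along(its)) {
    have <- kind[it == its[k]]
    keep[k] <- all(c("model", "optimiser") %in% have)
  }
  if (any(!keep)) {
    warning(sprintf("iteration(s) %s incomplete in %s; skipped",
                    paste(its[!keep], collapse = ", "), job_dir),
            call. = FALSE)
  }
  its <- its[keep]
  data.frame(
    iteration = its,
    model = file.path(job_dir, sprintf("run_it%03d_model.star", its)),
    optimiser = file.path(job_dir, sprintf("run_it%03d_optimiser.star", its)),
    stringsAsFactors = FALSE)
}

# Look a label up in the simple pairs of a document's blocks.
find_pair <- function(doc, label) {
  for (b in doc$blocks) {
    if (!length(b$pairs)) next
    for (cand in label_candidates(label)) {
      if (cand %in% names(b$pairs)) return(b$pairs[[cand]])
    }
  }
  NULL
}

#' Extract a per-iteration convergence series
#'
#' Returns the value of `label` at every discovered iteration, searched
#' first in the optimiser file's pairs, then in the model file's. The
#' conventional convergence variables are `ChangesOptimalClasses` for 2D/3D
#' classification and `CurrentResolution` for 3D refinement, but any label
#' present in those files can be tracked.
#'
#' @param job_dir job directory.
#' @param label metadata label (with or without `rln` prefix).
#' @return an `iteration_series`: list with `iterations` (integer),
#'   `values` (numeric) and `label`.
#' @export
extract_series <- function(job_dir, label) {
  iters <- discover_iterations(job_dir)
  vals <- numeric(0)
  avail <- character(0)
  for (i in seq_len(nrow(iters))) {
    opt <- read_star(iters$optimiser[i])
    mod <- read_star(iters$model[i])
    v <- find_pair(opt, label)
    if (is.null(v)) v <- find_pair(mod, label)
    if (is.null(v)) {
      avail <- unique(c(avail, unlist(lapply(c(opt$blocks, mod$blocks),
                                             function(b) names(b$pairs)))))
      relmeta_stop(
        "label '%s' not found at iteration %d; available labels: %s",
        label, iters$iteration[i], paste(avail, collapse = ", "),
        class = "relmeta_lookup_error")
    }
    vals <- c(vals, as.numeric(v))
  }
  structure(list(iterations = iters$iteration, values = vals,
                 label = label),
            class = "iteration_series")
}

#' Per-iteration class distribution matrix
#'
#' Fraction of particles assigned to each class at each iteration, read
#' from the model files' per-class table. Rows (iterations) sum to one.
#'
#' @param job_dir job directory.
#' @return a `class_distribution_matrix`: list with `iterations`,
#'   `classes` (integer ids) and `fractions` (iterations x classes
#'   matrix).
#' @export
class_distribution <- function(job_dir) {
  iters <- discover_iterations(job_dir)
  if (!nrow(iters)) {
    relmeta_stop("no iterations found in %s", job_dir,
                 class = "relmeta_lookup_error")
  }
  d <- model_dialect
  rows <- list()
  k_seen <- NULL
  for (i in seq_len(nrow(iters))) {
    tab <- get_table(read_star(iters$model[i]), d$classes_block)
    lab <- resolve_label(names(tab), d$class_distribution, "model classes")
    fr <- as.numeric(tab[[lab]])
    if (is.null(k_seen)) {
      k_seen <- length(fr)
    } else if (length(fr) != k_seen) {
      relmeta_stop(
        "class count changes across iterations (%d then %d at it%03d)",
        k_seen, length(fr), iters$iteration[i],
        class = "relmeta_structure_error")
    }
    rows[[i]] <- fr
  }
  fractions <- do.call(rbind, rows)
  structure(list(iterations = iters$iteration,
                 classes = seq_len(k_seen),
                 fractions = fractions),
            class = "class_distribution_matrix")
}

#' Per-class spectral curves from a model file
#'
#' Extracts, for every class block (`data_model_class_K`) of a model file,
#' the `(resolution, value)` curve of one spectral label such as
#' `GoldStandardFsc`, `SpectralOrientabilityContribution`,
#' `FourierCompleteness` or `SsnrMap`. The resolution axis is spatial
#' frequency in 1/Angstrom.
#'
#' @param model_path path to a `run_itNNN_model.star`.
#' @param label spectral label.
#' @return named list, one `data.frame(resolution, value)` per class.
#' @export
model_spectra <- function(model_path, label) {
  doc <- read_star(model_path)
  d <- model_dialect
  blocks <- names(doc$blocks)
  class_blocks <- blocks[startsWith(blocks, d$class_block_prefix)]
  if (!length(class_blocks)) {
    relmeta_stop("model file %s has no per-class spectral tables",
                 model_path, class = "relmeta_lookup_error")
  }
  ord <- order(as.integer(sub(d$class_block_prefix, "", class_blocks,
                              fixed = TRUE)))
  class_blocks <- class_blocks[ord]
  out <- list()
  for (cb in class_blocks) {
    tab <- get_table(doc, cb)
    if (!nrow(tab)) {
      relmeta_stop("model file %s: class table data_%s is empty",
                   model_path, cb, class = "relmeta_structure_error")
    }
    rl <- resolve_label(names(tab), d$resolution, paste0("data_", cb))
    vl <- resolve_label(names(tab), label, paste0("data_", cb))
    out[[cb]] <- data.frame(resolution = as.numeric(tab[[rl]]),
                            value = as.numeric(tab[[vl]]))
  }
  out
}

#' Resolution at an FSC threshold crossing
#'
#' Linearly interpolates the first downward crossing of the Fourier shell
#' correlation through `threshold` and returns the corresponding
#' resolution `1 / f_cross` in Angstrom. The default threshold 0.143 is
#' the gold-standard criterion for FSC between independently refined
#' half-maps. When the curve never drops to the threshold, the Nyquist
#' resolution `1 / f_max` is returned with `at_nyquist = TRUE`.
#'
#' @param curve `data.frame` (or list) with strictly increasing
#'   `frequency` (1/Angstrom) and `fsc` columns; `fsc[1]` must exceed the
#'   threshold.
#' @param threshold FSC threshold.
#' @return list with `resolution` (Angstrom), `frequency` (1/Angstrom)
#'   and `at_nyquist` (logical).
#' @export
fsc_crossing <- function(curve, threshold = 0.143) {
  f <- as.numeric(curve$frequency)
  s <- as.numeric(curve$fsc)
  stopifnot(length(f) == length(s), length(f) >= 2L)
  if (any(diff(f) <= 0)) {
    relmeta_stop("FSC frequency axis must be strictly increasing",
                 class = "relmeta_validation_error")
  }
  if (s[1] <= threshold) {
    relmeta_stop("FSC starts at %g, already at or below threshold %g",
                 s[1], threshold, class = "relmeta_validation_error")
  }
  below <- which(s <= threshold)
  if (!length(below)) {
    return(list(resolution = 1 / f[length(f)], frequency = f[length(f)],
                at_nyquist = TRUE))
  }
  i <- below[1]
  if (s[i] == threshold) {
    fc <- f[i]
  } else {
    fc <- f[i - 1] + (s[i - 1] - threshold) / (s[i - 1] - s[i]) *
      (f[i] - f[i - 1])
  }
  list(resolution = 1 / fc, frequency = fc, at_nyquist = FALSE)
}

#' 2D histogram of particle angular assignments
#'
#' Bins particle Euler angles (rotation in `[-180, 180]`, tilt in
#' `[0, 180]` degrees) over a regular grid; the heatmap of these counts
#' reveals preferential orientation. Values on a right/top bin edge fall
#' in the last bin, so the total count is conserved. The 5-degree default
#' (72 x 36 bins) matches typical orientation plots.
#'
#' @param particles particle loop table with `AngleRot` / `AngleTilt`
#'   columns.
#' @param n_rot_bins,n_tilt_bins bin counts.
#' @return an `angular_histogram`: list with `rot_edges`, `tilt_edges`
#'   and `counts` (`n_rot_bins` x `n_tilt_bins` integer matrix).
#' @export
angular_histogram <- function(particles, n_rot_bins = 72L,
                              n_tilt_bins = 36L) {
  rl <- resolve_label(names(particles), "rlnAngleRot", "particle table")
  tl <- resolve_label(names(particles), "rlnAngleTilt", "particle table")
  rot <- as.numeric(particles[[rl]])
  tilt <- as.numeric(particles[[tl]])
  bad <- which(rot < -180 | rot > 180 | tilt < 0 | tilt > 180 |
                 !is.finite(rot) | !is.finite(tilt))
  if (length(bad)) {
    relmeta_stop("angles out of range at row(s): %s",
                 paste(utils::head(bad, 20), collapse = ", "),
                 class = "relmeta_validation_error")
  }
  rot_edges <- seq(-180, 180, length.out = n_rot_bins + 1L)
  tilt_edges <- seq(0, 180, length.out = n_tilt_bins + 1L)
  ri <- pmin(n_rot_bins, floor((rot + 180) / 360 * n_rot_bins) + 1L)
  ti <- pmin(n_tilt_bins, floor(tilt / 180 * n_tilt_bins) + 1L)
  counts <- matrix(0L, n_rot_bins, n_tilt_bins)
  for (k in seq_along(ri)) {
    counts[ri[k], ti[k]] <- counts[ri[k], ti[k]] + 1L
  }
  structure(list(rot_edges = rot_edges, tilt_edges = tilt_edges,
                 counts = counts),
            class = "angular_histogram")
}

#' Processing backlog of live pre-processing jobs
#'
#' For each job, counts the rows of its output micrograph table (`done`)
#' against the rows of its upstream input table (`pending = upstream -
#' done`, clamped at zero: during polling the output can momentarily run
#' ahead of a stale input listing). A missing output file counts as zero
#' done.
#'
#' @param project_root project root directory.
#' @param jobs `data.frame` with columns `name`, `input_star`,
#'   `output_star` (paths relative to `project_root`).
#' @return `data.frame` with columns `name`, `done`, `pending`.
#' @export
job_backlog <- function(project_root, jobs) {
  stopifnot(all(c("name", "input_star", "output_star") %in% names(jobs)))
  count_rows <- function(rel) {
    p <- file.path(project_root, rel)
    if (!file.exists(p)) return(NA_integer_)
    nrow(get_table(read_star(p)))
  }
  done <- integer(nrow(jobs))
  pending <- integer(nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    up <- count_rows(jobs$input_star[i])
    dn <- count_rows(jobs$output_star[i])
    if (is.na(up)) up <- 0L
    if (is.na(dn)) dn <- 0L
    if (dn > up) {
      warning(sprintf("job %s: output (%d) ahead of input (%d); %s",
                      jobs$name[i], dn, up, "pending clamped to 0"),
              call. = FALSE)
    }
    done[i] <- dn
    pending[i] <- max(0L, up - dn)
  }
  data.frame(name = jobs$name, done = done, pending = pending,
             stringsAsFactors = FALSE)
}
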