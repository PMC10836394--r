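#' Ice scoring band
#'
#' Both vitreous and crystalline ice produce intensity maxima in the
#' micrograph power spectrum between roughly 3.6 and 4 Angstrom. The mean
#' spectral signal over the spatial-frequency band 1/4 to 1/3.6 per Angstrom
#' is therefore a cheap proxy for ice thickness and crystalline-ice
#' contamination; crystalline ice scores far higher than thin vitreous ice.
#'
#' @param f_lo,f_hi band edges in 1/Angstrom, both inclusive.
#' @return an object of class `ice_band`.
#' @export
ice_band <- function(f_lo = 1 / 4.0, f_hi = 1 / 3.6) {
  if (!(f_lo > 0 && f_hi > f_lo)) {
    relmeta_stop("ice band requires 0 < f_lo < f_hi (got %g, %g)", f_lo, f_hi,
                 class = "relmeta_validation_error")
  }
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "ice_band")
}

#' Radial spectral profile
#'
#' Pairs strictly increasing spatial frequencies (1/Angstrom, excluding the
#' zero-frequency sample) with the rotationally averaged spectral signal at
#' each frequency.
#'
#' @param frequencies numeric, strictly increasing, all > 0.
#' @param values numeric, same length.
#' @return an object of class `radial_profile`.
#' @export
radial_profile <- function(frequencies, values) {
  if (length(frequencies) != length(values)) {
    relmeta_stop("frequencies (%d) and values (%d) differ in length",
                 length(frequencies), length(values),
                 class = "relmeta_validation_error")
  }
  if (length(frequencies) && (any(frequencies <= 0) ||
                              any(diff(frequencies) <= 0))) {
    relmeta_stop("frequencies must be strictly increasing and positive",
                 class = "relmeta_validation_error")
  }
  structure(list(frequencies = as.numeric(frequencies),
                 values = as.numeric(values)),
            class = "radial_profile")
}

#' Centered power spectrum of a micrograph
#'
#' Computes `|DFT(image)|^2` with the zero-frequency component shifted to
#' the center. Non-square inputs are center-cropped to the largest square so
#' radial bins stay isotropic. The DFT is unnormalized, so Parseval's
#' identity reads `sum(spectrum) == N * sum(image^2)` with `N` the pixel
#' count.
#'
#' @param image 2D numeric matrix, both dims >= 16, finite values.
#' @param pixel_size pixel size in Angstrom (> 0); carried as an attribute.
#' @return square matrix of spectral power, DC at `floor(n/2) + 1`.
#' @export
power_spectrum <- function(image, pixel_size) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) {
    relmeta_stop("image contains non-finite pixels",
                 class = "relmeta_validation_error")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    relmeta_stop("pixel_size must be a single positive value in Angstrom",
                 class = "relmeta_validation_error")
  }
  if (min(dim(image)) < 16L) {
    relmeta_stop("image dims %dx%d too small (need >= 16)",
                 nrow(image), ncol(image), class = "relmeta_validation_error")
  }
  n <- min(dim(image))
  r0 <- (nrow(image) - n) %/% 2L
  c0 <- (ncol(image) - n) %/% 2L
  img <- image[r0 + seq_len(n), c0 + seq_len(n), drop = FALSE]
  sp <- Mod(stats::fft(img))^2
  sp <- fft_shift(sp)
  attr(sp, "pixel_size") <- pixel_size
  sp
}

# Move the DC component from [1,1] to the centered position floor(n/2)+1.
fft_shift <- function(m) {
  n <- nrow(m)
  k <- n %/% 2L
  idx <- c((n - k + 1L):n, 1L:(n - k))
  m[idx, idx, drop = FALSE]
}

#' Rotationally average a power spectrum
#'
#' Bins every Fourier pixel (excluding DC) by its integer radius from the
#' spectrum center: the bin of a pixel at distance `d` is `round(d)` with
#' ties at .5 rounded away from zero. The profile value at radius `r` is the
#' mean power over that bin; its frequency is `r / (n * pixel_size)`. Bins
#' beyond Nyquist (`r > n/2`) are discarded.
#'
#' @param spectrum square DC-centered power spectrum (see
#'   [power_spectrum()]).
#' @param pixel_size pixel size in Angstrom.
#' @return a [radial_profile()].
#' @export
radial_average <- function(spectrum, pixel_size = attr(spectrum, "pixel_size")) {
  stopifnot(is.matrix(spectrum))
  if (nrow(spectrum) != ncol(spectrum)) {
    relmeta_stop("spectrum must be square (got %dx%d)",
                 nrow(spectrum), ncol(spectrum),
                 class = "relmeta_validation_error")
  }
  if (is.null(pixel_size)) {
    relmeta_stop("pixel_size missing (not found in spectrum attributes)",
                 class = "relmeta_validation_error")
  }
  n <- nrow(spectrum)
  ctr <- n %/% 2L + 1L
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  r <- round_half_away(d)
  keep <- r >= 1L & r <= n %/% 2L
  sums <- tapply(spectrum[keep], r[keep], mean)
  radii <- as.integer(names(sums))
  o <- order(radii)
  radial_profile(frequencies = radii[o] / (n * pixel_size),
                 values = as.numeric(sums[o]))
}

#' Mean spectral signal inside the ice band
#'
#' Arithmetic mean of the profile values whose frequency lies inside the
#' band, both edges inclusive. This is the ice score for one micrograph.
#'
#' @param profile a [radial_profile()].
#' @param band an [ice_band()].
#' @return single numeric score (dimensionless).
#' @export
band_mean <- function(profile, band = ice_band()) {
  stopifnot(inherits(profile, "radial_profile"), inherits(band, "ice_band"))
  inside <- profile$frequencies >= band$f_lo & profile$frequencies <= band$f_hi
  if (!any(inside)) {
    relmeta_stop(paste0(
      "no profile samples inside the band [%g, %g] 1/Angstrom; the profile ",
      "ends at %g. Seeing the ice ring at 1/4 1/Angstrom requires a pixel ",
      "size of at most 2 Angstrom."),
      band$f_lo, band$f_hi, max(profile$frequencies, 0),
      class = "relmeta_band_error")
  }
  mean(profile$values[inside])
}

#' Read a CTFFIND4 radial-profile ("avrot") text file
#'
#' CTFFIND4 writes, next to each CTF fit, a plain-text file of
#' whitespace-separated numeric rows preceded by `#` comment lines. The
#' first numeric row is the spatial-frequency axis (1/Angstrom); in the full
#' six-row layout the following rows are the raw rotational average of the
#' power spectrum, the background-subtracted rotational average, the fitted
#' CTF, the correlation between fit and data, and the significance
#' threshold.
#'
#' @param path path to the avrot file.
#' @param signal_row 1-based index of the row to use as the profile signal.
#'   The default (3) selects the background-subtracted rotational average,
#'   which removes the defocus-envelope trend from the ice score.
#' @return a [radial_profile()] (the zero-frequency sample is dropped).
#' @export
read_ctffind_radial_profile <- function(path, signal_row = 3L) {
  if (!file.exists(path)) {
    relmeta_stop("avrot file not found: %s", path,
                 class = "relmeta_lookup_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) {
    relmeta_stop("avrot file %s: need at least 2 numeric rows, found %d",
                 path, length(lines), class = "relmeta_format_error")
  }
  rows <- lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
  if (anyNA(unlist(rows))) {
    relmeta_stop("avrot file %s: non-numeric cell in a data row", path,
                 class = "relmeta_format_error")
  }
  len <- vapply(rows, length, integer(1))
  if (length(unique(len)) != 1L) {
    relmeta_stop("avrot file %s: rows of unequal length (%s)",
                 path, paste(unique(len), collapse = ", "),
                 class = "relmeta_format_error")
  }
  if (signal_row < 2L || signal_row > length(rows)) {
    relmeta_stop("avrot file %s: signal row %d out of range (2..%d)",
                 path, signal_row, length(rows),
                 class = "relmeta_format_error")
  }
  freq <- rows[[1]]
  val <- rows[[signal_row]]
  keep <- freq > 0
  radial_profile(freq[keep], val[keep])
}

#' Native ice score of one micrograph image
#'
#' Power spectrum, rotational averaging and band mean in one step. By
#' default the spectrum is normalized by the total power excluding DC
#' before averaging, which makes the score invariant to overall image
#' intensity; set `normalize = FALSE` for the raw band power (which scales
#' as the square of image intensity).
#'
#' @param image 2D numeric matrix.
#' @param pixel_size pixel size in Angstrom.
#' @param band an [ice_band()].
#' @param normalize divide the spectrum by its total non-DC power first.
#' @return single numeric score.
#' @export
ice_score <- function(image, pixel_size, band = ice_band(), normalize = TRUE) {
  sp <- power_spectrum(image, pixel_size)
  if (normalize) {
    n <- nrow(sp)
    ctr <- n %/% 2L + 1L
    tot <- sum(sp) - sp[ctr, ctr]
    if (tot > 0) sp <- sp / tot
  }
  band_mean(radial_average(sp, pixel_size), band)
}

#' Score a table of micrographs for ice quality
#'
#' Appends an `rlnMicrographIceThickness` column to a micrograph metadata
#' table, allowing later selection of micrographs (or their particles) by
#' ice quality. With `source = "native"` each referenced MRC micrograph is
#' read and scored via [ice_score()]; with `source = "ctffind-profile"` the
#' per-micrograph avrot file is read and its band mean taken directly. The
#' two routes agree in ranking, not in absolute value.
#'
#' @param table micrograph loop table.
#' @param source `"native"` or `"ctffind-profile"`.
#' @param band an [ice_band()].
#' @param pixel_size pixel size in Angstrom (native path).
#' @param path_label label of the column holding file paths
#'   (micrograph MRC for native, avrot file for the profile path).
#' @param root directory the paths are relative to.
#' @param signal_row avrot signal row, see
#'   [read_ctffind_radial_profile()].
#' @param normalize see [ice_score()].
#' @param on_error `"abort"` stops at the first unreadable file;
#'   `"skip"` records `NaN` for the row and collects a warning.
#' @return the table with the score column appended.
#' @export
score_micrographs <- function(table,
                              source = c("native", "ctffind-profile"),
                              band = ice_band(),
                              pixel_size = NULL,
                              path_label = if (source == "native")
                                "rlnMicrographName" else "rlnCtfPowerSpectrum",
                              root = ".",
                              signal_row = 3L,
                              normalize = TRUE,
                              on_error = c("abort", "skip")) {
  source <- match.arg(source)
  on_error <- match.arg(on_error)
  if (nrow(table) == 0L) {
    return(add_column(table, "rlnMicrographIceThickness", numeric(0)))
  }
  lab <- resolve_label(names(table), path_label, "micrograph table")
  paths <- file.path(root, table[[lab]])
  scores <- rep(NaN, length(paths))
  failures <- character(0)
  for (i in seq_along(paths)) {
    res <- tryCatch({
      if (source == "native") {
        img <- read_mrc(paths[i])
        ps <- if (!is.null(pixel_size)) pixel_size else img$pixel_size
        ice_score(img$pixels, ps, band, normalize)
      } else {
        band_mean(read_ctffind_radial_profile(paths[i], signal_row), band)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "abort") {
        relmeta_stop("scoring %s failed: %s", paths[i], conditionMessage(res))
      }
      failures <- c(failures, sprintf("%s: %s", paths[i],
                                      conditionMessage(res)))
    } else {
      scores[i] <- res
    }
  }
  if (length(failures)) {
    warning(sprintf("%d micrograph(s) could not be scored:\n%s",
                    length(failures), paste(failures, collapse = "\n")),
            call. = FALSE)
  }
  add_column(table, "rlnMicrographIceThickness", scores)
}
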