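# MRC image I/O and 8-bit preview rendering.
#
# The MRC header is 1024 bytes of little-endian words: nx, ny, nz, mode at
# words 1-4, mx/my/mz at words 8-10, the cell dimensions in Angstrom
# (cella) at words 11-13. Pixel size = cella.x / mx. Supported modes:
# 0 (int8), 1 (int16), 2 (float32).

mrc_mode_bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L)

#' Read an MRC image
#'
#' Returns the first 2D section of an MRC file as an `image2d` object:
#' a list with `pixels` (numeric matrix, row = image row as displayed,
#' origin top-left, no flips applied) and `pixel_size` (Angstrom per pixel
#' from the header cell dimensions, `NA` when the header carries none).
#'
#' @param path path to the MRC file.
#' @return an object of class `image2d`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) {
    relmeta_stop("MRC file not found: %s", path,
                 class = "relmeta_lookup_error")
  }
  size <- file.info(path)$size
  if (is.na(size) || size < 1024) {
    relmeta_stop("MRC file %s truncated: %d byte(s), header needs 1024",
                 path, size, class = "relmeta_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readBin(con, "integer", n = 3, size = 4, endian = "little")  # nstart
  m_grid <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (any(dims < 1L) || any(dims > 1e6)) {
    relmeta_stop("MRC file %s: implausible dims %s", path,
                 paste(dims, collapse = "x"), class = "relmeta_format_error")
  }
  if (!as.character(mode) %in% names(mrc_mode_bytes)) {
    relmeta_stop("MRC file %s: unsupported mode %d (supported: 0, 1, 2)",
                 path, mode, class = "relmeta_unsupported_mode_error")
  }
  nbytes <- mrc_mode_bytes[[as.character(mode)]]
  need <- 1024 + as.numeric(nbytes) * dims[1] * dims[2]
  if (size < need) {
    relmeta_stop("MRC file %s truncated: %d byte(s), need %d for one section",
                 path, size, need, class = "relmeta_format_error")
  }
  seek(con, 1024)
  n <- dims[1] * dims[2]
  vals <- if (mode == 2L) {
    readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = nbytes, signed = TRUE,
            endian = "little")
  }
  if (dims[3] > 1L) {
    message(sprintf("MRC file %s holds %d sections; returning the first",
                    path, dims[3]))
  }
  px <- if (m_grid[1] > 0 && cella[1] > 0) cella[1] / m_grid[1] else NA_real_
  # data are stored column-fastest (x fastest): rows of the matrix = y
  pixels <- matrix(as.numeric(vals), nrow = dims[2], ncol = dims[1],
                   byrow = TRUE)
  structure(list(pixels = pixels, pixel_size = px), class = "image2d")
}

#' Write a 2D image as MRC (mode 2, float32)
#'
#' Counterpart of [read_mrc()]; used by the synthetic-project generator.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param pixel_size Angstrom per pixel, recorded in the header cell.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(image, path, pixel_size = 1) {
  stopifnot(is.matrix(image), all(is.finite(image)), pixel_size > 0)
  nx <- ncol(image); ny <- nrow(image)
  con <- file(path, "wb")
  on.exit(close(con))
  header_int <- integer(256)
  header_int[1:3] <- c(nx, ny, 1L)          # nx ny nz
  header_int[4] <- 2L                        # mode 2 = float32
  header_int[8:10] <- c(nx, ny, 1L)          # mx my mz
  writeBin(header_int[1:10], con, size = 4, endian = "little")
  writeBin(as.numeric(c(nx, ny, 1) * pixel_size), con, size = 4,
           endian = "little")                # cella
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")  # cellb
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")  # mapc mapr maps
  writeBin(c(min(image), max(image), mean(image)), con, size = 4,
           endian = "little")                # dmin dmax dmean
  # pad the rest of the 1024-byte header (words 23..256)
  writeBin(integer(256 - 22), con, size = 4, endian = "little")
  writeBin(as.numeric(t(image)), con, size = 4, endian = "little")
  invisible(path)
}

#' Normalize an image to 8-bit grayscale
#'
#' Maps the `[p_lo, p_hi]` intensity percentiles linearly onto `[0, 255]`,
#' clipping outside; percentile scaling is robust to hot pixels, unlike a
#' min-max stretch. A constant image maps to mid-gray 128.
#'
#' @param img an `image2d` or a numeric matrix.
#' @param p_lo,p_hi percentiles in `[0, 100]`, `p_lo < p_hi`.
#' @return integer matrix with values in `[0, 255]`.
#' @export
normalize_to_8bit <- function(img, p_lo = 1, p_hi = 99) {
  m <- if (inherits(img, "image2d")) img$pixels else img
  stopifnot(is.matrix(m))
  if (!(p_lo >= 0 && p_lo < p_hi && p_hi <= 100)) {
    relmeta_stop("need 0 <= p_lo < p_hi <= 100 (got %g, %g)", p_lo, p_hi,
                 class = "relmeta_validation_error")
  }
  q <- stats::quantile(m, probs = c(p_lo, p_hi) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    out <- matrix(128L, nrow(m), ncol(m))
    return(out)
  }
  scaled <- (m - q[1]) / (q[2] - q[1]) * 255
  out <- matrix(as.integer(pmin(255, pmax(0, round(scaled)))),
                nrow(m), ncol(m))
  out
}

# Mean-pool an image by an integer factor (trailing partial windows kept,
# so output dims are ceiling(input / factor)).
bin_image <- function(m, factor) {
  if (factor <= 1L) return(m)
  ri <- (seq_len(nrow(m)) - 1L) %/% factor
  ci <- (seq_len(ncol(m)) - 1L) %/% factor
  grp <- outer(ri, ci, function(a, b) a * (max(ci) + 1L) + b)
  means <- tapply(m, grp, mean)
  matrix(as.numeric(means), nrow = max(ri) + 1L, ncol = max(ci) + 1L,
         byrow = TRUE)
}

#' Render PNG previews of a micrograph and its CTF
#'
#' Writes two deterministic 8-bit grayscale PNGs named from the micrograph
#' id: `<id>.png` and `<id>_ctf.png`. Images are optionally mean-pooled
#' (default 4x) to dashboard-preview size before percentile normalization.
#'
#' @param micrograph,ctf_image `image2d` objects or numeric matrices.
#' @param out_dir output directory (created if missing).
#' @param id micrograph identifier used as the file stem.
#' @param binning integer pooling factor (1 disables).
#' @param p_lo,p_hi normalization percentiles, see [normalize_to_8bit()].
#' @return character vector of the two paths written.
#' @export
render_preview_pair <- function(micrograph, ctf_image, out_dir, id,
                                binning = 4L, p_lo = 1, p_hi = 99) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, paste0(id, c("", "_ctf"), ".png"))
  imgs <- list(micrograph, ctf_image)
  for (k in 1:2) {
    m <- if (inherits(imgs[[k]], "image2d")) imgs[[k]]$pixels else imgs[[k]]
    m <- bin_image(m, as.integer(binning))
    g <- normalize_to_8bit(m, p_lo, p_hi)
    png::writePNG(g / 255, paths[k])
  }
  paths
}
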