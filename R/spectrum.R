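#' Centroided mass spectrum
#'
#' A minimal container for a centroided peak list: m/z strictly increasing,
#' intensities non-negative. This is the I/O currency of the pipeline.
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @param sample_id,polarity,label Optional metadata strings.
#' @return Object of class `"hdx_spectrum"`: a list with `mz`, `intensity`
#'   and a `meta` list. Peaks are sorted by m/z on construction; exact
#'   duplicate m/z values have their intensities summed.
#' @export
hdx_spectrum <- function(mz, intensity, sample_id = NA_character_,
                         polarity = NA_character_, label = NA_character_) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0),
            all(is.finite(mz)), all(is.finite(intensity)))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  structure(list(mz = mz, intensity = intensity,
                 meta = list(sample_id = sample_id, polarity = polarity,
                             label = label)),
            class = "hdx_spectrum")
}

#' @export
print.hdx_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d peaks, m/z %.4f-%.4f, TIC %.4g",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  if (!is.na(x$meta$sample_id)) cat("  [", x$meta$sample_id, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.hdx_spectrum <- function(x, ...) {
  graphics::plot(x$mz, x$intensity, type = "h", xlab = "m/z",
                 ylab = "intensity", ...)
  invisible(x)
}

#' Read / write a peak-list TSV
#'
#' The canonical on-disk format: two tab-separated numeric columns
#' (mz, intensity); lines starting with `#` are comments. Peaks are sorted
#' on read; values round-trip to at least 6 significant digits.
#'
#' @param path File path.
#' @param sample_id Optional sample id attached on read.
#' @return `read_peaklist` returns an [hdx_spectrum]; `write_peaklist`
#'   returns `path` invisibly.
#' @export
read_peaklist <- function(path, sample_id = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty spectrum file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) stop(sprintf("malformed row at line %d of %s", bad[1L], path))
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(mz) || anyNA(it)) {
    stop(sprintf("non-numeric value at line %d of %s",
                 which(is.na(mz) | is.na(it))[1L], path))
  }
  hdx_spectrum(mz, it, sample_id = sample_id)
}

#' @rdname read_peaklist
#' @param spectrum An [hdx_spectrum].
#' @export
write_peaklist <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "hdx_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s", spectrum$meta$sample_id), con)
  writeLines(sprintf("%.10g\t%.10g", spectrum$mz, spectrum$intensity), con)
  invisible(path)
}

#' Read a centroided spectrum from an mzML file
#'
#' Optional reader behind the same [hdx_spectrum] container; requires the
#' Bioconductor package mzR. Multiple scans are summed unless `scan` is
#' given.
#'
#' @param path mzML file path.
#' @param scan Optional 1-based scan index.
#' @return An [hdx_spectrum].
#' @export
read_mzml <- function(path, scan = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the 'mzR' package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(try(mzR::close(fh), silent = TRUE))
  idx <- if (is.null(scan)) seq_len(mzR::runInfo(fh)$scanCount) else scan
  pk <- mzR::peaks(fh, idx)
  if (is.list(pk)) pk <- do.call(rbind, pk)
  hdx_spectrum(pk[, 1L], pk[, 2L], sample_id = basename(path))
}

#' Total-ion-current normalization
#'
#' Scales intensities so their sum is 100, enabling cross-sample comparison.
#' Idempotent.
#'
#' @param spectrum An [hdx_spectrum].
#' @return The normalized [hdx_spectrum].
#' @export
tic_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "hdx_spectrum"))
  tic <- sum(spectrum$intensity)
  if (tic <= 0) stop("cannot TIC-normalize an all-zero spectrum")
  spectrum$intensity <- spectrum$intensity * (100 / tic)
  spectrum
}

#' Average replicate spectra with m/z tolerance merging
#'
#' Peaks within `mz_tol` across spectra are merged into one averaged peak:
#' intensity is the arithmetic mean over ALL input spectra (a spectrum in
#' which the peak is absent contributes zero), m/z is the intensity-weighted
#' mean of the contributing peaks. The default tolerance is the instrument
#' peak width (FWHM ~ 0.002 u).
#'
#' @param spectra Non-empty list of [hdx_spectrum]s.
#' @param mz_tol Merge tolerance in u.
#' @return The averaged [hdx_spectrum].
#' @export
average_spectra <- function(spectra, mz_tol = 0.002) {
  stopifnot(is.list(spectra), length(spectra) >= 1L, mz_tol > 0)
  stopifnot(all(vapply(spectra, inherits, TRUE, "hdx_spectrum")))
  n <- length(spectra)
  mz <- unlist(lapply(spectra, `[[`, "mz"))
  it <- unlist(lapply(spectra, `[[`, "intensity"))
  o <- order(mz)
  mz <- mz[o]; it <- it[o]
  # single-linkage grouping: break where consecutive gap exceeds tolerance
  grp <- cumsum(c(1, diff(mz) > mz_tol))
  mzm <- unname(vapply(split(seq_along(mz), grp), function(i) {
    w <- it[i]
    if (sum(w) > 0) sum(mz[i] * w) / sum(w) else mean(mz[i])
  }, 0))
  im <- unname(vapply(split(it, grp), sum, 0)) / n
  hdx_spectrum(mzm, im, sample_id = "average")
}
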