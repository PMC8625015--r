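#' Deuterium isotope ladder
#'
#' Intensities at integer deuteration channels D0..Dn of one precursor ion.
#' Channel k sits at `precursor_mz + k * deuterium_mass_step`. The relative
#' scale expresses each channel as a percentage of the base peak (the most
#' intense channel): `I_rel = 100 * I_abs / I_BP`.
#'
#' @param precursor_mz m/z of the D0 channel.
#' @param channels Non-negative absolute intensities at k = 0, 1, ....
#' @param compound Optional annotation.
#' @return Object of class `"hdx_ladder"`: list with `precursor_mz`,
#'   `channels` (absolute), `relative`, `n` (highest channel index) and
#'   `compound`.
#' @export
hdx_ladder <- function(precursor_mz, channels, compound = NULL) {
  channels <- as.numeric(channels)
  stopifnot(precursor_mz > 0, length(channels) >= 1L, all(channels >= 0),
            any(channels > 0))
  structure(list(precursor_mz = precursor_mz,
                 channels = channels,
                 relative = 100 * channels / max(channels),
                 n = length(channels) - 1L,
                 compound = compound),
            class = "hdx_ladder")
}

#' @export
print.hdx_ladder <- function(x, digits = 1, ...) {
  cat(sprintf("<deuterium ladder> %sm/z %.4f, D0..D%d\n",
              if (is.null(x$compound)) "" else paste0(x$compound, ", "),
              x$precursor_mz, x$n))
  rel <- round(x$relative, digits)
  names(rel) <- paste0("D", seq_along(rel) - 1L)
  print(rel)
  invisible(x)
}

#' @export
plot.hdx_ladder <- function(x, ...) {
  k <- seq_along(x$channels) - 1L
  graphics::plot(x$precursor_mz + k * deuterium_mass_step, x$relative,
                 type = "h", xlab = "m/z", ylab = "relative intensity (%)",
                 main = x$compound, ...)
  invisible(x)
}

#' Channel m/z positions of a ladder
#' @param ladder An [hdx_ladder].
#' @return Numeric vector, one m/z per channel.
#' @export
ladder_mz <- function(ladder) {
  ladder$precursor_mz + (seq_along(ladder$channels) - 1L) * deuterium_mass_step
}

#' Index of the ladder base peak
#'
#' The deuteration index k of the most intense channel; ties break toward
#' smaller k.
#'
#' @param ladder An [hdx_ladder].
#' @return Integer k (0-based).
#' @export
base_peak_index <- function(ladder) {
  stopifnot(inherits(ladder, "hdx_ladder"))
  which.max(ladder$channels) - 1L
}

#' Extract a deuterium ladder from a spectrum
#'
#' Walks up from the precursor in steps of one deuterium mass
#' (1.006277 u); a spectrum peak is assigned to channel k when it lies
#' within `k * step_tol` of `precursor_mz + k * 1.006277` (the per-step
#' window 1.0063 +/- 0.0002 accumulated over k steps). Missing channels are
#' recorded as zero; trailing all-zero channels are trimmed.
#'
#' @param spectrum An [hdx_spectrum] (raw or TIC-normalized).
#' @param precursor_mz Expected D0 m/z.
#' @param max_k Highest channel to search (>= 1).
#' @param step_tol Per-step m/z tolerance in u.
#' @param precursor_tol Match tolerance for the precursor itself.
#' @param compound Optional annotation.
#' @return An [hdx_ladder].
#' @export
find_ladder <- function(spectrum, precursor_mz, max_k = 10L,
                        step_tol = 0.0002, precursor_tol = 0.002,
                        compound = NULL) {
  stopifnot(inherits(spectrum, "hdx_spectrum"), max_k >= 1L, step_tol >= 0)
  ch <- numeric(max_k + 1L)
  for (k in 0:max_k) {
    target <- precursor_mz + k * deuterium_mass_step
    tol <- if (k == 0L) precursor_tol else k * step_tol
    d <- abs(spectrum$mz - target)
    hit <- which(d <= tol)
    if (length(hit)) ch[k + 1L] <- spectrum$intensity[hit[which.min(d[hit])]]
  }
  if (ch[1L] == 0) {
    stop(sprintf("precursor m/z %.4f not found within %.4g u",
                 precursor_mz, precursor_tol))
  }
  last <- max(which(ch > 0))
  hdx_ladder(precursor_mz, ch[seq_len(last)], compound = compound)
}

#' Natural-isotope correction of a ladder
#'
#' Inverts the forward convolution `I_abs(k) = sum_{d<=k} pmf(d) *
#' natural(k-d)` for the deuterium-count distribution `pmf` by forward
#' substitution of the triangular system. Negative solutions (possible under
#' noise) are clipped to zero and the result renormalized.
#'
#' @param ladder An [hdx_ladder].
#' @param formula,adduct Ion composition used for the natural pattern.
#' @return Numeric pmf over deuterium counts 0..n (sums to 1).
#' @export
natural_correction <- function(ladder, formula, adduct = "[M+H]+") {
  stopifnot(inherits(ladder, "hdx_ladder"))
  n <- ladder$n
  nat <- ion_natural_pattern(formula, adduct, length = n + 1L)
  if (nat[1L] <= 0) stop("singular system: natural pattern has zero monoisotopic abundance")
  I <- ladder$channels
  pmf <- numeric(n + 1L)
  for (k in 0:n) {
    acc <- I[k + 1L]
    if (k > 0) {
      d <- 0:(k - 1L)
      acc <- acc - sum(pmf[d + 1L] * nat[k - d + 1L])
    }
    pmf[k + 1L] <- acc / nat[1L]
  }
  pmf[pmf < 0] <- 0
  if (sum(pmf) <= 0) stop("natural correction removed all signal")
  pmf / sum(pmf)
}

#' Judge which channels are deuterated and count exchangeable sites
#'
#' After natural-isotope correction, channel k >= 1 is flagged as a true
#' deuterium peak when the corrected deuterium-count mass at k is at least
#' `excess_threshold`% of the largest corrected mass (base-peak-relative
#' threshold). The exchangeable-site count is the highest flagged k minus one
#' when the charge-site deuteron is assumed (proton-bearing adduct with
#' charge-site exchange), floored at 0.
#'
#' @param ladder An [hdx_ladder].
#' @param formula,adduct Ion composition.
#' @param excess_threshold Flagging threshold in % of the corrected base
#'   mass (default 1).
#' @param charge_site Whether a charge-site deuteron is assumed for
#'   proton-bearing adducts.
#' @return List of class `"hdx_judgment"`: `corrected_pmf`, `excess`
#'   (corrected mass above zero at k >= 1), `is_deuterated` (logical per
#'   channel, element 1 = D0 = FALSE by definition), `flagged` (integer
#'   vector of flagged k), `site_count_estimate`.
#' @export
judge_deuteration <- function(ladder, formula, adduct = "[M+H]+",
                              excess_threshold = 1.0, charge_site = TRUE) {
  stopifnot(excess_threshold >= 0)
  if (is.character(adduct)) adduct <- hdxladder::adduct(adduct)
  pmf <- natural_correction(ladder, formula, adduct)
  thr <- (excess_threshold / 100) * max(pmf)
  flags <- pmf >= thr
  flags[1L] <- FALSE
  flagged <- which(flags) - 1L
  charge_deuteron <- adduct$proton_bearing && charge_site
  site_count <- if (length(flagged)) {
    max(0L, max(flagged) - as.integer(charge_deuteron))
  } else 0L
  structure(list(corrected_pmf = pmf,
                 excess = pmf[-1L],
                 is_deuterated = flags,
                 flagged = flagged,
                 site_count_estimate = site_count),
            class = "hdx_judgment")
}

#' @export
print.hdx_judgment <- function(x, ...) {
  cat(sprintf("<HDX judgment> flagged channels: %s; site count estimate: %d\n",
              if (length(x$flagged)) paste0("D", x$flagged, collapse = ", ")
              else "(none)", x$site_count_estimate))
  invisible(x)
}

#' Rank candidate precursors by deuteration
#'
#' Candidates are ranked by the number of flagged deuterium channels on the
#' averaged spectrum of the set (ties: total corrected deuterium mass at
#' k >= 1, then ascending m/z), mirroring the selection of the "most
#' deuteration-shifted" ions for profiling.
#'
#' @param spectra List of [hdx_spectrum]s (a cohort or replicate set).
#' @param candidates Data frame with columns `name`, `formula`, `adduct` and
#'   optionally `charge_site` (logical); precursor m/z is computed from the
#'   formula and adduct.
#' @param top_n Number of precursors to return.
#' @param ... Passed to [find_ladder()].
#' @return `candidates` rows (with added `precursor_mz`, `n_flagged`,
#'   `deuterium_mass` columns) ordered by rank, truncated to `top_n`.
#' @export
rank_by_deuteration <- function(spectra, candidates, top_n = 10L, ...) {
  stopifnot(top_n >= 1L, nrow(candidates) >= 1L)
  if (inherits(spectra, "hdx_spectrum")) spectra <- list(spectra)
  avg <- average_spectra(spectra)
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    row <- candidates[i, ]
    pm <- ion_mz(row$formula, row$adduct)
    cs <- if ("charge_site" %in% names(candidates)) isTRUE(row$charge_site) else TRUE
    out <- list(precursor_mz = pm, n_flagged = 0L, deuterium_mass = 0)
    lad <- tryCatch(find_ladder(avg, pm, ...), error = function(e) NULL)
    if (!is.null(lad)) {
      j <- judge_deuteration(lad, row$formula, row$adduct, charge_site = cs)
      out$n_flagged <- length(j$flagged)
      out$deuterium_mass <- sum(j$corrected_pmf[-1L])
    }
    out
  })
  candidates$precursor_mz <- vapply(res, `[[`, 0, "precursor_mz")
  candidates$n_flagged <- vapply(res, `[[`, 0L, "n_flagged")
  candidates$deuterium_mass <- vapply(res, `[[`, 0, "deuterium_mass")
  o <- order(-candidates$n_flagged, -candidates$deuterium_mass,
             candidates$precursor_mz)
  utils::head(candidates[o, , drop = FALSE], top_n)
}
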