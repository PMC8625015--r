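#' Build a cohort feature matrix from spectra
#'
#' One row per sample, one feature per precursor (its D0 channel intensity);
#' with `include_deuterium = TRUE`, one additional feature per deuterium
#' channel k >= 1 detected across the cohort. Detection is judged on the
#' cohort-average spectrum with [judge_deuteration()] when the precursor's
#' formula is known (so only true deuterium peaks, not natural-isotope
#' tails, become features); for bare m/z precursors any channel that is
#' nonzero somewhere counts. HDX thus contributes the exchangeable-site
#' dimension as extra features on top of the plain-profile ion intensities.
#' Intensities should be TIC-normalized beforehand; missing peaks contribute
#' 0.
#'
#' @param spectra List of [hdx_spectrum]s (one per sample).
#' @param precursors Data frame with columns `name`, `formula`, `adduct`
#'   (precursor m/z is computed), or a numeric vector of precursor m/z.
#' @param include_deuterium Add D_k (k >= 1) channel features.
#' @param max_k Highest channel searched.
#' @param step_tol Ladder step tolerance in u.
#' @return Numeric matrix (samples x features) with feature labels
#'   `name` for D0 and `name+Dk` for deuterium channels; sample ids as row
#'   names.
#' @export
build_features <- function(spectra, precursors, include_deuterium = TRUE,
                           max_k = 10L, step_tol = 0.0002) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  if (is.numeric(precursors)) {
    precursors <- data.frame(name = sprintf("mz%.4f", precursors),
                             mz = precursors)
  } else {
    stopifnot(nrow(precursors) >= 1L)
    precursors$mz <- mapply(ion_mz, precursors$formula, precursors$adduct)
  }
  if (nrow(precursors) == 0L) stop("empty precursor list")
  n_s <- length(spectra); n_p <- nrow(precursors)
  # channel intensity cube: samples x precursors x channels
  cube <- array(0, dim = c(n_s, n_p, max_k + 1L))
  for (s in seq_len(n_s)) {
    for (p in seq_len(n_p)) {
      lad <- tryCatch(
        find_ladder(spectra[[s]], precursors$mz[p], max_k = max_k,
                    step_tol = step_tol),
        error = function(e) NULL)
      if (!is.null(lad)) {
        cube[s, p, seq_along(lad$channels)] <- lad$channels
      }
    }
  }
  mat <- cube[, , 1L, drop = FALSE]
  dim(mat) <- c(n_s, n_p)
  labels <- precursors$name
  if (include_deuterium) {
    has_formula <- "formula" %in% names(precursors)
    avg <- average_spectra(spectra)
    for (p in seq_len(n_p)) {
      detected <- integer(0)
      if (has_formula) {
        cs <- if ("charge_site" %in% names(precursors))
          isTRUE(precursors$charge_site[p]) else TRUE
        lad <- tryCatch(
          find_ladder(avg, precursors$mz[p], max_k = max_k,
                      step_tol = step_tol),
          error = function(e) NULL)
        if (!is.null(lad)) {
          detected <- judge_deuteration(lad, precursors$formula[p],
                                        precursors$adduct[p],
                                        charge_site = cs)$flagged
        }
      } else {
        detected <- which(apply(cube[, p, -1L, drop = FALSE] > 0, 3L, any))
      }
      for (k in detected[detected >= 1L & detected <= max_k]) {
        mat <- cbind(mat, cube[, p, k + 1L])
        labels <- c(labels, sprintf("%s+D%d", precursors$name[p], k))
      }
    }
  }
  colnames(mat) <- labels
  rownames(mat) <- vapply(spectra, function(s) {
    id <- s$meta$sample_id
    if (is.na(id)) "" else id
  }, "")
  mat
}

#' Principal component analysis of a feature matrix
#'
#' Thin wrapper around [stats::prcomp()] with mean centering and (by
#' default) unit-variance scaling, plus a deterministic sign convention:
#' each component is flipped so its largest-magnitude loading is positive.
#' Constant features are dropped before scaling.
#'
#' @param mat Samples x features numeric matrix.
#' @param n_components Number of components to keep.
#' @param scale. Autoscale features to unit variance.
#' @return List with `scores` (samples x n_components), `loadings`
#'   (features x n_components), `explained_variance` (fractions).
#' @export
hdx_pca <- function(mat, n_components = 2L, scale. = TRUE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  keep <- apply(mat, 2L, stats::var) > 0
  mat <- mat[, keep, drop = FALSE]
  if (n_components > min(nrow(mat) - 1L, ncol(mat))) {
    stop("n_components exceeds min(samples - 1, features)")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sco <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sco, loadings = rot,
       explained_variance = ev[seq_len(n_components)])
}

#' Silhouette separation score of grouped PCA scores
#'
#' Mean silhouette width (via [cluster::silhouette()]) of the group labels
#' over the first two principal-component dimensions — a quantitative
#' stand-in for visual score-plot separation. 1 = perfectly separated
#' groups, ~0 = no structure, negative = samples closer to the other group.
#'
#' @param scores Samples x >=2 score matrix (e.g. from [hdx_pca()]).
#' @param group_labels Factor/character group membership (>= 2 groups, each
#'   with >= 2 samples).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
separation_score <- function(scores, group_labels) {
  g <- as.factor(group_labels)
  if (nlevels(g) < 2L) stop("separation requires at least two groups")
  if (any(table(g) < 2L)) stop("each group needs at least two samples")
  stopifnot(nrow(scores) == length(g), ncol(scores) >= 2L)
  d <- stats::dist(scores[, 1:2, drop = FALSE])
  sil <- cluster::silhouette(as.integer(g), d)
  mean(sil[, "sil_width"])
}
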