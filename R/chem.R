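#' Parse a Hill-style chemical formula
#'
#' Turns a formula string such as `"C18H21NO3"` into a named integer vector of
#' element counts. Implicit counts of 1 are allowed (`"NO3"` means one N,
#' three O). Only element symbols present in the pinned mass table are
#' accepted.
#'
#' @param text A single formula string.
#' @return A named integer vector of class `"hdx_formula"`, one entry per
#'   element, counts >= 1, in order of first appearance.
#' @examples
#' parse_formula("C18H21NO3")
#' parse_formula("H2O")
#' @seealso [format_formula()], [ion_mz()], [natural_pattern()]
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1L]]
  if (m[1L] == -1L) {
    stop(sprintf("malformed formula '%s': unexpected token '%s'",
                 text, substr(text, 1L, 1L)))
  }
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    bad <- substr(text, 1L, 1L)
    # locate first character not consumed by any token
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m)) {
      covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
    }
    bad <- substr(text, which(!covered)[1L], which(!covered)[1L])
    stop(sprintf("malformed formula '%s': unexpected token '%s'", text, bad))
  }
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (is.na(match(sym, names(.ELEMENTS)))) {
      stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
    }
    if (n < 1L) stop(sprintf("element '%s' has count 0 in '%s'", sym, text))
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  structure(counts, class = "hdx_formula")
}

#' @rdname parse_formula
#' @param formula An `hdx_formula` (or named count vector).
#' @export
format_formula <- function(formula) {
  counts <- unclass(formula)
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' @export
print.hdx_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a neutral molecule
#'
#' @param formula An `hdx_formula` or formula string.
#' @return Mass in u (all-lightest isotopologue).
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  counts <- unclass(formula)
  sum(vapply(names(counts), function(s) .ELEMENTS[[s]]$mass, 0) * counts)
}

#' Adduct descriptions for singly charged ESI ions
#'
#' `adduct()` returns a descriptor for one of the supported adducts:
#' `"[M+H]+"`, `"[M+Na]+"`, `"[2M+H]+"`, `"[M-H]-"`. `proton_bearing`
#' records whether the charging species is an exchangeable proton, i.e.
#' whether a charge-site deuteron can appear under HDX ([M+Na]+ cannot).
#'
#' @param name Adduct name string.
#' @return A list of class `"hdx_adduct"` with fields `name`, `mass_delta`
#'   (u), `charge`, `multimer`, `proton_bearing`.
#' @examples
#' adduct("[M+H]+")
#' @export
adduct <- function(name = c("[M+H]+", "[M+Na]+", "[2M+H]+", "[M-H]-")) {
  name <- match.arg(name)
  mH <- .ELEMENTS$H$mass
  mNa <- .ELEMENTS$Na$mass
  spec <- switch(name,
    "[M+H]+"  = list(mass_delta = mH,  charge = 1L,  multimer = 1L, proton_bearing = TRUE),
    "[M+Na]+" = list(mass_delta = mNa, charge = 1L,  multimer = 1L, proton_bearing = FALSE),
    "[2M+H]+" = list(mass_delta = mH,  charge = 1L,  multimer = 2L, proton_bearing = TRUE),
    "[M-H]-"  = list(mass_delta = -mH, charge = -1L, multimer = 1L, proton_bearing = FALSE)
  )
  structure(c(list(name = name), spec), class = "hdx_adduct")
}

#' @export
print.hdx_adduct <- function(x, ...) {
  cat(sprintf("<adduct> %s  dm=%+.5f u  z=%+d  %dM  proton-bearing: %s\n",
              x$name, x$mass_delta, x$charge, x$multimer, x$proton_bearing))
  invisible(x)
}

#' Exact m/z of an adduct ion
#'
#' m/z = (multimer x M + mass_delta - charge x m_e) / |charge|, with M the
#' monoisotopic neutral mass; the electron mass correction is required to
#' reproduce published 4-decimal values.
#'
#' @param formula An `hdx_formula` or formula string.
#' @param adduct An `hdx_adduct` or adduct name string.
#' @return m/z in u at full double precision.
#' @examples
#' round(ion_mz("C18H21NO3", "[M+H]+"), 4) # 300.1594
#' round(ion_mz("C19H21NO4", "[M+H]+"), 4) # 328.1543
#' @export
ion_mz <- function(formula, adduct = "[M+H]+") {
  if (is.character(adduct)) adduct <- hdxladder::adduct(adduct)
  M <- monoisotopic_mass(formula)
  (adduct$multimer * M + adduct$mass_delta - adduct$charge * electron_mass) /
    abs(adduct$charge)
}

#' Relative mass-accuracy match
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @param tol_ppm Tolerance in parts per million (default 5).
#' @return `TRUE` iff `1e6 * |observed - theoretical| / theoretical <= tol_ppm`.
#' @export
ppm_match <- function(observed, theoretical, tol_ppm = 5.0) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  stopifnot(tol_ppm >= 0)
  1e6 * abs(observed - theoretical) / theoretical <= tol_ppm
}

#' Natural isotope pattern of a molecule at unit-mass resolution
#'
#' Relative abundances of the isotopologues grouped by nominal mass offset
#' 0, 1, 2, ... above the monoisotopic (all-lightest) species, computed by
#' per-element polynomial convolution of the pinned isotopic abundances.
#' Offsets are aggregated at unit mass: at the resolving power this package
#' models (R = 120,000, FWHM ~ 0.002 u at m/z 300) 13C, 2H and 15N
#' substitutions are not separated from each other or from a deuterium
#' replacement, so each nominal channel is one merged peak.
#'
#' @param formula An `hdx_formula` or formula string.
#' @param length Number of offsets to return (>= 1).
#' @return Numeric vector of abundances at offsets `0:(length-1)`; the total
#'   over all offsets (untruncated) is 1, so the returned entries sum to <= 1.
#' @examples
#' p <- natural_pattern("C6H12O6", 3)
#' p[2] / p[1] # ~ 6 * 1.08% from 13C plus 2H and absent 15N terms
#' @export
natural_pattern <- function(formula, length = 5L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(length >= 1L)
  counts <- unclass(formula)
  pat <- 1.0
  for (sym in names(counts)) {
    el <- .ELEMENTS[[sym]]
    if (is.null(el)) stop(sprintf("no abundance data for element '%s'", sym))
    a <- el$abund / sum(el$abund)
    for (i in seq_len(counts[[sym]])) {
      pat <- convolve_truncate(pat, a, length)
    }
  }
  out <- numeric(length)
  out[seq_along(pat)] <- pat
  out
}

# discrete convolution truncated to the first `len` offsets
convolve_truncate <- function(x, y, len) {
  n <- min(len, length(x) + length(y) - 1L)
  out <- numeric(n)
  for (i in seq_along(x)) {
    jmax <- min(length(y), n - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + x[i] * y[seq_len(jmax)]
  }
  out
}

#' Natural isotope pattern of an adduct ion
#'
#' Pattern of the full ion composition: `multimer` copies of the molecule
#' plus the adduct atoms (H or Na). The charging proton/sodium contributes
#' its own natural isotopes.
#'
#' @inheritParams ion_mz
#' @param length Number of offsets.
#' @return Numeric abundance vector as in [natural_pattern()].
#' @export
ion_natural_pattern <- function(formula, adduct = "[M+H]+", length = 5L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.character(adduct)) adduct <- hdxladder::adduct(adduct)
  counts <- unclass(formula) * adduct$multimer
  extra <- switch(adduct$name,
    "[M+H]+" = c(H = 1L), "[2M+H]+" = c(H = 1L),
    "[M+Na]+" = c(Na = 1L), "[M-H]-" = c(H = -1L))
  for (sym in names(extra)) {
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + extra[[sym]]
    if (counts[sym] == 0L) counts <- counts[names(counts) != sym]
    if (any(counts < 0L)) stop("adduct removes more atoms than present")
  }
  natural_pattern(structure(counts, class = "hdx_formula"), length)
}
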