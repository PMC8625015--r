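#' Fixture compound library
#'
#' The twelve model compounds shipped with the package (opioid pairs,
#' glucose/inositol, urea, creatinine, sphingosine, palmitoylethanolamide),
#' with formulas, adducts, exchangeable-site sets and nominal abundances
#' read from the packaged compound table. Site classes may carry explicit
#' per-compound probabilities overriding the class defaults (morphine's
#' phenol and hydroxyl exchange noticeably more slowly than naloxone's,
#' consistent with compound-specific back exchange in the liquid phase).
#'
#' @param path Optional alternative compound-table TSV (columns `name`,
#'   `formula`, `adduct`, `exchange_sites` as `class:count` pairs joined by
#'   `;`, optional `site_probs`, `charge_site`, `abundance`).
#' @return Named list of fixtures; each has `name`, `formula`
#'   (`hdx_formula`), `adduct` (`hdx_adduct`), `sites` (`hdx_sites`),
#'   `charge_site` (logical), `abundance`, `mz`.
#' @examples
#' lib <- fixture_library()
#' length(lib[["naloxone"]]$sites$classes) # 2
#' round(lib[["sphingosine"]]$mz, 4)       # 300.2897
#' @export
fixture_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compounds.tsv", package = "hdxladder")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    classes <- character(0)
    if (nzchar(trimws(row$exchange_sites))) {
      for (tok in strsplit(row$exchange_sites, ";", fixed = TRUE)[[1L]]) {
        kv <- strsplit(tok, ":", fixed = TRUE)[[1L]]
        classes <- c(classes, rep(kv[1L], as.integer(kv[2L])))
      }
    }
    probs <- rep(NA_real_, length(classes))
    if (!is.na(row$site_probs) && nzchar(trimws(row$site_probs))) {
      for (tok in strsplit(row$site_probs, ";", fixed = TRUE)[[1L]]) {
        kv <- strsplit(tok, ":", fixed = TRUE)[[1L]]
        probs[classes == kv[1L]] <- as.numeric(kv[2L])
      }
    }
    ad <- adduct(row$adduct)
    list(name = row$name,
         formula = parse_formula(row$formula),
         adduct = ad,
         sites = exchange_sites(classes, probs, compound = row$name),
         charge_site = isTRUE(row$charge_site),
         abundance = row$abundance,
         mz = ion_mz(row$formula, ad))
  })
  stats::setNames(out, tab$name)
}

# noiseless per-mole ladder of a fixture under given conditions
fixture_ladder <- function(fx, cond = NULL, scale = 1) {
  if (is.null(cond)) cond <- hdx_conditions(charge_site_exchange = fx$charge_site)
  cond$charge_site_exchange <- cond$charge_site_exchange && fx$charge_site
  simulate_ladder(fx$formula, fx$adduct, fx$sites, cond,
                  instrument_model(noise_cv = 0, intensity_floor = 0),
                  scale = scale)
}

# embed ladders into one centroided spectrum
ladders_to_spectrum <- function(ladders, sample_id = NA_character_,
                                extra_mz = numeric(0),
                                extra_intensity = numeric(0)) {
  mz <- c(unlist(lapply(ladders, ladder_mz)), extra_mz)
  it <- c(unlist(lapply(ladders, `[[`, "channels")), extra_intensity)
  keep <- it > 0
  hdx_spectrum(mz[keep], it[keep], sample_id = sample_id)
}

#' Synthetic two-component isobaric mixture spectra
#'
#' Simulates mixture spectra of an isobaric pair at given molar ratios:
#' noiseless per-mole pure ladders are combined linearly
#' (`I = N_g*I_g + N_i*I_i`), multiplicative log-normal channel noise is
#' applied, and each mixture is embedded in a spectrum. The truth table
#' records the true mole fractions.
#'
#' @param pair Character vector of two fixture names (default glucose,
#'   inositol).
#' @param ratios List of length-2 positive molar ratio vectors.
#' @param total_conc Total molar concentration (arbitrary units; sets the
#'   absolute intensity scale).
#' @param noise_cv Channel noise CV.
#' @param seed Integer seed.
#' @return List with `spectra` (list of [hdx_spectrum]), `truth` (data frame
#'   with ratio label and true fractions), `pure` (the two noiseless
#'   per-mole pure [hdx_ladder]s), `precursor_mz`.
#' @export
generate_mixture_samples <- function(pair = c("glucose", "inositol"),
                                     ratios = list(c(2, 2), c(1, 3), c(3, 1)),
                                     total_conc = 100, noise_cv = 0.03,
                                     seed = 1L) {
  lib <- fixture_library()
  stopifnot(all(pair %in% names(lib)), length(pair) == 2L)
  stopifnot(all(vapply(ratios, function(r) length(r) == 2L && all(r > 0), TRUE)))
  fg <- lib[[pair[1L]]]; fi <- lib[[pair[2L]]]
  pure_g <- fixture_ladder(fg); pure_i <- fixture_ladder(fi)
  with_seed(seed, {
    spectra <- list(); truth <- NULL
    for (r in ratios) {
      f <- r / sum(r)
      mixed <- mix_patterns(pure_g, pure_i, f[1L] * total_conc,
                            f[2L] * total_conc)
      noisy <- mixed
      noisy$channels <- mixed$channels *
        lognormal_factors(length(mixed$channels), noise_cv)
      noisy$relative <- 100 * noisy$channels / max(noisy$channels)
      id <- sprintf("%s_%g:%g", paste(pair, collapse = "-"), r[1L], r[2L])
      spectra[[id]] <- ladders_to_spectrum(list(noisy), sample_id = id)
      truth <- rbind(truth, data.frame(
        sample_id = id, ratio = sprintf("%g:%g", r[1L], r[2L]),
        frac_g = f[1L], frac_i = f[2L]))
    }
    list(spectra = spectra, truth = truth,
         pure = stats::setNames(list(pure_g, pure_i), pair),
         precursor_mz = fg$mz)
  })
}

#' Synthetic internal-standard calibration series
#'
#' Emulates the absolute-quantitation experiment: a dilution series of the
#' target is spiked with a fixed amount of an isobaric interferent and a
#' fixed internal standard; the response is the target's signature deuterium
#' channel (the lowest channel free of interferent deuteration) ratioed to
#' the internal standard's base deuterium channel. Before noise, the
#' signature response is strictly proportional to the target amount plus a
#' constant interferent natural-isotope offset.
#'
#' @param target,interferent,is_compound Fixture names (defaults: codeine,
#'   hydrocodone, 6-acetylmorphine).
#' @param levels Target concentrations.
#' @param interferent_conc,is_conc Fixed spike concentrations.
#' @param noise_cv Proportional channel noise CV.
#' @param seed Integer seed.
#' @return List with `points` (data frame concentration/response),
#'   `signature_k` (target signature channel), `is_k` (IS response channel),
#'   `spectra` (one [hdx_spectrum] per level), `units`.
#' @export
generate_calibration_series <- function(target = "codeine",
                                        interferent = "hydrocodone",
                                        is_compound = "6-acetylmorphine",
                                        levels = c(5, 10, 20, 50, 100, 200),
                                        interferent_conc = 35, is_conc = 50,
                                        noise_cv = 0.005, seed = 1L) {
  stopifnot(length(levels) >= 3L)
  lib <- fixture_library()
  ft <- lib[[target]]; fn <- lib[[interferent]]; fis <- lib[[is_compound]]
  pure_t <- fixture_ladder(ft); pure_n <- fixture_ladder(fn)
  pure_is <- fixture_ladder(fis)
  jt <- judge_deuteration(pure_t, ft$formula, ft$adduct,
                          charge_site = ft$charge_site)
  jn <- judge_deuteration(pure_n, fn$formula, fn$adduct,
                          charge_site = fn$charge_site)
  sig_k <- signature_channel(jt, jn)
  jis <- judge_deuteration(pure_is, fis$formula, fis$adduct,
                           charge_site = fis$charge_site)
  # IS response channel: its most intense deuterium channel
  is_k <- jis$flagged[which.max(pure_is$channels[jis$flagged + 1L])]
  with_seed(seed, {
    spectra <- list(); resp <- numeric(length(levels))
    for (i in seq_along(levels)) {
      mixed <- mix_patterns(pure_t, pure_n, levels[i], interferent_conc)
      mixed$channels <- mixed$channels *
        lognormal_factors(length(mixed$channels), noise_cv)
      isl <- pure_is
      isl$channels <- is_conc * isl$channels *
        lognormal_factors(length(isl$channels), noise_cv)
      id <- sprintf("cal_%g", levels[i])
      spectra[[id]] <- ladders_to_spectrum(list(mixed, isl), sample_id = id)
      resp[i] <- mixed$channels[sig_k + 1L] / isl$channels[is_k + 1L]
    }
    list(points = data.frame(concentration = levels, response = resp),
         signature_k = sig_k, is_k = is_k, spectra = spectra,
         units = "ug/mL")
  })
}

#' Synthetic two-group urine-like cohort
#'
#' Generates per-sample post-HDX spectra over the twelve-compound fixture
#' panel plus non-deuterating decoy background ions. The case group differs
#' from the control group in (a) a stronger back exchange (lower effective
#' deuteration) for designated exchange-marker ions (urea and creatinine by
#' default) and (b) an abundance multiplier on those markers; everything
#' else is shared biology: per-sample log-normal abundance scatter and
#' per-channel intensity noise. All randomness is seeded. Spectra are
#' TIC-normalized.
#'
#' @param n_cases,n_controls Group sizes (>= 2 each).
#' @param markers Fixture names whose deuteration/abundance differ between
#'   groups.
#' @param case_back_exchange,control_back_exchange Back-exchange factors for
#'   the marker ladders per group.
#' @param marker_abundance_multiplier Case-group abundance multiplier for
#'   markers.
#' @param abundance_cv Between-sample log-normal abundance CV.
#' @param noise_cv Per-channel intensity noise CV.
#' @param n_decoys Number of non-deuterating background ions (random m/z in
#'   50-300).
#' @param seed Integer seed.
#' @return List with `spectra` (post-HDX, TIC-normalized, one per sample),
#'   `spectra_pre` (the same samples sprayed without D2O: plain profiles,
#'   natural isotopes only, sharing each sample's abundance draws), `groups`
#'   (data frame sample_id/group with levels `"case"`, `"control"`),
#'   `panel` (the fixture precursor data frame), `decoy_mz`.
#' @export
generate_cohort <- function(n_cases = 30L, n_controls = 9L,
                            markers = c("urea", "creatinine"),
                            case_back_exchange = 0.3,
                            control_back_exchange = 1.0,
                            marker_abundance_multiplier = 1.2,
                            abundance_cv = 0.4, noise_cv = 0.05,
                            n_decoys = 30L, seed = 1L) {
  stopifnot(n_cases >= 2L, n_controls >= 2L,
            marker_abundance_multiplier > 0)
  lib <- fixture_library()
  stopifnot(all(markers %in% names(lib)))
  groups <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(n_cases)),
                  sprintf("control_%02d", seq_len(n_controls))),
    group = rep(c("case", "control"), c(n_cases, n_controls)))
  with_seed(seed, {
    decoy_mz <- sort(stats::runif(n_decoys, 50, 300))
    decoy_base <- stats::runif(n_decoys, 5, 60)
    spectra <- spectra_pre <- vector("list", nrow(groups))
    cond_pre <- hdx_conditions(d2o_fraction = 0, charge_site_exchange = FALSE)
    for (s in seq_len(nrow(groups))) {
      is_case <- groups$group[s] == "case"
      ladders <- ladders_pre <- list()
      for (fx in lib) {
        beta <- if (fx$name %in% markers) {
          if (is_case) case_back_exchange else control_back_exchange
        } else 1.0
        cond <- hdx_conditions(back_exchange_factor = beta,
                               charge_site_exchange = fx$charge_site)
        inst <- instrument_model(noise_cv = noise_cv,
                                 seed = sample.int(.Machine$integer.max, 1L))
        inst_pre <- instrument_model(noise_cv = noise_cv,
                                     seed = sample.int(.Machine$integer.max, 1L))
        ab <- fx$abundance *
          (if (is_case && fx$name %in% markers) marker_abundance_multiplier else 1) *
          lognormal_factors(1L, abundance_cv)
        ladders[[fx$name]] <- simulate_ladder(fx$formula, fx$adduct, fx$sites,
                                              cond, inst, scale = ab)
        ladders_pre[[fx$name]] <- simulate_ladder(fx$formula, fx$adduct,
                                                  fx$sites, cond_pre, inst_pre,
                                                  scale = ab)
      }
      dec <- decoy_base * lognormal_factors(n_decoys, abundance_cv)
      sp <- ladders_to_spectrum(ladders, sample_id = groups$sample_id[s],
                                extra_mz = decoy_mz, extra_intensity = dec)
      spectra[[s]] <- tic_normalize(sp)
      sp_pre <- ladders_to_spectrum(ladders_pre,
                                    sample_id = groups$sample_id[s],
                                    extra_mz = decoy_mz, extra_intensity = dec)
      spectra_pre[[s]] <- tic_normalize(sp_pre)
    }
    panel <- data.frame(
      name = vapply(lib, `[[`, "", "name"),
      formula = vapply(lib, function(f) format_formula(f$formula), ""),
      adduct = vapply(lib, function(f) f$adduct$name, ""),
      charge_site = vapply(lib, `[[`, TRUE, "charge_site"),
      mz = vapply(lib, `[[`, 0, "mz"),
      row.names = NULL)
    # isobaric pairs share one observable ion: one panel row per unique m/z
    panel <- panel[!duplicated(round(panel$mz, 4)), , drop = FALSE]
    panel$mz <- NULL
    list(spectra = spectra, spectra_pre = spectra_pre, groups = groups,
         panel = panel, decoy_mz = decoy_mz)
  })
}
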