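#' Default exchange probabilities per functional-group class
#'
#' Per-site probabilities that a labile proton of the given class is observed
#' as deuterium after microdroplet HDX, calibrated for the reference spray
#' condition (methanol/D2O 7:3 v/v, i.e. 30% D2O aqueous component, no extra
#' back exchange). `charge_site` is the probability that the charging proton
#' of a proton-bearing adduct is a deuteron. Values are read once from the
#' packaged YAML config (`inst/extdata/exchange_rates.yaml`) and can be
#' overridden per call.
#'
#' @param path Optional path to an alternative YAML config.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
exchange_rate_defaults <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exchange_rates.yaml", package = "hdxladder")
  }
  cfg <- yaml::read_yaml(path)
  p <- unlist(cfg$exchange_probability)
  stopifnot(all(p >= 0), all(p <= 1))
  p
}

.SITE_CLASSES <- c("hydroxyl", "phenol", "amine", "imine_NH", "amide_NH", "carboxyl")

#' Exchangeable-site set of a compound
#'
#' @param classes Character vector of site classes, one entry per labile
#'   proton (repeat a class for multiple protons); may be empty for compounds
#'   with no exchangeable proton (e.g. hydrocodone).
#' @param probabilities Optional per-site probabilities overriding the class
#'   defaults; `NA` entries fall back to the class default.
#' @param compound Optional compound name.
#' @return List of class `"hdx_sites"` with `classes`, `probabilities`,
#'   `compound`.
#' @examples
#' exchange_sites(c("phenol", "hydroxyl"), compound = "naloxone")
#' exchange_sites(character(0), compound = "hydrocodone")
#' @export
exchange_sites <- function(classes = character(0), probabilities = NULL,
                           compound = NULL) {
  stopifnot(all(classes %in% .SITE_CLASSES))
  if (is.null(probabilities)) probabilities <- rep(NA_real_, length(classes))
  stopifnot(length(probabilities) == length(classes))
  stopifnot(all(is.na(probabilities) | (probabilities >= 0 & probabilities <= 1)))
  structure(list(classes = classes, probabilities = as.numeric(probabilities),
                 compound = compound), class = "hdx_sites")
}

#' @export
print.hdx_sites <- function(x, ...) {
  cat(sprintf("<exchange sites> %s: %s\n",
              if (is.null(x$compound)) "?" else x$compound,
              if (length(x$classes)) paste(x$classes, collapse = ", ") else "(none)"))
  invisible(x)
}

#' HDX spray conditions
#'
#' @param d2o_fraction Volume fraction of D2O in the aqueous part of the
#'   spray solvent (reference condition 0.3, per methanol-D2O 7:3).
#' @param back_exchange_factor Multiplicative attenuation in `[0, 1]` for
#'   liquid-phase back exchange (1 = none).
#' @param charge_site_exchange Whether the charging proton of proton-bearing
#'   adducts may exchange.
#' @param charge_site_probability Probability that it does.
#' @param phase `"liquid"` or `"gas"`; gas-phase exchange is fast and free of
#'   back exchange, so every site probability becomes 1.
#' @return List of class `"hdx_conditions"`.
#' @export
hdx_conditions <- function(d2o_fraction = 0.3, back_exchange_factor = 1,
                           charge_site_exchange = TRUE,
                           charge_site_probability = NULL,
                           phase = c("liquid", "gas")) {
  phase <- match.arg(phase)
  if (is.null(charge_site_probability)) {
    charge_site_probability <- unname(exchange_rate_defaults()["charge_site"])
  }
  stopifnot(d2o_fraction >= 0, d2o_fraction <= 1,
            back_exchange_factor >= 0, back_exchange_factor <= 1,
            charge_site_probability >= 0, charge_site_probability <= 1)
  if (phase == "gas") back_exchange_factor <- 1
  structure(list(d2o_fraction = d2o_fraction,
                 back_exchange_factor = back_exchange_factor,
                 charge_site_exchange = charge_site_exchange,
                 charge_site_probability = charge_site_probability,
                 phase = phase),
            class = "hdx_conditions")
}

#' Effective per-site exchange probabilities under given conditions
#'
#' Liquid phase: `p_class * (d2o_fraction / 0.3) * back_exchange_factor`,
#' clamped to `[0, 1]` (class defaults are calibrated at 30% D2O). Gas phase:
#' all probabilities are 1 — fast exchange without back exchange erases the
#' functional-group dependence, which is why gas-phase ladders of isobars
#' with equal site counts coincide.
#'
#' @param sites An `hdx_sites` object.
#' @param cond An `hdx_conditions` object.
#' @param rates Named class-default probabilities (see
#'   [exchange_rate_defaults()]).
#' @return Numeric vector, one probability per site.
#' @export
effective_probabilities <- function(sites, cond = hdx_conditions(),
                                    rates = exchange_rate_defaults()) {
  stopifnot(inherits(sites, "hdx_sites"), inherits(cond, "hdx_conditions"))
  if (length(sites$classes) == 0L) return(numeric(0))
  if (cond$phase == "gas") return(rep(1, length(sites$classes)))
  p <- sites$probabilities
  miss <- is.na(p)
  p[miss] <- unname(rates[sites$classes[miss]])
  pmin(pmax(p * (cond$d2o_fraction / 0.3) * cond$back_exchange_factor, 0), 1)
}

#' Poisson-binomial deuterium-count distribution
#'
#' Distribution of the number of exchanged positions among independent,
#' non-identical Bernoulli sites, computed by iterative convolution (dynamic
#' programming). The charge-site deuteron, when present, is one extra
#' independent Bernoulli trial.
#'
#' @param probabilities Per-site success probabilities in `[0, 1]`.
#' @param charge_extra Optional probability for the charge-site trial
#'   (`NULL` to omit).
#' @return Numeric pmf over deuterium counts `0:n`, summing to 1, where
#'   `n = length(probabilities) + !is.null(charge_extra)`.
#' @examples
#' deuterium_distribution(numeric(0), charge_extra = 0.6) # c(0.4, 0.6)
#' @export
deuterium_distribution <- function(probabilities, charge_extra = NULL) {
  p <- as.numeric(probabilities)
  stopifnot(all(p >= 0), all(p <= 1))
  if (!is.null(charge_extra)) {
    stopifnot(charge_extra >= 0, charge_extra <= 1)
    p <- c(p, charge_extra)
  }
  pmf <- 1.0
  for (pi in p) {
    pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  }
  pmf
}

#' Instrument and noise model
#'
#' @param resolution Mass resolving power (default 120000); recorded for
#'   provenance, centroided channels are already unit-mass merged.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   intensity noise per channel (0 = noiseless).
#' @param intensity_floor Channels below `intensity_floor * max` are dropped.
#' @param seed Integer seed making the noise reproducible.
#' @return List of class `"hdx_instrument"`.
#' @export
instrument_model <- function(resolution = 120000, noise_cv = 0.05,
                             intensity_floor = 1e-4, seed = 1L) {
  stopifnot(resolution > 0, noise_cv >= 0,
            intensity_floor >= 0, intensity_floor < 1)
  structure(list(resolution = resolution, noise_cv = noise_cv,
                 intensity_floor = intensity_floor, seed = as.integer(seed)),
            class = "hdx_instrument")
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# mean-one multiplicative log-normal factors with coefficient of variation cv
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Forward-simulate the post-HDX isotope ladder of an ion
#'
#' Channel intensity at offset k is the discrete convolution of the
#' Poisson-binomial deuterium-count pmf with the ion's natural isotope
#' pattern: `I(k) = sum_{d+j=k} pmf(d) * natural(j)`. This models the fact
#' that a deuterium peak and the natural 13C/2H/15N isotopologues merge into
#' one unit-mass channel at the instrument's resolution. Multiplicative
#' log-normal noise (CV = `instrument$noise_cv`) is applied per channel,
#' seeded; channels below the intensity floor are dropped (set to zero).
#' For `[2M+H]+` multimers the site set is doubled — both monomer units
#' exchange.
#'
#' @param formula,adduct Ion definition (string or parsed forms).
#' @param sites An `hdx_sites` object.
#' @param cond An `hdx_conditions` object.
#' @param instrument An `hdx_instrument` object.
#' @param scale Total absolute intensity of the ladder (per-mole scale for
#'   mixture work).
#' @param extra_length Natural-pattern tail length beyond the deuterium
#'   channels (default 3).
#' @return An [hdx_ladder] with absolute-intensity channels.
#' @examples
#' lad <- simulate_ladder("C18H21NO3", "[M+H]+",
#'   exchange_sites("hydroxyl", compound = "codeine"),
#'   instrument = instrument_model(noise_cv = 0))
#' base_peak_index(lad)
#' @export
simulate_ladder <- function(formula, adduct = "[M+H]+",
                            sites = exchange_sites(),
                            cond = hdx_conditions(),
                            instrument = instrument_model(),
                            scale = 100, extra_length = 3L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.character(adduct)) adduct <- hdxladder::adduct(adduct)
  stopifnot(inherits(sites, "hdx_sites"), inherits(cond, "hdx_conditions"),
            inherits(instrument, "hdx_instrument"))
  eff <- effective_probabilities(sites, cond)
  if (adduct$multimer > 1L) eff <- rep(eff, adduct$multimer)
  charge_extra <- NULL
  if (adduct$proton_bearing && cond$charge_site_exchange) {
    # the charging proton is as labile as any site: same D2O availability and
    # back-exchange attenuation apply in the liquid phase
    charge_extra <- if (cond$phase == "gas") 1 else
      min(max(cond$charge_site_probability * (cond$d2o_fraction / 0.3) *
                cond$back_exchange_factor, 0), 1)
  }
  pmf <- deuterium_distribution(eff, charge_extra)
  len <- length(pmf) + as.integer(extra_length)
  nat <- ion_natural_pattern(formula, adduct, length = len)
  chan <- convolve_truncate(pmf, nat, len)
  chan <- chan * scale / sum(chan)
  noisy <- with_seed(instrument$seed,
                     chan * lognormal_factors(length(chan), instrument$noise_cv))
  noisy[noisy < instrument$intensity_floor * max(noisy)] <- 0
  hdx_ladder(precursor_mz = ion_mz(formula, adduct), channels = noisy,
             compound = sites$compound)
}

#' Replicate ladder simulations with independent seeded noise
#'
#' @inheritParams simulate_ladder
#' @param n_reps Number of replicates (>= 2).
#' @return List of [hdx_ladder]s; deterministic given `instrument$seed`
#'   (replicate r uses seed `seed + r - 1`).
#' @export
replicate_ladders <- function(formula, adduct = "[M+H]+",
                              sites = exchange_sites(),
                              cond = hdx_conditions(),
                              instrument = instrument_model(),
                              n_reps = 10L, ...) {
  if (n_reps < 2L) stop("n_reps must be >= 2")
  lapply(seq_len(n_reps) - 1L, function(r) {
    inst <- instrument
    inst$seed <- instrument$seed + r
    simulate_ladder(formula, adduct, sites, cond, inst, ...)
  })
}
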