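# simulate a fixture and embed it in a spectrum
sim_fixture_spectrum <- function(name, noise_cv = 0, seed = 1) {
  fx <- fixture_library()[[name]]
  cond <- hdx_conditions(charge_site_exchange = fx$charge_site)
  lad <- simulate_ladder(fx$formula, fx$adduct, fx$sites, cond,
                         instrument_model(noise_cv = noise_cv, seed = seed,
                                          intensity_floor = 0))
  list(fx = fx, ladder = lad,
       spectrum = hdx_spectrum(ladder_mz(lad), lad$channels))
}

test_that("find_ladder recovers simulated ladders exactly (noiseless)", {
  s <- sim_fixture_spectrum("codeine")
  lad <- find_ladder(s$spectrum, s$fx$mz, max_k = 8)
  expect_true(all(lad$channels[1:3] > 0)) # D0..D2 populated
  n <- min(length(lad$channels), length(s$ladder$channels))
  expect_equal(lad$channels[1:n], s$ladder$channels[1:n], tolerance = 1e-12)

  for (name in c("naloxone", "glucose", "urea")) {
    s <- sim_fixture_spectrum(name)
    lad <- find_ladder(s$spectrum, s$fx$mz, max_k = 12)
    n <- min(length(lad$channels), length(s$ladder$channels))
    expect_equal(lad$channels[1:n], s$ladder$channels[1:n],
                 tolerance = 1e-12, label = name)
  }
})

test_that("find_ladder window semantics: lone precursors and near-miss peaks", {
  sp <- hdx_spectrum(300.1594, 42)
  lad <- find_ladder(sp, 300.1594)
  expect_equal(lad$relative, 100)
  expect_equal(lad$n, 0L)

  # a 13C neighbor of another species at +1.0075: outside 1.0063 +/- 0.0002
  sp2 <- hdx_spectrum(c(300.1594, 300.1594 + 1.0075), c(42, 10))
  lad2 <- find_ladder(sp2, 300.1594)
  expect_equal(lad2$n, 0L)

  expect_error(find_ladder(sp, 310.0), "not found")
})

test_that("natural correction inverts the forward convolution", {
  # unlabeled compound: ladder is the bare natural pattern -> delta at 0
  nat <- ion_natural_pattern("C18H21NO3", "[M+H]+", 5)
  lad <- hdx_ladder(300.1594, nat)
  pmf <- natural_correction(lad, "C18H21NO3", "[M+H]+")
  expect_equal(pmf, c(1, 0, 0, 0, 0), tolerance = 1e-9)

  # round-trip with the forward model
  for (name in c("morphine", "inositol", "creatinine")) {
    s <- sim_fixture_spectrum(name)
    fx <- s$fx
    cond <- hdx_conditions(charge_site_exchange = fx$charge_site)
    true_pmf <- deuterium_distribution(
      effective_probabilities(fx$sites, cond),
      charge_extra = if (fx$charge_site && fx$adduct$proton_bearing)
        cond$charge_site_probability else NULL)
    if (fx$adduct$multimer > 1L) {
      true_pmf <- deuterium_distribution(
        rep(effective_probabilities(fx$sites, cond), fx$adduct$multimer),
        charge_extra = cond$charge_site_probability)
    }
    est <- natural_correction(s$ladder, fx$formula, fx$adduct)
    n <- min(length(est), length(true_pmf))
    expect_equal(est[1:n], true_pmf[1:n], tolerance = 1e-9, label = name)
  }
})

test_that("forward substitution matches hand-worked 3-channel algebra", {
  # natural pattern n = (n0, n1, n2); observed I = pmf (*) n with
  # pmf = (0.5, 0.3, 0.2):
  n <- ion_natural_pattern("C2H6O", "[M+H]+", 3)
  I <- c(0.5 * n[1],
         0.5 * n[2] + 0.3 * n[1],
         0.5 * n[3] + 0.3 * n[2] + 0.2 * n[1])
  lad <- hdx_ladder(47.0491, I)
  expect_equal(natural_correction(lad, "C2H6O", "[M+H]+"),
               c(0.5, 0.3, 0.2), tolerance = 1e-9)
})

test_that("deuteration judgment reproduces the opioid site counts", {
  expected <- c(codeine = 1L, hydrocodone = 0L, `6-acetylmorphine` = 1L,
                naloxone = 2L, morphine = 2L, norcodeine = 2L)
  lib <- fixture_library()
  for (name in names(expected)) {
    s <- sim_fixture_spectrum(name)
    j <- judge_deuteration(s$ladder, s$fx$formula, s$fx$adduct)
    expect_identical(j$site_count_estimate, expected[[name]], label = name)
  }

  # hydrocodone: zero sites, exactly one deuterated peak (the charge deuteron)
  s <- sim_fixture_spectrum("hydrocodone")
  j <- judge_deuteration(s$ladder, s$fx$formula, s$fx$adduct)
  expect_identical(j$flagged, 1L)

  # naloxone has exactly one more deuterium peak than 6-acetylmorphine
  jn <- with(sim_fixture_spectrum("naloxone"),
             judge_deuteration(ladder, fx$formula, fx$adduct))
  ja <- with(sim_fixture_spectrum("6-acetylmorphine"),
             judge_deuteration(ladder, fx$formula, fx$adduct))
  expect_identical(length(jn$flagged), length(ja$flagged) + 1L)
})

test_that("judgment handles the no-excess case", {
  nat <- ion_natural_pattern("C6H12O6", "[M+H]+", 4)
  lad <- hdx_ladder(181.0707, nat)
  j <- judge_deuteration(lad, "C6H12O6", "[M+H]+")
  expect_length(j$flagged, 0)
  expect_identical(j$site_count_estimate, 0L)
})

test_that("base peaks fall where the exchange kinetics put them", {
  expect_identical(base_peak_index(sim_fixture_spectrum("naloxone")$ladder), 1L)
  expect_identical(base_peak_index(sim_fixture_spectrum("morphine")$ladder), 0L)
  expect_identical(base_peak_index(sim_fixture_spectrum("norcodeine")$ladder), 1L)
  expect_identical(base_peak_index(sim_fixture_spectrum("glucose")$ladder), 2L)
  expect_identical(base_peak_index(sim_fixture_spectrum("inositol")$ladder), 3L)
  # ties break toward smaller k
  expect_identical(base_peak_index(hdx_ladder(100, c(50, 100, 100))), 1L)
})

test_that("ranking by deuteration surfaces the most exchanged ions", {
  coh <- generate_cohort(n_cases = 3, n_controls = 3, seed = 5)
  ranked <- rank_by_deuteration(coh$spectra, coh$panel, top_n = 3, max_k = 12)
  expect_true("urea" %in% ranked$name[1:2])
  expect_equal(nrow(ranked), 3)

  one <- rank_by_deuteration(coh$spectra, coh$panel[coh$panel$name == "urea", ],
                             top_n = 5, max_k = 12)
  expect_equal(nrow(one), 1) # top_n larger than the candidate list
  expect_identical(one$name, "urea")
})
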