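test_that("the fixture library carries the documented chemistry", {
  lib <- fixture_library()
  expect_length(lib, 12)
  expect_length(lib[["naloxone"]]$sites$classes, 2)
  expect_length(lib[["hydrocodone"]]$sites$classes, 0)
  expect_equal(round(lib[["sphingosine"]]$mz, 4), 300.2897)
  expect_equal(round(lib[["palmitoylethanolamide"]]$mz, 4), 322.2717)
  expect_identical(lib[["urea"]]$adduct$name, "[2M+H]+")
  expect_false(lib[["palmitoylethanolamide"]]$adduct$proton_bearing)
  # isobaric pairs share exact precursor m/z
  expect_equal(lib[["codeine"]]$mz, lib[["hydrocodone"]]$mz)
  expect_equal(lib[["glucose"]]$mz, lib[["inositol"]]$mz)
})

test_that("mixture generation is seeded and honest about its truth table", {
  gen <- generate_mixture_samples(noise_cv = 0.03, seed = 21)
  gen2 <- generate_mixture_samples(noise_cv = 0.03, seed = 21)
  expect_identical(gen, gen2)
  expect_equal(gen$truth$frac_g, c(0.5, 0.25, 0.75))

  # noiseless limit: deconvolution recovers the truth exactly
  gen0 <- generate_mixture_samples(noise_cv = 0, seed = 1)
  for (i in 1:3) {
    lad <- find_ladder(gen0$spectra[[gen0$truth$sample_id[i]]],
                       gen0$precursor_mz, max_k = 9)
    fit <- estimate_composition(lad, gen0$pure[[1]], gen0$pure[[2]])
    expect_equal(unname(coef(fit)[1]), gen0$truth$frac_g[i], tolerance = 1e-3)
  }
})

test_that("calibration series: proportional signature response over six levels", {
  cal <- generate_calibration_series(noise_cv = 0, seed = 2)
  expect_equal(nrow(cal$points), 6)
  expect_equal(cal$points$concentration, c(5, 10, 20, 50, 100, 200))
  expect_identical(cal$signature_k, 2L)

  # the zero-target response is the constant interferent isotope baseline;
  # above it, the signature response is strictly proportional to the target
  base <- generate_calibration_series(levels = c(0, 1, 2), noise_cv = 0,
                                      seed = 2)$points$response[1]
  resid <- cal$points$response - base
  expect_gt(min(resid), 0)
  expect_equal(stats::sd(resid / cal$points$concentration) /
                 mean(resid / cal$points$concentration), 0, tolerance = 1e-9)
})

test_that("cohort generation is seeded, sized and structured as specified", {
  coh <- generate_cohort(n_cases = 30, n_controls = 9, seed = 3)
  expect_length(coh$spectra, 39)
  expect_length(coh$spectra_pre, 39)
  expect_identical(table(coh$groups$group),
                   table(factor(rep(c("case", "control"), c(30, 9)))))
  # TIC-normalized output
  for (s in coh$spectra[c(1, 39)]) {
    expect_equal(sum(s$intensity), 100, tolerance = 1e-9)
  }
  coh2 <- generate_cohort(n_cases = 30, n_controls = 9, seed = 3)
  expect_identical(coh, coh2)

  # pre-HDX spectra carry no deuterium excess
  avg_pre <- average_spectra(coh$spectra_pre)
  pm <- ion_mz("CH4N2O", "[2M+H]+")
  lad <- find_ladder(avg_pre, pm, max_k = 10)
  j <- judge_deuteration(lad, "CH4N2O", "[2M+H]+")
  expect_length(j$flagged, 0)
})

test_that("a null cohort (equal group parameters) shows no separation", {
  coh <- generate_cohort(n_cases = 6, n_controls = 6,
                         case_back_exchange = 1, control_back_exchange = 1,
                         marker_abundance_multiplier = 1, seed = 13)
  m <- build_features(coh$spectra, coh$panel, include_deuterium = TRUE,
                      max_k = 12)
  sil <- separation_score(hdx_pca(m)$scores, coh$groups$group)
  expect_lt(abs(sil), 0.25)
})

test_that("generated ladders reproduce the fixture site counts (noiseless)", {
  lib <- fixture_library()
  for (name in c("codeine", "naloxone", "glucose", "inositol", "creatinine")) {
    fx <- lib[[name]]
    lad <- simulate_ladder(fx$formula, fx$adduct, fx$sites,
                           hdx_conditions(charge_site_exchange = fx$charge_site),
                           instrument_model(noise_cv = 0, intensity_floor = 0))
    j <- judge_deuteration(lad, fx$formula, fx$adduct,
                           charge_site = fx$charge_site)
    expect_identical(j$site_count_estimate, length(fx$sites$classes),
                     label = name)
  }
})
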