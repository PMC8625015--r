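test_that("effective probabilities follow phase, D2O fraction and back exchange", {
  sites <- exchange_sites(c("hydroxyl", "phenol", "amide_NH"))
  gas <- hdx_conditions(phase = "gas")
  expect_equal(effective_probabilities(sites, gas), c(1, 1, 1))

  dead <- hdx_conditions(back_exchange_factor = 0)
  expect_equal(effective_probabilities(sites, dead), c(0, 0, 0))

  cond <- hdx_conditions()
  p <- effective_probabilities(exchange_sites(c("hydroxyl", "phenol")), cond)
  expect_gt(p[1], p[2]) # hydroxyls exchange faster than phenols

  half <- hdx_conditions(d2o_fraction = 0.15)
  expect_equal(effective_probabilities(sites, half),
               effective_probabilities(sites, cond) / 2)

  expect_equal(effective_probabilities(exchange_sites(), cond), numeric(0))
})

test_that("per-site probability overrides take precedence over class defaults", {
  s <- exchange_sites(c("phenol", "hydroxyl"), probabilities = c(0.13, NA))
  p <- effective_probabilities(s, hdx_conditions())
  expect_equal(p[1], 0.13)
  expect_equal(p[2], unname(exchange_rate_defaults()["hydroxyl"]))
})

test_that("Poisson-binomial pmf matches forced arithmetic and enumeration", {
  expect_equal(deuterium_distribution(numeric(0), charge_extra = 0.6),
               c(0.4, 0.6))
  expect_equal(deuterium_distribution(c(1, 1, 1)), c(0, 0, 0, 1))
  expect_equal(deuterium_distribution(c(0.3, 0.5, 0.8)),
               enum_poisson_binomial(c(0.3, 0.5, 0.8)), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:25) {
    p <- stats::runif(sample(0:10, 1))
    pmf <- deuterium_distribution(p)
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    expect_true(all(pmf >= 0))
    expect_equal(pmf, enum_poisson_binomial(p), tolerance = 1e-12)
  }
})

test_that("raising any site probability cannot decrease the mean deuteration", {
  set.seed(7)
  for (i in 1:20) {
    p <- stats::runif(5)
    j <- sample(5, 1)
    q <- p
    q[j] <- min(1, p[j] + stats::runif(1) * (1 - p[j]))
    mean_of <- function(pr) {
      pmf <- deuterium_distribution(pr)
      sum((seq_along(pmf) - 1) * pmf)
    }
    expect_gte(mean_of(q), mean_of(p) - 1e-12)
  }
})

test_that("noiseless ladder equals the oracle convolution of pmf and natural pattern", {
  lib <- fixture_library()
  fx <- lib[["codeine"]]
  cond <- hdx_conditions()
  lad <- simulate_ladder(fx$formula, fx$adduct, fx$sites, cond,
                         instrument_model(noise_cv = 0, intensity_floor = 0),
                         scale = 1)
  pmf <- deuterium_distribution(effective_probabilities(fx$sites, cond),
                                charge_extra = cond$charge_site_probability)
  nat <- ion_natural_pattern(fx$formula, fx$adduct, length(lad$channels))
  oracle <- brute_convolve(pmf, nat, length(lad$channels))
  expect_equal(lad$channels, oracle / sum(oracle), tolerance = 1e-12)
  expect_true(all(lad$channels >= 0))
})

test_that("no-HDX limit reproduces the pure natural pattern", {
  cond <- hdx_conditions(d2o_fraction = 0, charge_site_exchange = FALSE)
  lad <- simulate_ladder("C18H21NO3", "[M+H]+", exchange_sites(), cond,
                         instrument_model(noise_cv = 0, intensity_floor = 0),
                         scale = 1)
  nat <- ion_natural_pattern("C18H21NO3", "[M+H]+", length(lad$channels))
  expect_equal(lad$channels, nat / sum(nat), tolerance = 1e-12)
})

test_that("morphine shows three deuterium channels under defaults", {
  fx <- fixture_library()[["morphine"]]
  lad <- simulate_ladder(fx$formula, fx$adduct, fx$sites, hdx_conditions(),
                         instrument_model(noise_cv = 0, intensity_floor = 0))
  j <- judge_deuteration(lad, fx$formula, fx$adduct)
  expect_identical(j$flagged, 1:3)
})

test_that("gas phase erases functional-group differences between isobars", {
  lib <- fixture_library()
  gas <- hdx_conditions(phase = "gas")
  inst <- instrument_model(noise_cv = 0, intensity_floor = 0)
  mor <- simulate_ladder(lib$morphine$formula, lib$morphine$adduct,
                         lib$morphine$sites, gas, inst)
  nor <- simulate_ladder(lib$norcodeine$formula, lib$norcodeine$adduct,
                         lib$norcodeine$sites, gas, inst)
  expect_equal(mor$channels, nor$channels, tolerance = 1e-12)
})

test_that("replicate ladders are seeded, reproducible and bounded in spread", {
  fx <- fixture_library()[["codeine"]]
  inst0 <- instrument_model(noise_cv = 0)
  reps0 <- replicate_ladders(fx$formula, fx$adduct, fx$sites, hdx_conditions(),
                             inst0, n_reps = 3)
  expect_equal(reps0[[1]]$channels, reps0[[2]]$channels)
  expect_equal(reps0[[2]]$channels, reps0[[3]]$channels)

  inst <- instrument_model(noise_cv = 0.05, seed = 11)
  r1 <- replicate_ladders(fx$formula, fx$adduct, fx$sites, hdx_conditions(),
                          inst, n_reps = 10)
  r2 <- replicate_ladders(fx$formula, fx$adduct, fx$sites, hdx_conditions(),
                          inst, n_reps = 10)
  expect_identical(r1, r2)
  expect_false(identical(r1[[1]]$channels, r1[[2]]$channels))

  d1 <- vapply(r1, function(l) l$relative[2], 0)
  expect_lt(stats::sd(d1) / mean(d1), 0.15)

  expect_error(replicate_ladders(fx$formula, fx$adduct, fx$sites,
                                 n_reps = 1), "n_reps")
})
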