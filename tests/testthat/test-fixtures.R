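# Toy molecules, simulated spectra, decoy libraries.

test_that("the toy set is self-consistent and carries the named entries", {
  toys <- toy_molecule_set()
  expect_gte(nrow(toys), 15)
  expect_true(all(c("naringenin", "epicatechin", "ethanol", "propane",
                    "cyclohexane") %in% toys$name))
  nar <- toys[toys$name == "naringenin", ]
  expect_equal(nar$ref_formula, "C15H12O5")
  expect_equal(nar$ref_mass, 272.068, tolerance = 0.001 / 272)
  for (i in seq_len(nrow(toys))) {
    f <- formula_of(toys$mol[[i]])
    expect_equal(formula_string(f), toys$ref_formula[i])
    expect_equal(monoisotopic_mass(f), toys$ref_mass[i],
                 tolerance = 5e-4 / 100)
  }
})

test_that("simulated spectra are deterministic under a fixed seed", {
  toys <- toy_molecule_set()
  m <- toys$mol[[match("dopamine", toys$name)]]
  s1 <- simulate_spectrum(m, seed = 99)
  s2 <- simulate_spectrum(m, seed = 99)
  expect_identical(s1$mz, s2$mz)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- simulate_spectrum(m, seed = 100)
  expect_false(identical(s1$mz, s3$mz))
})

test_that("zero-noise peaks sit exactly on protonated fragment masses", {
  toys <- toy_molecule_set()
  m <- toys$mol[[match("glucose", toys$name)]]
  frs <- enumerate_fragments(m, fragmenter_config(min_mass = 30))
  spec <- simulate_spectrum(m, n_peaks = 6, mass_noise_sd = 0, seed = 4)
  for (mz in spec$mz) {
    expect_true(any(abs(frs$mass + PROTON_MASS - mz) < 1e-9))
  }
  # heaviest fragment is always included
  expect_true(any(abs(spec$mz - (max(frs$mass) + PROTON_MASS)) < 1e-9))
})

test_that("single-peak and over-asked simulations behave", {
  toys <- toy_molecule_set()
  m <- toys$mol[[match("vanillin", toys$name)]]
  s1 <- simulate_spectrum(m, n_peaks = 1, seed = 1)
  expect_equal(nrow(s1), 1)
  eth <- toys$mol[[match("ethanol", toys$name)]]
  expect_warning(sall <- simulate_spectrum(eth, n_peaks = 50, seed = 1),
                 "emitting all")
  expect_lt(nrow(sall), 50)
})

test_that("isomer libraries hold the target once plus exact isomers", {
  toys <- toy_molecule_set()
  m <- toys$mol[[match("tyramine", toys$name)]]
  lib <- make_isomer_library(m, n = 25, seed = 13)
  expect_equal(nrow(lib), 26)
  expect_equal(sum(lib$id == "tyramine"), 1)
  target_mass <- monoisotopic_mass(formula_of(m))
  expect_true(all(abs(lib$mass - target_mass) <= 1e-9))
  # deterministic under the seed
  lib2 <- make_isomer_library(m, n = 25, seed = 13)
  expect_identical(lib$id, lib2$id)
  # isomers are connected, valence-consistent graphs of the same formula
  for (d in lib$mol[lib$id != "tyramine"][1:5]) {
    expect_true(all(d$atoms$nH >= 0))
    expect_equal(formula_string(formula_of(d)), "C8H11NO")
  }
})

test_that("decoy libraries hold in-window near-isobars, never isomers", {
  toys <- toy_molecule_set()
  m <- toys$mol[[match("tyramine", toys$name)]]
  lib <- make_decoy_library(m, n = 25, seed = 13)
  expect_equal(nrow(lib), 26)
  expect_equal(sum(lib$id == "tyramine"), 1)
  target_mass <- monoisotopic_mass(formula_of(m))
  window <- 0.01 + 50e-6 * target_mass
  expect_true(all(abs(lib$mass - target_mass) <= window))
  decoys <- lib[lib$id != "tyramine", ]
  expect_false(any(decoys$formula == "C8H11NO"))
  # deterministic under the seed
  lib2 <- make_decoy_library(m, n = 25, seed = 13)
  expect_identical(lib$id, lib2$id)
  expect_identical(lib$formula, lib2$formula)
})

test_that("self-identification: the target tops its own decoy library", {
  toys <- toy_molecule_set()
  m <- toys$mol[[match("salicylic acid", toys$name)]]
  spec <- simulate_spectrum(m, n_peaks = 6, mass_noise_sd = 0, seed = 8)
  lib <- make_decoy_library(m, n = 15, seed = 8)
  res <- rank_candidates(lib, spec,
                         params = match_params(mzabs = 0, mzppm = 10))
  expect_equal(res$rank[match("salicylic acid", res$id)], 1)
})
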