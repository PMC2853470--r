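# Tolerance windows, fragment-peak matching, Eq-style scoring.

test_that("the tolerance window combines mzabs and mzppm", {
  p10 <- match_params(mzabs = 0, mzppm = 10)
  expect_true(within_tolerance(272.068, 272.068, p10))
  expect_equal(mass_tolerance(272.068, p10), 0.00272068)
  expect_true(within_tolerance(272.068 + 0.0027, 272.068, p10))
  expect_false(within_tolerance(272.068 + 0.0028, 272.068, p10))
  p50 <- match_params(mzabs = 0.01, mzppm = 50)
  expect_equal(mass_tolerance(100, p50), 0.015)
})

test_that("the proton adjustment displays as 1.007 Da", {
  expect_equal(round(match_params()$proton_mass, 3), 1.007)
})

test_that("a molecule explains all peaks of its own simulated spectrum", {
  for (nm in c("dopamine", "vanillin", "glucose")) {
    toys <- toy_molecule_set()
    m <- toys$mol[[match(nm, toys$name)]]
    spec <- simulate_spectrum(m, n_peaks = 6, mass_noise_sd = 0, seed = 3)
    res <- fragment_and_match(m, spec, params = match_params(mzabs = 0,
                                                             mzppm = 10))
    expect_equal(res$n_explained, nrow(spec))
    expect_true(all(abs(res$matches$error_ppm) <= 10))
  }
})

test_that("peaks below every fragment mass stay unexplained", {
  m <- parse_smi("CCO")
  spec <- spectrum(c(5.0, 46.0419 + 1.00728), c(10, 100))
  res <- fragment_and_match(m, spec, params = match_params())
  expect_equal(res$n_explained, 1)
})

test_that("matching an empty spectrum errors", {
  m <- parse_smi("CCO")
  suppressWarnings(empty <- spectrum(numeric(0), numeric(0)))
  expect_error(fragment_and_match(m, empty), "empty")
})

test_that("a water-loss-derived fragment explains the M+H-18 signal", {
  toys <- toy_molecule_set()
  epi <- toys$mol[[match("epicatechin", toys$name)]]
  mh <- monoisotopic_mass(formula_of(epi)) + 1.00728
  spec <- spectrum(c(mh - 18.0106, mh), c(100, 50))
  res <- fragment_and_match(epi, spec,
                            params = match_params(mzabs = 0, mzppm = 10))
  loss_match <- res$matches[abs(res$matches$peak_mz - (mh - 18.0106)) <
                              1e-6, ]
  expect_equal(nrow(loss_match), 1)
  expect_equal(loss_match$source, "OH")
  # without rules the signal goes unexplained
  res0 <- fragment_and_match(epi, spec, rules = NULL,
                             params = match_params(mzabs = 0, mzppm = 10))
  expect_lt(res0$n_explained, res$n_explained)
})

test_that("intrinsically charged fragments match as-is with a penalty", {
  # betaine: quaternary N fragment keeps its + charge
  bet <- parse_structure("C[N+](C)(C)CC(=O)[O-]", "smiles", id = "betaine")
  frs <- enumerate_fragments(bet, fragmenter_config(min_mass = 30))
  charged <- frs[frs$charge != 0, ]
  expect_gte(nrow(charged), 1)
  ion <- charged$mass[1]  # as-is, no proton added
  spec <- spectrum(ion, 100)
  res <- fragment_and_match(bet, spec,
                            params = match_params(mzabs = 0.001, mzppm = 5))
  hit <- res$matches[res$matches$intrinsic, ]
  expect_gte(nrow(hit), 1)
  expect_gte(hit$bde[1], max(default_bde_table()$bde_kj_mol))
})

test_that("peak weights follow intensity^m * mz^n", {
  sp <- score_params()
  expect_equal(sp$m, 0.6)
  expect_equal(sp$n, 3)
  expect_equal(peak_weight(100, 0), 0)
  expect_equal(peak_weight(100, 100), 100^0.6 * 100^3)
  expect_equal(peak_weight(200, 7) / peak_weight(100, 7), 8)
})

test_that("score normalization matches the stated bounds", {
  # a single candidate with matches: w/max(w)=1, e/(2 max e)=0.5
  one <- candidate_scores(tibble::tibble(w = 5, e = 300))
  expect_equal(one$score, 0.5)
  # identical candidates tie
  two <- candidate_scores(tibble::tibble(w = c(3, 3), e = c(100, 100)))
  expect_equal(two$score[1], two$score[2])
  # no matches anywhere: all zero
  none <- candidate_scores(tibble::tibble(w = c(0, 0), e = c(0, 0)))
  expect_equal(none$score, c(0, 0))
  # superset of explained peaks with equal BDEs scores no lower
  sup <- candidate_scores(tibble::tibble(w = c(10, 7), e = c(200, 200)))
  expect_gte(sup$score[1], sup$score[2])
  expect_error(candidate_scores(tibble::tibble(w = numeric(0),
                                               e = numeric(0))), "no cand")
})

test_that("scores stay within [-0.5, 1] on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    raw <- tibble::tibble(w = round(runif(n, 0, 1e8)),
                          e = round(runif(n, 0, 2000)))
    raw$e[raw$w == 0] <- 0
    sc <- candidate_scores(raw)$score
    expect_true(all(sc >= -0.5 - 1e-12 & sc <= 1 + 1e-12))
  }
})

test_that("candidate order does not change scores or ranks", {
  toys <- toy_molecule_set()
  m <- toys$mol[[match("vanillin", toys$name)]]
  spec <- simulate_spectrum(m, seed = 5)
  lib <- make_decoy_library(m, n = 6, seed = 5)
  res1 <- rank_candidates(lib, spec,
                          params = match_params(mzabs = 0, mzppm = 10))
  perm <- lib[rev(seq_len(nrow(lib))), ]
  class(perm) <- class(lib)
  res2 <- rank_candidates(perm, spec,
                          params = match_params(mzabs = 0, mzppm = 10))
  j <- match(res1$id, res2$id)
  expect_equal(res2$score[j], res1$score)
  expect_equal(res2$rank[j], res1$rank)
})
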