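# Neutral-loss rules: bundled table, site finding, rule application.

test_that("the bundled rule table holds the five standard losses", {
  rules <- default_rules()
  expect_equal(nrow(rules), 5)
  expect_setequal(rules$pattern, c("OH", "CN", "NH2", "COH", "COOH"))
  hcooh <- rules[rules$pattern == "COOH", ]
  expect_equal(hcooh$ion_mode, "+")
  expect_equal(hcooh$exact_mass, 46.0055)
  expect_true(all(rules$max_distance == 3))
  # printed exact masses agree with the loss formulas
  for (i in seq_len(nrow(rules))) {
    expect_equal(monoisotopic_mass(rules$loss_formula[i]),
                 rules$exact_mass[i], tolerance = 5e-4 / 18)
  }
})

test_that("water-loss sites need an OH plus a donor H within distance", {
  rules <- default_rules()
  h2o <- as.list(rules[rules$pattern == "OH", ])
  eth <- parse_smi("CCO")
  sites <- find_loss_sites(eth, h2o)
  expect_gte(nrow(sites), 1)
  expect_true(all(sites$distance >= 1 & sites$distance <= 3))
  # benzene has no hydroxyl
  expect_equal(nrow(find_loss_sites(parse_smi("c1ccccc1"), h2o)), 0)
  # epicatechin: at least one site within distance 3
  epi <- parse_smi("OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1")
  epi_sites <- find_loss_sites(epi, h2o)
  expect_gte(nrow(epi_sites), 1)
  expect_true(any(epi_sites$distance <= 3))
})

test_that("applying rules derives structures with the loss subtracted", {
  eth <- parse_smi("CCO")
  derived <- apply_rules(eth, ion_mode = "positive")
  expect_length(derived, 1)
  expect_equal(formula_string(formula_of(derived[[1]])), "C2H4")
  expect_equal(attr(derived[[1]], "rule"), "OH")
  # mass bookkeeping within 0.001 Da
  expect_equal(monoisotopic_mass(formula_of(derived[[1]])),
               monoisotopic_mass(formula_of(eth)) - 18.0106,
               tolerance = 0.001 / 28)
})

test_that("ion-mode restrictions are honoured (HCOOH positive-only)", {
  benzoic <- parse_smi("OC(=O)c1ccccc1")
  pos <- apply_rules(benzoic, ion_mode = "positive")
  neg <- apply_rules(benzoic, ion_mode = "negative")
  expect_true(any(vapply(pos, function(d) attr(d, "rule"), character(1))
                  == "COOH"))
  expect_false(any(vapply(neg, function(d) attr(d, "rule"), character(1))
                   == "COOH"))
})

test_that("molecules without any pattern derive nothing", {
  expect_length(apply_rules(parse_smi("CCC")), 0)
  expect_length(apply_rules(parse_smi("C1CCCCC1")), 0)
})

test_that("derived structures are deduplicated by formula", {
  # glycerol: three hydroxyls, all water losses share one formula
  gly <- parse_smi("OCC(O)CO")
  derived <- apply_rules(gly)
  fs <- vapply(derived, function(d) formula_string(formula_of(d)),
               character(1))
  expect_false(any(duplicated(fs)))
  expect_true("C3H6O2" %in% fs)
})

test_that("mass bookkeeping holds across rules and molecules", {
  rules <- default_rules()
  cases <- list(
    parse_smi("NCCc1ccc(O)cc1"),   # tyramine: OH + NH2
    parse_smi("CC#N"),             # acetonitrile: CN
    parse_smi("COc1cc(C=O)ccc1O")  # vanillin: OH + COH
  )
  for (m in cases) {
    for (d in apply_rules(m)) {
      loss <- rules$exact_mass[rules$loss_formula ==
                                 attr(d, "loss_formula")][1]
      expect_equal(monoisotopic_mass(formula_of(d)),
                   monoisotopic_mass(formula_of(m)) - loss,
                   tolerance = 0.001)
    }
  }
})

test_that("a removal that would disconnect the graph is skipped", {
  # dimethyl ether COC: no OH (the O is internal), so no water loss at all
  expect_length(apply_rules(parse_smi("COC")), 0)
})

test_that("rule files validate mass/formula consistency", {
  bad <- withr::local_tempfile(
    lines = c("ion_mode\texact_mass\tpattern\tloss_formula\tmax_distance",
              "+-\t19.5\tOH\tH2O\t3"),
    fileext = ".tsv")
  expect_error(read_loss_rules(bad), "disagrees")
})
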