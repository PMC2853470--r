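# Structure I/O, formulas, monoisotopic masses, fingerprints.

test_that("structure parsing populates hydrogens and ring flags", {
  w <- parse_structure("O", "smiles")
  expect_equal(nrow(w$atoms), 1)
  expect_equal(w$atoms$element, "O")
  expect_equal(w$atoms$nH, 2L)

  chx <- parse_structure("C1CCCCC1", "smiles", id = "cyclohexane")
  expect_equal(nrow(chx$atoms), 6)
  expect_equal(nrow(chx$bonds), 6)
  expect_true(all(chx$bonds$ring))
  expect_equal(chx$id, "cyclohexane")

  # chain bonds are not flagged as rings
  tol <- parse_structure("Cc1ccccc1", "smiles")
  expect_equal(sum(!tol$bonds$ring), 1)
})

test_that("a multi-record SDF round trip preserves ids, formulas, bonds", {
  a <- parse_structure("CCO", "smiles", id = "ethanol")
  b <- parse_structure("c1ccccc1", "smiles", id = "benzene")
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(a, b), path)
  back <- read_structures(paste(readLines(path), collapse = "\n"), "sdf")
  expect_length(back, 2)
  expect_equal(vapply(back, function(m) m$id, character(1)),
               c("ethanol", "benzene"))
  expect_equal(formula_string(formula_of(back[[1]])), "C2H6O")
  expect_equal(formula_string(formula_of(back[[2]])), "C6H6")
  expect_equal(nrow(back[[2]]$bonds), nrow(b$bonds))
})

test_that("SMILES round trip preserves formula and bond count", {
  for (smi in c("CCO", "C1CCCCC1", "CC(=O)O", "c1ccncc1")) {
    m <- parse_structure(smi, "smiles")
    m2 <- parse_structure(to_smiles(m), "smiles")
    expect_equal(formula_string(formula_of(m2)),
                 formula_string(formula_of(m)))
    expect_equal(nrow(m2$bonds), nrow(m$bonds))
  }
})

test_that("InChI input parses", {
  m <- parse_structure("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", "inchi")
  expect_equal(formula_string(formula_of(m)), "C2H6O")
})

test_that("parse failures raise structured errors", {
  expect_error(parse_structure("not_a_smiles((", "smiles"), "parse")
  expect_error(parse_structure("C", "xyz"))
})

test_that("monoisotopic masses match reference values", {
  expect_equal(monoisotopic_mass(parse_formula("C15H12O5")), 272.068,
               tolerance = 0.001 / 272)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 3e-5)
  expect_equal(monoisotopic_mass("CH2O"), 30.0106, tolerance = 2e-5)
  expect_equal(monoisotopic_mass(as_formula(integer(0))), 0)
  expect_error(monoisotopic_mass(as_formula(c(Xx = 1))), "unknown element")
})

test_that("mass is additive over disjoint formulas", {
  combos <- list(c("C2H6O", "H2O"), c("C15H12O5", "CH2O2"),
                 c("C6H12", "NH3"))
  for (cp in combos) {
    expect_equal(
      monoisotopic_mass(formula_add(parse_formula(cp[1]),
                                    parse_formula(cp[2]))),
      monoisotopic_mass(cp[1]) + monoisotopic_mass(cp[2])
    )
  }
})

test_that("formula_of counts heavy atoms from the graph and H from fields", {
  chx <- parse_structure("C1CCCCC1", "smiles")
  expect_equal(formula_string(formula_of(chx)), "C6H12")

  # ethyl fragment of propane: H is not transferred to the cut site
  pr <- parse_structure("CCC", "smiles")
  frag <- cleave(pr, bonds = which(pr$bonds$a1 == 1 | pr$bonds$a2 == 1)[1])
  expect_setequal(frag$formula, c("CH3", "C2H5"))

  # round trip: full candidate formula equals the parse input
  nar <- parse_structure("O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12", "smiles")
  expect_equal(formula_string(formula_of(nar)), "C15H12O5")
})

test_that("formula strings parse back and ignore element order", {
  expect_equal(formula_string(as_formula(c(O = 5, C = 15, H = 12))),
               "C15H12O5")
  expect_equal(as_formula(c(H = 2, O = 1)), parse_formula("H2O"))
  expect_equal(formula_string(formula_subtract("C2H6O", "H2O")), "C2H4")
  expect_error(formula_subtract("H2O", "H2O2"), "negative")
})

test_that("tanimoto follows the set formula and is symmetric", {
  a <- c(rep(FALSE, 4), rep(TRUE, 4))
  b <- c(rep(FALSE, 6), TRUE, TRUE)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(b, a), 0.5)
  expect_warning(z <- tanimoto(logical(8), logical(8)), "empty")
  expect_equal(z, 0)
})

test_that("fingerprints: identity, symmetry, stereoisomer collapse", {
  mols <- lapply(c("CCO", "C1CCCCC1", "NCCc1ccc(O)c(O)c1"), parse_smi)
  for (m in mols) {
    fp <- fingerprint(m)
    expect_equal(tanimoto(fp, fp), 1.0)
  }
  # stereoisomers differ only in stereo annotations, which the
  # connectivity fingerprint never sees
  epi <- parse_structure("O[C@H]1Cc2c(O)cc(O)cc2O[C@@H]1c1ccc(O)c(O)c1",
                         "smiles")
  ent <- parse_structure("O[C@@H]1Cc2c(O)cc(O)cc2O[C@H]1c1ccc(O)c(O)c1",
                         "smiles")
  expect_gte(tanimoto(fingerprint(epi), fingerprint(ent)), 0.95)
  # different connectivity separates
  expect_lt(tanimoto(fingerprint(parse_smi("CCO")),
                     fingerprint(parse_smi("c1ccccc1"))), 0.95)
})
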