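#' @title Synthetic fixtures: toy molecules, simulated spectra, decoy
#'   libraries
#' @description
#' Everything needed to exercise the full identification pipeline without
#' network access: a curated set of small molecules spanning chains, rings
#' and heteroatoms (each with an independently recorded formula and
#' monoisotopic mass); a spectrum simulator that emits the protonated
#' masses of a random sample of a molecule's own in-silico fragments; and
#' two library generators — exact isomers of a target
#' ([make_isomer_library()], emulating a high-accuracy search hit list)
#' and formula-enumerated near-isobars ([make_decoy_library()], emulating
#' a low-accuracy search neighbourhood). All structures are synthetic
#' random graphs, not catalogued compounds.
#' @name fixtures-model
NULL

# name, SMILES, and independently computed reference formula/mass
.TOY_TABLE <- tibble::tribble(
  ~name,            ~smiles,                                ~ref_formula, ~ref_mass,
  "naringenin",     "O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12",  "C15H12O5",   272.0685,
  "epicatechin",    "OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1",  "C15H14O6",   290.0790,
  "ethanol",        "CCO",                                  "C2H6O",      46.0419,
  "propane",        "CCC",                                  "C3H8",       44.0626,
  "cyclohexane",    "C1CCCCC1",                             "C6H12",      84.0939,
  "benzene",        "c1ccccc1",                             "C6H6",       78.0470,
  "phenol",         "Oc1ccccc1",                            "C6H6O",      94.0419,
  "toluene",        "Cc1ccccc1",                            "C7H8",       92.0626,
  "pyridine",       "c1ccncc1",                             "C5H5N",      79.0422,
  "furan",          "c1ccoc1",                              "C4H4O",      68.0262,
  "acetone",        "CC(C)=O",                              "C3H6O",      58.0419,
  "acetic acid",    "CC(=O)O",                              "C2H4O2",     60.0211,
  "alanine",        "CC(N)C(=O)O",                          "C3H7NO2",    89.0477,
  "glycine",        "NCC(=O)O",                             "C2H5NO2",    75.0320,
  "glucose",        "OCC1OC(O)C(O)C(O)C1O",                 "C6H12O6",    180.0634,
  "dopamine",       "NCCc1ccc(O)c(O)c1",                    "C8H11NO2",   153.0790,
  "tyramine",       "NCCc1ccc(O)cc1",                       "C8H11NO",    137.0841,
  "vanillin",       "COc1cc(C=O)ccc1O",                     "C8H8O3",     152.0473,
  "salicylic acid", "OC(=O)c1ccccc1O",                      "C7H6O3",     138.0317,
  "cinnamaldehyde", "O=CC=Cc1ccccc1",                       "C9H8O",      132.0575,
  "nicotinamide",   "NC(=O)c1cccnc1",                       "C6H6N2O",    122.0480,
  "methionine",     "CSCCC(N)C(=O)O",                       "C5H11NO2S",  149.0510,
  "caffeine",       "Cn1cnc2c1c(=O)n(C)c(=O)n2C",           "C8H10N4O2",  194.0804,
  "indole",         "c1ccc2[nH]ccc2c1",                     "C8H7N",      117.0578,
  "quinoline",      "c1ccc2ncccc2c1",                       "C9H7N",      129.0578,
  "benzoic acid",   "OC(=O)c1ccccc1",                       "C7H6O2",     122.0368,
  "anisole",        "COc1ccccc1",                           "C7H8O",      108.0575,
  "catechol",       "Oc1ccccc1O",                           "C6H6O2",     110.0368,
  "1-octanol",      "CCCCCCCCO",                            "C8H18O",     130.1358,
  "serotonin",      "NCCc1c[nH]c2ccc(O)cc12",               "C10H12N2O",  176.0950
)

.toy_cache <- new.env(parent = emptyenv())

#' The curated toy molecule set
#'
#' 30 small molecules spanning chains, rings, aromatics and C/H/N/O/S,
#' including naringenin (C15H12O5, 272.068 Da) and epicatechin. Each row
#' records the reference formula and monoisotopic mass the structure is
#' expected to have. At least 20 of them are rich enough to yield a
#' six-peak depth-2 simulated spectrum (see [fragmentable_toys()]).
#'
#' @return tibble: `name`, `smiles`, `ref_formula`, `ref_mass`, `mol`
#'   (list-column of parsed `fr_mol`).
#' @export
toy_molecule_set <- function() {
  if (is.null(.toy_cache$set)) {
    tab <- .TOY_TABLE
    tab$mol <- lapply(seq_len(nrow(tab)), function(i) {
      m <- parse_structure(tab$smiles[i], "smiles")
      m$id <- tab$name[i]
      m$name <- tab$name[i]
      m
    })
    .toy_cache$set <- tab
  }
  .toy_cache$set
}

#' Toy molecules rich enough for an n-peak simulated spectrum
#'
#' Filters [toy_molecule_set()] to molecules with at least `n_peaks`
#' distinct fragments at the given depth above the minimum mass, so a
#' simulated spectrum with that many peaks exists.
#'
#' @param n_peaks required number of distinct fragments (default 6).
#' @param depth fragmentation depth (default 2).
#' @param min_mass minimum fragment mass in Da (default 30).
#' @return the qualifying subset of the toy-set tibble.
#' @export
fragmentable_toys <- function(n_peaks = 6L, depth = 2L, min_mass = 30) {
  toys <- toy_molecule_set()
  counts <- vapply(toys$mol, function(m) {
    nrow(enumerate_fragments(m, fragmenter_config(max_depth = depth,
                                                  min_mass = min_mass)))
  }, integer(1))
  toys[counts >= n_peaks, ]
}

#' Simulate a tandem-MS spectrum from a molecule's own fragments
#'
#' Samples `n_peaks` distinct fragments from [enumerate_fragments()] at the
#' given depth (the heaviest fragment is always included, and sampling is
#' weighted by `mass^3`, mirroring the scoring model's view that high-mass
#' peaks are the characteristic ones — real CID spectra are dominated by
#' small neutral losses from the precursor), emits their singly protonated
#' ion masses with optional Gaussian mass noise, and draws intensities
#' log-uniformly over two decades.
#'
#' @param m an `fr_mol`.
#' @param n_peaks number of peaks to emit (default 6). If fewer fragments
#'   exist, all are emitted with a warning.
#' @param depth fragmentation tree depth used for simulation (default 2).
#' @param mass_noise_sd Gaussian m/z noise standard deviation in Da
#'   (default 0).
#' @param intensity_range intensity bounds (default `c(100, 10000)`, i.e.
#'   two decades).
#' @param min_mass minimum fragment mass (default 30 Da).
#' @param seed RNG seed; a fixed seed gives an identical spectrum.
#' @param bde_table BDE table for the fragmenter.
#' @return an `fr_spectrum` (positive mode) with the precursor m/z set to
#'   the protonated molecule.
#' @export
simulate_spectrum <- function(m, n_peaks = 6L, depth = 2L,
                              mass_noise_sd = 0,
                              intensity_range = c(100, 10000),
                              min_mass = 30, seed = 1L,
                              bde_table = default_bde_table()) {
  stopifnot(inherits(m, "fr_mol"), n_peaks >= 1)
  frs <- enumerate_fragments(
    m, fragmenter_config(max_depth = depth, min_mass = min_mass), bde_table
  )
  if (nrow(frs) == 0) {
    stop("molecule has no fragments above the minimum mass", call. = FALSE)
  }
  k <- n_peaks
  if (nrow(frs) < k) {
    warning("only ", nrow(frs), " fragments available; emitting all",
            call. = FALSE)
    k <- nrow(frs)
  }
  withr::with_seed(seed, {
    pick <- 1L  # heaviest fragment always present
    if (k > 1) {
      rest <- setdiff(seq_len(nrow(frs)), 1L)
      pick <- c(pick, rest[sample.int(length(rest), k - 1L,
                                      prob = frs$mass[rest]^3)])
    }
    masses <- frs$mass[pick] + PROTON_MASS +
      stats::rnorm(k, 0, mass_noise_sd)
    intens <- 10^stats::runif(k, log10(intensity_range[1]),
                              log10(intensity_range[2]))
  })
  keep <- !duplicated(round(masses, 6))
  spectrum(masses[keep], intens[keep], ion_mode = "positive",
           precursor_mz = monoisotopic_mass(formula_of(m)) + PROTON_MASS)
}

# ---- random isomer decoys --------------------------------------------------

# One random connected structure over exactly the target's heavy-atom
# multiset with the same per-atom valences (incident bond order + H), hence
# the same molecular formula and monoisotopic mass. Bonds between two
# heteroatoms are avoided whenever a carbon partner is available: real
# compound libraries contain almost no peroxide/hydrazine-like linkages,
# and such cheap bonds would make a decoy's fragments systematically
# easier to reach than any catalogued structure's. Returns NULL on a dead
# end (caller retries).
.random_isomer <- function(elements, valences, total_h, id) {
  n <- length(elements)
  is_c <- elements == "C"
  # random spanning tree: attach each atom to an earlier one with capacity
  ord <- sample(n)
  residual <- valences
  a1 <- integer(0); a2 <- integer(0); ord_bond <- integer(0)
  for (k in 2:n) {
    v <- ord[k]
    cand <- ord[seq_len(k - 1)]
    cand <- cand[residual[cand] >= 1]
    if (!length(cand) || residual[v] < 1) return(NULL)
    if (!is_c[v] && any(is_c[cand])) cand <- cand[is_c[cand]]
    u <- if (length(cand) == 1) cand else sample(cand, 1)
    a1 <- c(a1, min(u, v)); a2 <- c(a2, max(u, v))
    ord_bond <- c(ord_bond, 1L)
    residual[u] <- residual[u] - 1L
    residual[v] <- residual[v] - 1L
  }
  # distribute extra bond order (new edges or order increments) until the
  # leftover valence equals the target's hydrogen count
  deficit <- as.integer((sum(residual) - total_h) / 2)
  if (deficit < 0) return(NULL)
  tries <- 0L
  while (deficit > 0) {
    tries <- tries + 1L
    if (tries > 200L) return(NULL)
    open <- which(residual >= 1)
    if (length(open) < 2) return(NULL)
    u <- sample(open, 1)
    w <- setdiff(open, u)
    if (!length(w)) return(NULL)
    if (!is_c[u] && any(is_c[w]) && tries <= 150L) w <- w[is_c[w]]
    v <- if (length(w) == 1) w else sample(w, 1)
    ei <- which(a1 == min(u, v) & a2 == max(u, v))
    if (length(ei)) {
      if (ord_bond[ei] >= 3) next
      ord_bond[ei] <- ord_bond[ei] + 1L
    } else {
      a1 <- c(a1, min(u, v)); a2 <- c(a2, max(u, v))
      ord_bond <- c(ord_bond, 1L)
    }
    residual[u] <- residual[u] - 1L
    residual[v] <- residual[v] - 1L
    deficit <- deficit - 1L
  }
  atoms <- tibble::tibble(element = elements, charge = 0L, nH = residual)
  bonds <- tibble::tibble(a1 = a1, a2 = a2, order = ord_bond)
  mol <- .new_mol(atoms, bonds, id = id, name = id)
  mol$bonds$ring <- .perceive_rings(mol)
  mol
}

#' Build an isomer library around a target molecule
#'
#' The target plus `n` random connected structures over the target's own
#' heavy-atom multiset with matching per-atom valences: every entry is an
#' exact isomer (identical formula and neutral mass). This emulates the
#' isomer-dominated hit list of a high-accuracy exact-mass search — for
#' example, a handful of isomers sharing C15H12O5. The library order is
#' shuffled deterministically by the seed.
#'
#' @param target an `fr_mol`.
#' @param n number of isomers to generate (default 14).
#' @param seed RNG seed.
#' @return an `fr_library` containing the target exactly once and up to
#'   `n` isomers (fewer, with a warning, if construction keeps failing).
#' @export
make_isomer_library <- function(target, n = 14L, seed = 1L) {
  stopifnot(inherits(target, "fr_mol"), n >= 1)
  elements <- target$atoms$element
  # actual per-atom valence in the target structure
  inc_order <- integer(nrow(target$atoms))
  if (nrow(target$bonds)) {
    for (i in seq_len(nrow(target$bonds))) {
      inc_order[target$bonds$a1[i]] <- inc_order[target$bonds$a1[i]] +
        target$bonds$order[i]
      inc_order[target$bonds$a2[i]] <- inc_order[target$bonds$a2[i]] +
        target$bonds$order[i]
    }
  }
  valences <- inc_order + target$atoms$nH
  target_formula <- formula_string(formula_of(target))
  decoys <- withr::with_seed(seed, {
    out <- list()
    attempts <- 0L
    while (length(out) < n && attempts < 50L * n) {
      attempts <- attempts + 1L
      d <- .random_isomer(elements, valences, sum(target$atoms$nH),
                          sprintf("ISOMER%03d", length(out) + 1L))
      if (is.null(d)) next
      if (formula_string(formula_of(d)) != target_formula) next
      out[[length(out) + 1L]] <- d
    }
    out
  })
  if (length(decoys) < n) {
    warning("constructed only ", length(decoys), " of ", n, " isomers",
            call. = FALSE)
  }
  tgt <- target
  if (is.na(tgt$id)) tgt$id <- "TARGET"
  lib <- as_candidate_library(c(list(tgt), decoys), source = "synthetic")
  perm <- withr::with_seed(seed + 1L, sample(nrow(lib)))
  out <- lib[perm, ]
  class(out) <- class(lib)
  out
}

# ---- formula-enumerated decoys ---------------------------------------------

.STD_VALENCE <- c(C = 4L, N = 3L, O = 2L, P = 3L, S = 2L)

# All CHNOPS formulas whose monoisotopic mass lies within the window and
# that admit a connected structure with standard valences.
.formulas_in_window <- function(mass, window, max_h_excess = 2L) {
  mc <- .ELEMENT_MASSES
  out <- list()
  for (nC in 0:floor(mass / mc[["C"]])) {
    for (nN in 0:6) {
      for (nO in 0:14) {
        for (nS in 0:3) {
          heavy <- nC * mc[["C"]] + nN * mc[["N"]] + nO * mc[["O"]] +
            nS * mc[["S"]]
          if (heavy > mass + window) break
          n_heavy <- nC + nN + nO + nS
          if (n_heavy < 2) next
          nH <- round((mass - heavy) / mc[["H"]])
          for (h in c(nH - 1L, nH, nH + 1L)) {
            if (h < 0) next
            m <- heavy + h * mc[["H"]]
            if (abs(m - mass) > window) next
            # even-electron molecule: integer, non-negative ring+double count
            dbe <- nC + 1 - (h - nN) / 2
            if (dbe < 0 || abs(dbe - round(dbe)) > 1e-9) next
            # connectable with standard valences
            sum_val <- 4 * nC + 3 * nN + 2 * nO + 2 * nS
            b <- (sum_val - h) / 2
            if (b < n_heavy - 1 || b != round(b)) next
            f <- c(C = nC, H = h, N = nN, O = nO, S = nS)
            out[[length(out) + 1L]] <- f[f > 0]
          }
        }
      }
    }
  }
  out
}

#' Build a decoy library of near-isobars around a target molecule
#'
#' Emulates the candidate neighbourhood of an exact-mass database search
#' on a low-accuracy instrument: CHNOS formulas are enumerated within
#' `mzabs + ppm` of the target's neutral mass, and each decoy is a random
#' connected structure realizing one of those formulas (standard valences,
#' heteroatom-heteroatom bonds avoided). The target structure is present
#' exactly once; decoy formulas exclude the target's own, so decoys are
#' structurally dissimilar near-isobars rather than isomers (see
#' [make_isomer_library()] for those). The library order is shuffled
#' deterministically by the seed.
#'
#' @param target an `fr_mol`.
#' @param n number of decoys (default 100).
#' @param ppm relative half-window in ppm (default 50).
#' @param mzabs absolute half-window in Da (default 0.01). The defaults
#'   match a low-accuracy instrument's search tolerance.
#' @param seed RNG seed.
#' @return an `fr_library` containing the target exactly once and up to
#'   `n` decoys (fewer, with a warning, if the window admits too few
#'   realizable formulas).
#' @export
make_decoy_library <- function(target, n = 100L, ppm = 50, mzabs = 0.01,
                               seed = 1L) {
  stopifnot(inherits(target, "fr_mol"), n >= 1)
  t_mass <- monoisotopic_mass(formula_of(target))
  window <- mzabs + ppm * 1e-6 * t_mass
  t_formula <- formula_string(formula_of(target))
  formulas <- .formulas_in_window(t_mass, window)
  fstr <- vapply(formulas, function(f) formula_string(as_formula(f)),
                 character(1))
  keep <- fstr != t_formula
  formulas <- formulas[keep]; fstr <- fstr[keep]
  decoys <- withr::with_seed(seed, {
    out <- list()
    attempts <- 0L
    while (length(out) < n && attempts < 50L * n && length(formulas)) {
      attempts <- attempts + 1L
      fi <- sample.int(length(formulas), 1)
      f <- formulas[[fi]]
      heavies <- setdiff(names(f), "H")
      elements <- rep(heavies, unlist(f[heavies]))
      d <- .random_isomer(elements, .STD_VALENCE[elements],
                          if ("H" %in% names(f)) f[["H"]] else 0L,
                          sprintf("DECOY%03d", length(out) + 1L))
      if (is.null(d)) next
      if (abs(monoisotopic_mass(formula_of(d)) - t_mass) > window) next
      out[[length(out) + 1L]] <- d
    }
    out
  })
  if (length(decoys) < n) {
    warning("constructed only ", length(decoys), " of ", n, " decoys",
            call. = FALSE)
  }
  tgt <- target
  if (is.na(tgt$id)) tgt$id <- "TARGET"
  lib <- as_candidate_library(c(list(tgt), decoys), source = "synthetic")
  perm <- withr::with_seed(seed + 1L, sample(nrow(lib)))
  out <- lib[perm, ]
  class(out) <- class(lib)
  out
}
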