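#' @title Neutral-loss rearrangement rules
#' @description
#' Pure bond disconnection cannot reach fragments formed by rearrangement:
#' a water loss, for instance, removes a hydroxyl group and a hydrogen from
#' *different* positions. Each rule names a topological pattern (a small
#' heavy-atom motif), the neutral loss it produces, and the maximum
#' topological distance (bond count) at which a donor hydrogen may sit.
#' Applying a rule removes the pattern atoms and the donor hydrogen,
#' producing a derived structure that is fragmented like any candidate.
#' By default rules are applied only to the intact candidate; applying them
#' to every fragment generates more fragments but lowers the positive
#' predictive value.
#' @name rearrangements-model
NULL

#' Load neutral-loss rules from a file
#'
#' @param path tab-separated rule file with columns `ion_mode` (`+`, `-`,
#'   or `+-`), `exact_mass` (Da), `pattern` (motif name, see
#'   [find_loss_sites()]), `loss_formula`, `max_distance` (bonds).
#' @return tibble of class `fr_rules`. Each rule's printed exact mass must
#'   agree with the monoisotopic mass of its loss formula within 0.0005 Da.
#' @export
read_loss_rules <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("ion_mode", "exact_mass", "pattern", "loss_formula",
                  "max_distance") %in% names(tab)))
  out <- tibble::as_tibble(tab)
  calc <- vapply(out$loss_formula, monoisotopic_mass, numeric(1))
  off <- abs(calc - out$exact_mass) > 5e-4
  if (any(off)) {
    stop("rule exact mass disagrees with its loss formula: ",
         paste(out$pattern[off], collapse = ", "), call. = FALSE)
  }
  if (any(out$max_distance < 1)) {
    stop("rule max_distance must be >= 1", call. = FALSE)
  }
  class(out) <- c("fr_rules", class(out))
  out
}

#' The five bundled neutral-loss rules
#'
#' Hydroxyl (H2O, 18.0106 Da), nitrile (HCN, 27.0109), amine (NH3,
#' 17.0266), formyl (CH2O, 30.0106) in both ion modes, and carboxyl
#' (HCOOH, 46.0055) in positive mode only; all with maximum donor
#' distance 3.
#' @return an `fr_rules` tibble with five rows.
#' @export
default_rules <- function() {
  read_loss_rules(system.file("extdata", "neutral_loss_rules.tsv",
                              package = "fragrank", mustWork = TRUE))
}

.rule_applies <- function(rule_mode, ion_mode) {
  ion <- if (ion_mode == "positive") "+" else "-"
  grepl(ion, rule_mode, fixed = TRUE)
}

# ---- pattern registry ------------------------------------------------------
#
# Each matcher returns a list of sites:
#   list(atoms = pattern atom ids, attach = attachment heavy atom,
#        pattern_h = hydrogens leaving with the pattern)
# The registry is extensible: register new motifs with .loss_patterns.

.heavy_degree <- function(m) {
  deg <- integer(nrow(m$atoms))
  if (nrow(m$bonds)) {
    t1 <- tabulate(m$bonds$a1, nbins = nrow(m$atoms))
    t2 <- tabulate(m$bonds$a2, nbins = nrow(m$atoms))
    deg <- t1 + t2
  }
  deg
}

.neighbors_of <- function(m, a) {
  c(m$bonds$a2[m$bonds$a1 == a], m$bonds$a1[m$bonds$a2 == a])
}

.loss_patterns <- list(
  # terminal hydroxyl: O with >= 1 H bonded to exactly one heavy atom
  OH = function(m) {
    deg <- .heavy_degree(m)
    hits <- which(m$atoms$element == "O" & m$atoms$nH >= 1 & deg == 1)
    lapply(hits, function(o) {
      list(atoms = o, attach = .neighbors_of(m, o)[1],
           pattern_h = m$atoms$nH[o])
    })
  },
  # nitrile-like: terminal N without H on a carbon with one other neighbor
  CN = function(m) {
    deg <- .heavy_degree(m)
    hits <- which(m$atoms$element == "N" & m$atoms$nH == 0 & deg == 1)
    out <- list()
    for (n in hits) {
      c_at <- .neighbors_of(m, n)[1]
      if (m$atoms$element[c_at] != "C") next
      others <- setdiff(.neighbors_of(m, c_at), n)
      if (length(others) != 1) next
      out[[length(out) + 1L]] <- list(
        atoms = c(c_at, n), attach = others,
        pattern_h = m$atoms$nH[c_at]
      )
    }
    out
  },
  # primary amine: terminal N carrying >= 2 H
  NH2 = function(m) {
    deg <- .heavy_degree(m)
    hits <- which(m$atoms$element == "N" & m$atoms$nH >= 2 & deg == 1)
    lapply(hits, function(n) {
      list(atoms = n, attach = .neighbors_of(m, n)[1],
           pattern_h = m$atoms$nH[n])
    })
  },
  # formyl/carbinol carbon: C with one terminal O and one other neighbor
  COH = function(m) {
    deg <- .heavy_degree(m)
    term_o <- which(m$atoms$element == "O" & deg == 1)
    out <- list()
    for (o in term_o) {
      c_at <- .neighbors_of(m, o)[1]
      if (m$atoms$element[c_at] != "C") next
      others <- setdiff(.neighbors_of(m, c_at), o)
      if (length(others) != 1) next
      out[[length(out) + 1L]] <- list(
        atoms = c(c_at, o), attach = others,
        pattern_h = m$atoms$nH[c_at] + m$atoms$nH[o]
      )
    }
    out
  },
  # carboxyl: C bearing two terminal oxygens and one other neighbor
  COOH = function(m) {
    deg <- .heavy_degree(m)
    out <- list()
    cands <- which(m$atoms$element == "C")
    for (c_at in cands) {
      nb <- .neighbors_of(m, c_at)
      os <- nb[m$atoms$element[nb] == "O" & deg[nb] == 1]
      others <- setdiff(nb, os)
      if (length(os) != 2 || length(others) != 1) next
      out[[length(out) + 1L]] <- list(
        atoms = c(c_at, os), attach = others,
        pattern_h = m$atoms$nH[c_at] + sum(m$atoms$nH[os])
      )
    }
    out
  }
)

#' Find neutral-loss sites on a molecule
#'
#' A site is a (pattern occurrence, donor hydrogen) pair: the pattern motif
#' plus a heavy atom carrying at least one hydrogen whose shortest-path
#' distance from the pattern's attachment atom is positive and at most the
#' rule's maximum distance. Rules whose loss is fully covered by the
#' pattern's own hydrogens need no donor and yield one site per occurrence.
#'
#' @param m an `fr_mol`.
#' @param rule one row of an `fr_rules` table (data frame or list).
#' @return tibble: `pattern_atoms` (list), `attach`, `donor` (atom id, `NA`
#'   if no donor hydrogen is needed), `distance`, `rule`.
#' @export
find_loss_sites <- function(m, rule) {
  stopifnot(inherits(m, "fr_mol"))
  matcher <- .loss_patterns[[rule$pattern]]
  if (is.null(matcher)) {
    stop("unknown neutral-loss pattern: ", rule$pattern, call. = FALSE)
  }
  loss_h <- unclass(parse_formula(rule$loss_formula))[["H"]]
  occurrences <- matcher(m)
  rows <- list()
  for (occ in occurrences) {
    need <- loss_h - occ$pattern_h
    if (need < 0) next
    if (need == 0) {
      rows[[length(rows) + 1L]] <- list(pattern_atoms = occ$atoms,
                                        attach = occ$attach,
                                        donor = NA_integer_,
                                        distance = NA_integer_)
      next
    }
    if (need > 1) next  # no registered motif needs more than one donor H
    dist <- .bfs_distances(occ$attach, nrow(m$atoms),
                           seq_len(nrow(m$bonds)), m$bonds$a1, m$bonds$a2)
    donors <- which(m$atoms$nH >= 1 & !is.na(dist) & dist > 0 &
                      dist <= rule$max_distance)
    donors <- setdiff(donors, occ$atoms)
    for (d in donors) {
      rows[[length(rows) + 1L]] <- list(pattern_atoms = occ$atoms,
                                        attach = occ$attach,
                                        donor = d,
                                        distance = dist[d])
    }
  }
  tibble::tibble(
    pattern_atoms = lapply(rows, `[[`, "pattern_atoms"),
    attach = vapply(rows, `[[`, integer(1), "attach"),
    donor = vapply(rows, `[[`, integer(1), "donor"),
    distance = vapply(rows, `[[`, integer(1), "distance"),
    rule = rep(rule$pattern, length(rows))
  )
}

# Materialize an atom subset of m as a standalone molecule, with optional
# per-atom hydrogen removals (named vector: atom id -> H count to remove).
.extract_submol <- function(m, atoms, h_remove = NULL, id = NA_character_,
                            name = NA_character_) {
  atoms <- sort(atoms)
  at <- m$atoms[atoms, , drop = FALSE]
  if (!is.null(h_remove)) {
    for (a in names(h_remove)) {
      i <- match(as.integer(a), atoms)
      at$nH[i] <- at$nH[i] - h_remove[[a]]
      if (at$nH[i] < 0) stop("hydrogen count went negative", call. = FALSE)
    }
  }
  remap <- integer(nrow(m$atoms)); remap[atoms] <- seq_along(atoms)
  keep <- m$bonds$a1 %in% atoms & m$bonds$a2 %in% atoms
  bd <- m$bonds[keep, c("a1", "a2", "order"), drop = FALSE]
  bd$a1 <- remap[bd$a1]; bd$a2 <- remap[bd$a2]
  out <- .new_mol(tibble::as_tibble(at), tibble::as_tibble(bd),
                  id = id, name = name)
  out$bonds$ring <- .perceive_rings(out)
  out
}

#' Apply neutral-loss rules to a molecule
#'
#' For every applicable rule and every site, removes the pattern atoms and
#' the donor hydrogen, yielding a derived structure whose formula is the
#' parent formula minus the loss formula. Sites whose removal disconnects
#' the heavy-atom graph are skipped. Derived structures are deduplicated by
#' molecular formula.
#'
#' @param m an `fr_mol`.
#' @param rules an `fr_rules` table ([default_rules()]).
#' @param ion_mode `"positive"` or `"negative"`; rules not applicable in
#'   this mode are skipped.
#' @return list of derived `fr_mol` objects, each carrying attributes
#'   `rule` (pattern name) and `loss_formula`.
#' @examples
#' eth <- parse_structure("CCO", "smiles", id = "ethanol")
#' length(apply_rules(eth))  # one derived structure, C2H4
#' @export
apply_rules <- function(m, rules = default_rules(),
                        ion_mode = c("positive", "negative")) {
  ion_mode <- match.arg(ion_mode)
  stopifnot(inherits(m, "fr_mol"))
  derived <- list()
  seen_formulas <- character(0)
  n <- nrow(m$atoms)
  for (i in seq_len(nrow(rules))) {
    rule <- as.list(rules[i, ])
    if (!.rule_applies(rule$ion_mode, ion_mode)) next
    sites <- find_loss_sites(m, rule)
    if (!nrow(sites)) next
    for (j in seq_len(nrow(sites))) {
      pattern_atoms <- sites$pattern_atoms[[j]]
      keep_atoms <- setdiff(seq_len(n), pattern_atoms)
      if (!length(keep_atoms)) next
      if (!.is_connected(keep_atoms, n,
                         which(m$bonds$a1 %in% keep_atoms &
                                 m$bonds$a2 %in% keep_atoms),
                         m$bonds$a1, m$bonds$a2)) next
      h_remove <- NULL
      if (!is.na(sites$donor[j])) {
        h_remove <- stats::setNames(list(1L), sites$donor[j])
      }
      d <- .extract_submol(
        m, keep_atoms, h_remove,
        id = paste0(if (!is.na(m$id)) m$id else "mol", "-", rule$loss_formula),
        name = m$name
      )
      fs <- formula_string(formula_of(d))
      if (fs %in% seen_formulas) next
      seen_formulas <- c(seen_formulas, fs)
      attr(d, "rule") <- rule$pattern
      attr(d, "loss_formula") <- rule$loss_formula
      derived[[length(derived) + 1L]] <- d
    }
  }
  derived
}
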