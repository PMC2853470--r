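#' @title Combinatorial bond-disconnection fragmenter
#' @description
#' Generates all topological fragments of a candidate by breadth-first
#' bond disconnection. One cleavage event — a single acyclic (bridge) bond,
#' or an unordered pair of ring bonds whose joint removal disconnects the
#' fragment — produces the two connected components as child fragments and
#' advances the tree depth by one. Hydrogens travel with their heavy atom;
#' cut sites gain no hydrogen (rearrangements are handled separately by
#' neutral-loss rules). Fragments below the minimum-mass cutoff are pruned,
#' and redundant fragments are eliminated under a configurable redundancy
#' key; among duplicates the fragment requiring the lower cumulative bond
#' dissociation energy is retained.
#' @name fragmenter-model
NULL

#' Fragmenter configuration
#'
#' @param max_depth maximum tree depth: number of successive cleavage
#'   events (default 2).
#' @param min_mass minimum fragment neutral mass in Da. `NULL` means
#'   "derive from the query": the smallest query peak when fragmenting
#'   against a spectrum, 30 Da otherwise.
#' @param redundancy redundancy-check mode: `"molecular_formula"`
#'   (default), `"atom_id"`, or `"isomorphism"`.
#' @param apply_rules_to_fragments apply neutral-loss rules to every
#'   generated fragment rather than only the intact candidate
#'   (default `FALSE`; turning this on generates more fragments but lowers
#'   the positive predictive value).
#' @param include_root include the intact molecule (depth 0) in the
#'   returned fragment set (default `FALSE`).
#' @return a list of class `fr_config`.
#' @export
fragmenter_config <- function(max_depth = 2L,
                              min_mass = NULL,
                              redundancy = c("molecular_formula", "atom_id",
                                             "isomorphism"),
                              apply_rules_to_fragments = FALSE,
                              include_root = FALSE) {
  redundancy <- match.arg(redundancy)
  stopifnot(max_depth >= 1, is.null(min_mass) || min_mass > 0)
  structure(list(max_depth = as.integer(max_depth), min_mass = min_mass,
                 redundancy = redundancy,
                 apply_rules_to_fragments = isTRUE(apply_rules_to_fragments),
                 include_root = isTRUE(include_root)),
            class = "fr_config")
}

# ---- fragmentation context -------------------------------------------------

# Precomputed per-molecule element codes for fast formula strings.
.fast_ctx_fields <- function(mol) {
  els <- sort(unique(mol$atoms$element))
  list(
    els = els,
    el_code = match(mol$atoms$element, els),
    nH = mol$atoms$nH,
    atom_masses = .atom_masses(mol)
  )
}

# Hill-order formula string of an atom subset, avoiding the generic
# formula machinery (this runs once per fragment record).
.ctx_formula_string <- function(fc, atoms) {
  cnt <- tabulate(fc$el_code[atoms], nbins = length(fc$els))
  present <- cnt > 0L
  syms <- fc$els[present]; vals <- cnt[present]
  h <- sum(fc$nH[atoms])
  if (h > 0) { syms <- c(syms, "H"); vals <- c(vals, h) }
  front <- c("C", "H")[c("C", "H") %in% syms]
  ordnames <- c(front, sort(setdiff(syms, front)))
  v <- vals[match(ordnames, syms)]
  paste0(ordnames, ifelse(v == 1L, "", v), collapse = "")
}

# Precomputed per-candidate flat arrays used by the BFS.
.frag_ctx <- function(mol, bde_table = default_bde_table()) {
  fc <- .fast_ctx_fields(mol)
  c(list(
    mol = mol,
    n = nrow(mol$atoms),
    a1 = mol$bonds$a1,
    a2 = mol$bonds$a2,
    charges = mol$atoms$charge,
    bond_bdes = .bond_bdes(mol, bde_table)
  ), fc)
}

.rec <- function(atoms, broken, bde, depth) {
  list(atoms = atoms, broken = broken, bde = bde, depth = depth)
}

.rec_key <- function(atoms) paste(atoms, collapse = ",")

# All cleavage events of one fragment record; returns list of child recs
# (children below min_mass dropped).
.expand_record <- function(ctx, rec, min_mass) {
  atoms <- rec$atoms
  if (length(atoms) < 2) return(list())
  member <- logical(ctx$n); member[atoms] <- TRUE
  B <- which(member[ctx$a1] & member[ctx$a2])
  if (!length(B)) return(list())
  cs <- .cut_structure(atoms, ctx$n, B, ctx$a1, ctx$a2)
  children <- list()
  emit <- function(cut_bonds) {
    rest <- setdiff(B, cut_bonds)
    comp1 <- .component_from(ctx$a1[cut_bonds[1]], ctx$n, rest,
                             ctx$a1, ctx$a2)
    comp2 <- setdiff(atoms, comp1)
    cut_bde <- sum(ctx$bond_bdes[cut_bonds])
    for (comp in list(comp1, sort(comp2))) {
      if (sum(ctx$atom_masses[comp]) + 1e-9 >= min_mass) {
        children[[length(children) + 1L]] <<- .rec(
          comp, c(rec$broken, cut_bonds), rec$bde + cut_bde, rec$depth + 1L
        )
      }
    }
  }
  for (b in cs$bridges) emit(b)
  if (nrow(cs$ring_pairs)) {
    for (i in seq_len(nrow(cs$ring_pairs))) emit(cs$ring_pairs[i, ])
  }
  children
}

# ---- user-facing operations ------------------------------------------------

#' Bonds eligible for cleavage
#'
#' Exactly the bonds between two heavy atoms; bonds to hydrogen are never
#' cleaved (hydrogens are not graph vertices in this model). Ring flags are
#' perceived within the fragment's own subgraph: a ring bond of the parent
#' can become acyclic in a fragment.
#'
#' @param m an `fr_mol`.
#' @param atoms optional atom subset defining a fragment; default the whole
#'   molecule.
#' @return tibble with columns `bond` (bond id in the parent molecule),
#'   `a1`, `a2`, `order`, `ring`.
#' @export
cleavable_bonds <- function(m, atoms = NULL) {
  stopifnot(inherits(m, "fr_mol"))
  if (is.null(atoms)) atoms <- seq_len(nrow(m$atoms))
  member <- logical(nrow(m$atoms)); member[atoms] <- TRUE
  B <- which(member[m$bonds$a1] & member[m$bonds$a2])
  if (!length(B)) {
    return(tibble::tibble(bond = integer(0), a1 = integer(0),
                          a2 = integer(0), order = integer(0),
                          ring = logical(0)))
  }
  bridges <- .bridge_flags(atoms, nrow(m$atoms), B, m$bonds$a1, m$bonds$a2)
  tibble::tibble(
    bond = B,
    a1 = m$bonds$a1[B], a2 = m$bonds$a2[B], order = m$bonds$order[B],
    ring = !bridges
  )
}

#' Cleave a fragment at one bond or one ring-bond pair
#'
#' A linear (acyclic) bond yields the two connected components; a ring-bond
#' pair yields two components if their joint removal disconnects the
#' fragment, otherwise an empty result.
#'
#' @param m the parent `fr_mol`.
#' @param bonds one bond id (linear cleavage) or two bond ids (ring pair).
#' @param atoms atom subset defining the fragment being cleaved; default
#'   the whole molecule.
#' @param bde_table BDE table for the cumulative-energy bookkeeping.
#' @param parent optional parent fragment state `list(broken=, bde=,
#'   depth=)`; defaults to the intact molecule at depth 0.
#' @return a fragment tibble (see [enumerate_fragments()]) with 0 or 2 rows.
#' @export
cleave <- function(m, bonds, atoms = NULL, bde_table = default_bde_table(),
                   parent = NULL) {
  stopifnot(inherits(m, "fr_mol"), length(bonds) %in% c(1, 2))
  if (is.null(atoms)) atoms <- seq_len(nrow(m$atoms))
  if (is.null(parent)) parent <- list(broken = integer(0), bde = 0,
                                      depth = 0L)
  member <- logical(nrow(m$atoms)); member[atoms] <- TRUE
  B <- which(member[m$bonds$a1] & member[m$bonds$a2])
  if (!all(bonds %in% B)) {
    stop("bond id(s) not part of this fragment: ",
         paste(setdiff(bonds, B), collapse = ", "), call. = FALSE)
  }
  cb <- cleavable_bonds(m, atoms)
  ring <- stats::setNames(cb$ring, cb$bond)
  if (length(bonds) == 1 && ring[[as.character(bonds)]]) {
    stop("bond ", bonds, " is in a ring; ring bonds must be cleaved in ",
         "pairs", call. = FALSE)
  }
  if (length(bonds) == 2 && !all(ring[as.character(bonds)])) {
    stop("ring-pair cleavage requires two in-ring bonds", call. = FALSE)
  }
  ctx <- .frag_ctx(m, bde_table)
  rest <- setdiff(B, bonds)
  comp1 <- .component_from(ctx$a1[bonds[1]], ctx$n, rest, ctx$a1, ctx$a2)
  if (length(comp1) == length(atoms)) {
    # joint removal leaves the fragment connected: not a valid ring cut
    return(.frag_tibble(m, list()))
  }
  comp2 <- sort(setdiff(atoms, comp1))
  cut_bde <- sum(ctx$bond_bdes[bonds])
  recs <- lapply(list(comp1, comp2), function(comp) {
    .rec(comp, c(parent$broken, sort(bonds)), parent$bde + cut_bde,
         parent$depth + 1L)
  })
  .frag_tibble(m, recs)
}

#' Redundancy key of a fragment
#'
#' Two fragments with equal keys are treated as duplicates. Modes:
#' `"molecular_formula"` compares elemental composition only; `"atom_id"`
#' compares the (unique, stable) atom-index set within the parent;
#' `"isomorphism"` compares canonical labelled-graph forms
#' (element/H-count/charge vertex labels, bond orders).
#'
#' @param m the parent `fr_mol`.
#' @param atoms the fragment's atom-index subset.
#' @param mode redundancy mode.
#' @return an opaque key string.
#' @export
redundancy_key <- function(m, atoms,
                           mode = c("molecular_formula", "atom_id",
                                    "isomorphism")) {
  mode <- match.arg(mode)
  switch(mode,
    molecular_formula = formula_string(formula_of(m, atoms)),
    atom_id = .rec_key(sort(atoms)),
    isomorphism = .canonical_key(m, atoms)
  )
}

# Canonical labelled-graph key via BLISS. Bond orders are encoded by
# subdividing every bond with a dummy vertex coloured by the order, since
# BLISS colours vertices only.
.canonical_key <- function(m, atoms) {
  atoms <- sort(atoms)
  k <- length(atoms)
  remap <- integer(nrow(m$atoms)); remap[atoms] <- seq_len(k)
  keep <- which(m$bonds$a1 %in% atoms & m$bonds$a2 %in% atoms)
  at <- m$atoms[atoms, , drop = FALSE]
  vlab <- paste0(at$element, ":", at$nH, ":", at$charge)
  nb <- length(keep)
  elab <- if (nb) paste0("bond", m$bonds$order[keep]) else character(0)
  labels <- c(vlab, elab)
  # fixed global colour scheme: colours comparable across fragments
  colour <- match(labels, sort(unique(labels)))
  # order alone is not canonical across fragments with different label
  # sets, so the key includes the label strings themselves (below)
  edges <- integer(0)
  if (nb > 0) {
    for (i in seq_len(nb)) {
      b <- keep[i]
      mid <- k + i
      edges <- c(edges, remap[m$bonds$a1[b]], mid, mid, remap[m$bonds$a2[b]])
    }
  }
  g <- igraph::make_empty_graph(n = k + nb, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  perm <- igraph::canonical_permutation(g, colors = colour)$labeling
  # canonical form: labels and edges rewritten in canonical vertex order
  inv <- order(perm)
  lab_canon <- labels[inv]
  em <- igraph::as_edgelist(g)
  if (nrow(em)) {
    e1 <- perm[em[, 1]]; e2 <- perm[em[, 2]]
    lo <- pmin(e1, e2); hi <- pmax(e1, e2)
    eo <- order(lo, hi)
    estr <- paste(lo[eo], hi[eo], sep = "-", collapse = ";")
  } else estr <- ""
  paste0(paste(lab_canon, collapse = ","), "|", estr)
}

# ---- fragment enumeration --------------------------------------------------

# Build the user-facing fragment tibble from internal records.
.frag_tibble <- function(m, recs, tag = NA_character_) {
  if (!length(recs)) {
    return(tibble::tibble(
      formula = character(0), mass = numeric(0), depth = integer(0),
      bde = numeric(0), n_atoms = integer(0), charge = integer(0),
      atoms = list(), broken_bonds = list(), tag = character(0)
    ))
  }
  fc <- .fast_ctx_fields(m)
  tibble::tibble(
    formula = vapply(recs, function(r)
      .ctx_formula_string(fc, r$atoms), character(1)),
    mass = vapply(recs, function(r)
      sum(fc$atom_masses[r$atoms]), numeric(1)),
    depth = vapply(recs, function(r) r$depth, integer(1)),
    bde = vapply(recs, function(r) r$bde, numeric(1)),
    n_atoms = vapply(recs, function(r) length(r$atoms), integer(1)),
    charge = vapply(recs, function(r)
      as.integer(sum(m$atoms$charge[r$atoms])), integer(1)),
    atoms = lapply(recs, function(r) r$atoms),
    broken_bonds = lapply(recs, function(r) r$broken),
    tag = rep(tag, length(recs))
  )
}

# Core BFS over one molecule. Expansion is deduplicated by atom subset
# (lossless: identical subsets have identical futures); the reported set is
# deduplicated afterwards under the configured redundancy mode, keeping the
# lower-BDE representative. min_mass may be a function() returning the
# current cutoff (dynamic raising during matching) or a number.
# on_level(recs, depth) is called with the new records of each level.
.bfs_enumerate <- function(ctx, max_depth, min_mass, on_level = NULL) {
  get_min <- if (is.function(min_mass)) min_mass else function() min_mass
  seen <- new.env(parent = emptyenv(), size = 1024L)
  root <- .rec(seq_len(ctx$n), integer(0), 0, 0L)
  records <- list(root)
  assign(.rec_key(root$atoms), 1L, envir = seen)
  if (!is.null(on_level)) on_level(list(root), 0L)
  queue <- list(root)
  depth <- 0L
  while (length(queue) && depth < max_depth) {
    depth <- depth + 1L
    mm <- get_min()
    nxt <- list()
    new_level <- list()
    for (rec in queue) {
      for (child in .expand_record(ctx, rec, mm)) {
        key <- .rec_key(child$atoms)
        idx <- seen[[key]]
        if (is.null(idx)) {
          records[[length(records) + 1L]] <- child
          assign(key, length(records), envir = seen)
          nxt[[length(nxt) + 1L]] <- child
          new_level[[length(new_level) + 1L]] <- child
        } else if (child$bde < records[[idx]]$bde) {
          # cheaper route to a known subset: keep the cheaper provenance
          records[[idx]] <- child
          if (child$depth < max_depth) nxt[[length(nxt) + 1L]] <- child
        }
      }
    }
    if (!is.null(on_level) && length(new_level)) on_level(new_level, depth)
    queue <- nxt
  }
  records
}

# Report-level dedup: among records with equal redundancy key keep the
# lowest cumulative BDE (ties: lower depth, then subset key).
.record_keys <- function(mol, records, mode, fc = NULL) {
  if (mode == "molecular_formula") {
    if (is.null(fc)) fc <- .fast_ctx_fields(mol)
    vapply(records, function(r) .ctx_formula_string(fc, r$atoms),
           character(1))
  } else if (mode == "atom_id") {
    vapply(records, function(r) .rec_key(sort(r$atoms)), character(1))
  } else {
    vapply(records, function(r) .canonical_key(mol, r$atoms), character(1))
  }
}

.dedup_records <- function(mol, records, mode, fc = NULL) {
  if (!length(records)) return(records)
  keys <- .record_keys(mol, records, mode, fc)
  bdes <- vapply(records, function(r) r$bde, numeric(1))
  depths <- vapply(records, function(r) r$depth, integer(1))
  skeys <- vapply(records, function(r) .rec_key(r$atoms), character(1))
  ord <- order(keys, bdes, depths, skeys)
  keep <- ord[!duplicated(keys[ord])]
  records[sort(keep)]
}

#' Enumerate all in-silico fragments of a candidate
#'
#' Breadth-first bond disconnection up to the configured tree depth, with
#' minimum-mass pruning and redundancy elimination. Output order is
#' deterministic: mass descending, then formula, then atom-subset key.
#'
#' @param m a connected `fr_mol`.
#' @param config an [fragmenter_config()].
#' @param bde_table a BDE table ([default_bde_table()]).
#' @return a fragment tibble: `formula`, `mass` (neutral, Da), `depth`,
#'   `bde` (cumulative, kJ/mol), `n_atoms`, `charge` (net formal charge),
#'   `atoms` (list of atom-index vectors), `broken_bonds` (list of bond ids
#'   in cleavage order), `tag` (neutral-loss rule name, `NA` for plain
#'   disconnection fragments).
#' @examples
#' pr <- parse_structure("CCC", "smiles", id = "propane")
#' enumerate_fragments(pr, fragmenter_config(max_depth = 1, min_mass = 10))
#' @export
enumerate_fragments <- function(m, config = fragmenter_config(),
                                bde_table = default_bde_table()) {
  stopifnot(inherits(m, "fr_mol"))
  min_mass <- if (is.null(config$min_mass)) 30 else config$min_mass
  ctx <- .frag_ctx(m, bde_table)
  records <- .bfs_enumerate(ctx, config$max_depth, min_mass)
  is_root <- vapply(records, function(r) r$depth == 0L, logical(1))
  kept <- records[!is_root]
  kept <- kept[vapply(kept, function(r)
    sum(ctx$atom_masses[r$atoms]) + 1e-9 >= min_mass, logical(1))]
  kept <- .dedup_records(m, kept, config$redundancy, ctx)
  if (config$include_root) kept <- c(records[is_root], kept)
  out <- .frag_tibble(m, kept)
  skey <- vapply(out$atoms, .rec_key, character(1))
  out[order(-out$mass, out$formula, skey), ]
}
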