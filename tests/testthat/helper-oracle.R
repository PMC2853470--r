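# Independent brute-force fragment oracle, built on igraph.
#
# Enumerates every connected subgraph reachable from the intact molecule by
# at most `depth` cleavage events, where one event removes either a single
# acyclic (bridge) bond or an unordered pair of ring (non-bridge) bonds
# whose joint removal disconnects the current fragment. No search-order
# shortcuts: every reachable subset is expanded. Results are filtered by
# minimum mass at the end and deduplicated by formula.

oracle_subsets <- function(m, depth) {
  n <- nrow(m$atoms)
  g <- igraph::graph_from_data_frame(
    data.frame(from = m$bonds$a1, to = m$bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n)))
  )
  key <- function(s) paste(sort(as.integer(s)), collapse = ",")
  seen <- new.env(parent = emptyenv())
  frontier <- list(seq_len(n))
  assign(key(frontier[[1]]), TRUE, envir = seen)
  collected <- list()
  for (lev in seq_len(depth)) {
    nxt <- list()
    for (S in frontier) {
      gs <- igraph::induced_subgraph(g, as.character(S))
      es <- igraph::E(gs)
      if (length(es) == 0) next
      br <- igraph::bridges(gs)
      ring_edges <- setdiff(seq_along(es), as.integer(br))
      cuts <- lapply(as.integer(br), function(b) b)
      if (length(ring_edges) >= 2) {
        prs <- utils::combn(ring_edges, 2)
        cuts <- c(cuts, lapply(seq_len(ncol(prs)), function(j) prs[, j]))
      }
      for (cut in cuts) {
        gc <- igraph::delete_edges(gs, cut)
        comp <- igraph::components(gc)
        if (comp$no != 2) next
        for (ci in seq_len(comp$no)) {
          atoms <- as.integer(igraph::V(gs)$name[comp$membership == ci])
          k <- key(atoms)
          if (is.null(seen[[k]])) {
            assign(k, TRUE, envir = seen)
            collected[[length(collected) + 1L]] <- sort(atoms)
            nxt[[length(nxt) + 1L]] <- sort(atoms)
          }
        }
      }
    }
    frontier <- nxt
  }
  collected
}

# Deduplicated formula set of the oracle's fragments at/above min_mass.
oracle_formula_set <- function(m, depth, min_mass = 10) {
  subs <- oracle_subsets(m, depth)
  if (!length(subs)) return(character(0))
  masses <- vapply(subs, function(s)
    monoisotopic_mass(formula_of(m, s)), numeric(1))
  keep <- masses + 1e-9 >= min_mass
  sort(unique(vapply(subs[keep], function(s)
    formula_string(formula_of(m, s)), character(1))))
}

# small molecules (<= 8 heavy atoms) used for oracle comparisons
oracle_smiles <- c(
  ethanol = "CCO", propane = "CCC", butane = "CCCC",
  isobutane = "CC(C)C", cyclopropane = "C1CC1", cyclobutane = "C1CCC1",
  cyclopentane = "C1CCCC1", cyclohexane = "C1CCCCC1",
  benzene = "c1ccccc1", furan = "c1ccoc1", pyrrole = "c1cc[nH]c1",
  thiophene = "c1ccsc1", pyridine = "c1ccncc1", toluene = "Cc1ccccc1",
  phenol = "Oc1ccccc1", acetone = "CC(C)=O", acetic_acid = "CC(=O)O",
  glycine = "NCC(=O)O", methylamine = "CN", dimethyl_ether = "COC",
  propanol = "CCCO", glycol = "OCCO", acetonitrile = "CC#N",
  glycerol = "OCC(O)CO"
)

parse_smi <- function(smi, id = "m") parse_structure(smi, "smiles", id = id)
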