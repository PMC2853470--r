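# Internal plain-R graph helpers for the heavy-atom graph.
#
# The fragmenter calls these in a tight loop, so everything works on flat
# integer vectors (bond endpoint arrays a1/a2 indexed by bond id) rather
# than adjacency objects. Atom ids are always indices into the parent
# molecule's atom table, so membership masks are logical vectors of the
# molecule's atom count.

# Connected component containing `seed`, over atoms `atoms` and bonds whose
# ids are in `bond_ids` (endpoints a1/a2). Returns sorted atom ids.
.component_from <- function(seed, n_atoms, bond_ids, a1, a2) {
  if (length(bond_ids) == 0) return(seed)
  b1 <- a1[bond_ids]; b2 <- a2[bond_ids]
  visited <- logical(n_atoms)
  visited[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    hit <- visited[b1] | visited[b2]
    nxt <- unique(c(b1[hit], b2[hit]))
    nxt <- nxt[!visited[nxt]]
    if (!length(nxt)) break
    visited[nxt] <- TRUE
    keep <- !(visited[b1] & visited[b2])
    b1 <- b1[keep]; b2 <- b2[keep]
    frontier <- nxt
  }
  which(visited)
}

# Are atoms `atoms` connected under bonds `bond_ids`?
.is_connected <- function(atoms, n_atoms, bond_ids, a1, a2) {
  if (length(atoms) <= 1) return(TRUE)
  comp <- .component_from(atoms[1], n_atoms, bond_ids, a1, a2)
  length(comp) == length(atoms)
}

# BFS spanning tree of the subgraph (atoms, bond_ids). Assumes connected.
# Returns list(order, parent_atom, parent_bond, depth) where vectors are
# indexed by molecule atom id (NA outside the subgraph). parent_bond[root]
# is NA.
.spanning_tree <- function(atoms, n_atoms, bond_ids, a1, a2) {
  parent_atom <- rep(NA_integer_, n_atoms)
  parent_bond <- rep(NA_integer_, n_atoms)
  depth <- rep(NA_integer_, n_atoms)
  root <- atoms[1]
  depth[root] <- 0L
  # incidence: for each subgraph atom, the bonds touching it
  inc <- vector("list", n_atoms)
  for (b in bond_ids) {
    inc[[a1[b]]] <- c(inc[[a1[b]]], b)
    inc[[a2[b]]] <- c(inc[[a2[b]]], b)
  }
  queue <- root; qi <- 1L
  order <- integer(length(atoms)); oi <- 0L
  while (qi <= length(queue)) {
    v <- queue[qi]; qi <- qi + 1L
    oi <- oi + 1L; order[oi] <- v
    for (b in inc[[v]]) {
      w <- if (a1[b] == v) a2[b] else a1[b]
      if (is.na(depth[w])) {
        depth[w] <- depth[v] + 1L
        parent_atom[w] <- v
        parent_bond[w] <- b
        queue <- c(queue, w)
      }
    }
  }
  list(order = order[seq_len(oi)], parent_atom = parent_atom,
       parent_bond = parent_bond, depth = depth)
}

# Shortest-path (bond count) distances from `source` within the subgraph.
# Returns integer vector indexed by molecule atom id (NA if unreachable).
.bfs_distances <- function(source, n_atoms, bond_ids, a1, a2) {
  dist <- rep(NA_integer_, n_atoms)
  dist[source] <- 0L
  inc1 <- a1[bond_ids]; inc2 <- a2[bond_ids]
  frontier <- source
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    hit <- (inc1 %in% frontier) | (inc2 %in% frontier)
    nxt <- unique(c(inc1[hit], inc2[hit]))
    nxt <- nxt[is.na(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Bridge classification for the subgraph (atoms, bond_ids): a bond is a
# bridge iff it lies on no cycle. Derived from the spanning-tree cover
# structure computed by .cut_structure().
.bridge_flags <- function(atoms, n_atoms, bond_ids, a1, a2) {
  cs <- .cut_structure(atoms, n_atoms, bond_ids, a1, a2)
  flags <- stats::setNames(logical(length(bond_ids)), bond_ids)
  flags[as.character(cs$bridges)] <- TRUE
  unname(flags[as.character(bond_ids)])
}

# Spanning-tree cover-set analysis of a connected subgraph.
#
# Fix a BFS spanning tree T. Every non-tree bond f "covers" the tree bonds
# on the tree path between its endpoints. Then:
#   * a tree bond with an empty cover set is a bridge;
#   * {tree e, non-tree f} is a 2-edge-cut iff cover(e) == {f};
#   * {tree e1, tree e2} is a 2-edge-cut iff their (nonempty) cover sets
#     are identical;
#   * two non-tree bonds never disconnect the graph (the tree survives).
# This yields all single-bond and ring-bond-pair cleavages without testing
# every candidate pair for connectivity.
#
# Returns list(bridges = bond ids, ring_pairs = 2-column matrix of bond id
# pairs (each row an unordered pair forming a 2-edge-cut), tree = spanning
# tree, nontree = non-tree bond ids).
.cut_structure <- function(atoms, n_atoms, bond_ids, a1, a2) {
  st <- .spanning_tree(atoms, n_atoms, bond_ids, a1, a2)
  tree_bonds <- st$parent_bond[!is.na(st$parent_bond)]
  nontree <- setdiff(bond_ids, tree_bonds)
  # position of each tree bond, indexed by bond id
  tpos <- integer(if (length(bond_ids)) max(bond_ids) else 0)
  tpos[tree_bonds] <- seq_along(tree_bonds)
  cover <- vector("list", length(tree_bonds))
  for (f in nontree) {
    u <- a1[f]; v <- a2[f]
    # walk both endpoints up to their LCA, marking tree bonds passed
    while (u != v) {
      if (st$depth[u] >= st$depth[v]) {
        p <- tpos[st$parent_bond[u]]
        cover[[p]] <- c(cover[[p]], f)
        u <- st$parent_atom[u]
      } else {
        p <- tpos[st$parent_bond[v]]
        cover[[p]] <- c(cover[[p]], f)
        v <- st$parent_atom[v]
      }
    }
  }
  keys <- vapply(cover, function(cv) {
    if (is.null(cv)) "" else paste(sort(cv), collapse = ",")
  }, character(1))
  bridges <- tree_bonds[keys == ""]
  pairs <- list()
  # tree-tree pairs: identical nonempty cover sets
  nz <- which(keys != "")
  if (length(nz)) {
    grp <- split(tree_bonds[nz], keys[nz])
    for (g in grp) {
      if (length(g) >= 2) {
        cmb <- utils::combn(sort(g), 2)
        pairs[[length(pairs) + 1L]] <- t(cmb)
      }
    }
    # tree-nontree pairs: cover set of size one
    single <- nz[!grepl(",", keys[nz])]
    if (length(single)) {
      pairs[[length(pairs) + 1L]] <- cbind(
        tree_bonds[single], as.integer(keys[single])
      )
    }
  }
  ring_pairs <- if (length(pairs)) do.call(rbind, pairs)
                else matrix(integer(0), ncol = 2)
  # normalize: unordered, sorted rows, deterministic order
  if (nrow(ring_pairs)) {
    ring_pairs <- t(apply(ring_pairs, 1, sort))
    ring_pairs <- ring_pairs[order(ring_pairs[, 1], ring_pairs[, 2]), ,
                             drop = FALSE]
  }
  list(bridges = sort(bridges), ring_pairs = ring_pairs,
       tree = st, nontree = nontree)
}
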