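# Ring perception on the parsed molecular graph.  The ring basis is the
# smallest set of smallest rings (SSSR): candidate rings are the shortest
# cycles through each ring bond, and a linearly independent subset (over
# GF(2) on edge incidence) of cyclomatic size is selected smallest-first.

# Returns a list of integer vectors of atom indices, one per SSSR ring.
sssr_rings <- function(mg) {
  bonds <- mg$bonds
  n_ring <- nrow(bonds) - nrow(mg$atoms) +
    igraph::count_components(mg$graph)
  if (n_ring <= 0) return(list())
  ring_bond_ids <- which(bonds$in_ring)

  candidates <- list()
  for (eid in ring_bond_ids) {
    g2 <- igraph::delete_edges(mg$graph, eid)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = bonds$from[eid], to = bonds$to[eid], output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) >= 3) candidates[[length(candidates) + 1]] <- path
  }
  if (length(candidates) == 0) return(list())

  # deduplicate by atom set, order by ring size
  keys <- vapply(candidates, function(p) paste(sort(p), collapse = ","), "")
  candidates <- candidates[!duplicated(keys)]
  candidates <- candidates[order(vapply(candidates, length, 1L))]

  edge_vec <- function(path) {
    cyc <- c(path, path[1])
    v <- rep(FALSE, nrow(bonds))
    for (k in seq_len(length(cyc) - 1)) {
      a <- cyc[k]; b <- cyc[k + 1]
      hit <- which((bonds$from == a & bonds$to == b) |
                     (bonds$from == b & bonds$to == a))
      v[hit[1]] <- TRUE
    }
    v
  }

  basis <- list()     # reduced GF(2) vectors
  chosen <- list()
  for (cand in candidates) {
    if (length(chosen) >= n_ring) break
    v <- edge_vec(cand)
    w <- v
    for (b in basis) {
      pivot <- which(b)[1]
      if (w[pivot]) w <- xor(w, b)
    }
    if (any(w)) {
      basis[[length(basis) + 1]] <- w
      chosen[[length(chosen) + 1]] <- cand
    }
  }
  chosen
}

#' Fused ring systems of a molecule
#'
#' Perceives the SSSR ring basis and groups rings into fused systems: two
#' rings belong to the same system when they share at least one bond
#' (spiro junctions, which share only an atom, do not fuse).
#'
#' @param mol A valid [molecule] object (or SMILES string).
#' @return A list with one entry per fused system; each entry is a list with
#'   `ring_sizes` (integer vector) and `n_rings`.
#' @examples
#' fused_ring_systems(canonicalize("c1ccc2ccccc2c1"))  # naphthalene: one [6,6]
#' @export
fused_ring_systems <- function(mol) {
  mol <- as_molecule(mol)
  hit <- cache_get("fused", mol$smiles_canonical)
  if (!is.null(hit)) return(hit)
  mg <- molecule_graph(mol)
  rings <- sssr_rings(mg)
  if (length(rings) == 0) {
    return(cache_set("fused", mol$smiles_canonical, list()))
  }
  ring_bond_key <- function(path) {
    cyc <- c(path, path[1])
    vapply(seq_len(length(cyc) - 1), function(k) {
      paste(sort(c(cyc[k], cyc[k + 1])), collapse = "-")
    }, "")
  }
  bond_sets <- lapply(rings, ring_bond_key)
  nr <- length(rings)
  adj <- matrix(FALSE, nr, nr)
  if (nr > 1) {
    for (a in 1:(nr - 1)) for (b in (a + 1):nr) {
      if (length(intersect(bond_sets[[a]], bond_sets[[b]])) > 0) {
        adj[a, b] <- adj[b, a] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- lapply(unique(comp), function(ci) {
    members <- which(comp == ci)
    list(ring_sizes = sort(vapply(rings[members], length, 1L)),
         n_rings = length(members),
         rings = rings[members])
  })
  cache_set("fused", mol$smiles_canonical, out)
}

# Number of SSSR rings (cyclomatic number).
ring_count <- function(mol) {
  mg <- molecule_graph(mol)
  max(0L, nrow(mg$bonds) - nrow(mg$atoms) +
        igraph::count_components(mg$graph))
}

# Aromatic SSSR ring count (every ring bond aromatic), used by the
# drug-likeness descriptors.
aromatic_ring_count <- function(mg) {
  rings <- sssr_rings(mg)
  if (length(rings) == 0) return(0L)
  arom <- vapply(rings, function(path) {
    cyc <- c(path, path[1])
    all(vapply(seq_len(length(cyc) - 1), function(k) {
      a <- cyc[k]; b <- cyc[k + 1]
      hit <- which((mg$bonds$from == a & mg$bonds$to == b) |
                     (mg$bonds$from == b & mg$bonds$to == a))
      mg$bonds$aromatic[hit[1]]
    }, TRUE))
  }, TRUE)
  sum(arom)
}
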