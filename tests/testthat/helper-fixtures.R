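# Shared fixtures, built once per test run and memoised.  All molecule sets
# are generated in code from the seeded fixture generator; nothing is read
# from disk.

.shared <- new.env(parent = emptyenv())

shared <- function(name, build) {
  if (is.null(.shared[[name]])) .shared[[name]] <- build()
  .shared[[name]]
}

# small diverse library used across module tests
small_lib <- function() shared("small_lib", function() {
  generate_library(fixture_config(n_molecules = 120, rng_seed = 11))
})

small_pairs <- function() shared("small_pairs", function() {
  library_pairs(small_lib())
})

small_nn <- function() shared("small_nn", function() {
  nn_decoder(small_pairs())
})

mgraph <- function(smiles) molevo:::molecule_graph(canonicalize(smiles))

# independent brute-force oracles -----------------------------------------

# adjacency list from a molecule's bond table (no igraph)
bf_adj <- function(mg) {
  n <- nrow(mg$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mg$bonds))) {
    a <- mg$bonds$from[k]; b <- mg$bonds$to[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# shortest path between two atoms avoiding one forbidden edge (plain BFS)
bf_shortest <- function(adj, from, to, avoid) {
  n <- length(adj)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n); seen[from] <- TRUE
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if ((v == avoid[1] && w == avoid[2]) ||
          (v == avoid[2] && w == avoid[1])) next
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- v
        if (w == to) {
          path <- w
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# brute-force smallest-set-of-smallest-rings: shortest cycle through every
# cycle edge, greedy GF(2)-independent selection, smallest first
bf_sssr <- function(mg) {
  nb <- nrow(mg$bonds)
  n_ring <- nb - nrow(mg$atoms) + n_components_bf(mg)
  if (n_ring <= 0) return(list())
  adj <- bf_adj(mg)
  cands <- list()
  for (k in seq_len(nb)) {
    p <- bf_shortest(adj, mg$bonds$from[k], mg$bonds$to[k],
                     c(mg$bonds$from[k], mg$bonds$to[k]))
    if (!is.null(p) && length(p) >= 3) cands[[length(cands) + 1]] <- p
  }
  keys <- vapply(cands, function(p) paste(sort(p), collapse = ","), "")
  cands <- cands[!duplicated(keys)]
  cands <- cands[order(vapply(cands, length, 1L))]
  edge_id <- function(a, b) {
    which((mg$bonds$from == a & mg$bonds$to == b) |
            (mg$bonds$from == b & mg$bonds$to == a))[1]
  }
  evec <- function(p) {
    cyc <- c(p, p[1]); v <- rep(FALSE, nb)
    for (i in seq_len(length(cyc) - 1)) v[edge_id(cyc[i], cyc[i + 1])] <- TRUE
    v
  }
  basis <- list(); chosen <- list()
  for (p in cands) {
    if (length(chosen) >= n_ring) break
    w <- evec(p)
    for (b in basis) { pv <- which(b)[1]; if (w[pv]) w <- xor(w, b) }
    if (any(w)) { basis <- c(basis, list(w)); chosen <- c(chosen, list(p)) }
  }
  chosen
}

n_components_bf <- function(mg) {
  n <- nrow(mg$atoms)
  adj <- bf_adj(mg)
  seen <- rep(FALSE, n); comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  comp
}

# brute-force fused systems: union-find over rings sharing a bond
bf_fused_systems <- function(mg) {
  rings <- bf_sssr(mg)
  if (length(rings) == 0) return(list())
  bond_keys <- lapply(rings, function(p) {
    cyc <- c(p, p[1])
    vapply(seq_len(length(cyc) - 1), function(i) {
      paste(sort(c(cyc[i], cyc[i + 1])), collapse = "-")
    }, "")
  })
  parent <- seq_along(rings)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nr <- length(rings)
  if (nr > 1) {
    for (a in 1:(nr - 1)) for (b in (a + 1):nr) {
      if (length(intersect(bond_keys[[a]], bond_keys[[b]])) > 0) {
        parent[find(a)] <- find(b)
      }
    }
  }
  roots <- vapply(seq_along(rings), find, 1L)
  lapply(unique(roots), function(r) {
    members <- which(roots == r)
    sort(vapply(rings[members], length, 1L))
  })
}

# brute-force longest alkyl chain: DFS over all simple paths in the
# eligible-carbon subgraph
bf_longest_alkyl <- function(mg) {
  atoms <- mg$atoms; bonds <- mg$bonds
  sp3 <- rep(TRUE, nrow(atoms))
  if (nrow(bonds) > 0) {
    bad <- bonds$order != 1 | bonds$aromatic
    sp3[unique(c(bonds$from[bad], bonds$to[bad]))] <- FALSE
  }
  ok <- atoms$elem == "C" & !atoms$aromatic & !atoms$in_ring & sp3
  for (a in which(ok)) {
    k <- which(bonds$from == a | bonds$to == a)
    other <- ifelse(bonds$from[k] == a, bonds$to[k], bonds$from[k])
    if (any(atoms$elem[other] != "C")) ok[a] <- FALSE
  }
  idx <- which(ok)
  if (length(idx) == 0) return(0L)
  adj <- bf_adj(mg)
  best <- 1L
  dfs <- function(v, visited) {
    best <<- max(best, length(visited))
    for (w in adj[[v]]) {
      if (w %in% idx && !(w %in% visited)) dfs(w, c(visited, w))
    }
  }
  for (s in idx) dfs(s, s)
  best
}

# brute-force tanimoto over explicit bit sets
bf_tanimoto <- function(a, b) {
  sa <- which(a >= 0.5); sb <- which(b >= 0.5)
  if (length(sa) == 0 && length(sb) == 0) return(1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}
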