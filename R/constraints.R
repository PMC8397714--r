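# Structural blacklist and property-window filtering of generated molecules.
# The blacklist encodes three rules applied during evolution: fused-ring
# sizes limited to 4-7, at most 6 rings per fused system, alkyl chains at
# most 6 carbons; plus a ring-count window around the seed so candidates
# keep the seed's overall shape.

#' Blacklist configuration for structural filtering
#'
#' @param fused_ring_size_min,fused_ring_size_max Allowed ring sizes inside
#'   fused systems (default 4-7).
#' @param max_fused_rings Maximum rings per fused system (default 6).
#' @param max_alkyl_chain Maximum alkyl-chain length in carbons (default 6).
#' @param ring_delta_limit Allowed |ring count(candidate) - ring count(seed)|;
#'   removal triggers at a difference of two, so the default window is 1.
#' @return A `blacklist_config` list.
#' @export
blacklist_config <- function(fused_ring_size_min = 4, fused_ring_size_max = 7,
                             max_fused_rings = 6, max_alkyl_chain = 6,
                             ring_delta_limit = 1) {
  stopifnot(fused_ring_size_min <= fused_ring_size_max,
            max_fused_rings > 0, max_alkyl_chain > 0, ring_delta_limit >= 0)
  structure(list(fused_ring_size_min = fused_ring_size_min,
                 fused_ring_size_max = fused_ring_size_max,
                 max_fused_rings = max_fused_rings,
                 max_alkyl_chain = max_alkyl_chain,
                 ring_delta_limit = ring_delta_limit),
            class = "blacklist_config")
}

#' Longest alkyl chain of a molecule
#'
#' Length (in carbons) of the longest simple path through acyclic,
#' non-aromatic, sp3 carbons whose heavy neighbours are all carbon.
#'
#' @param mol A valid [molecule] (or SMILES string).
#' @return Integer chain length (0 when no such carbon exists).
#' @examples
#' longest_alkyl_chain("CCCCCCC")    # 7
#' longest_alkyl_chain("CC(C)C")     # 3
#' @export
longest_alkyl_chain <- function(mol) {
  mol <- as_molecule(mol)
  hit <- cache_get("alkyl", mol$smiles_canonical)
  if (!is.null(hit)) return(hit)
  mg <- molecule_graph(mol)
  atoms <- mg$atoms; bonds <- mg$bonds
  # sp3 carbons: all incident bonds single and non-aromatic
  sp3 <- rep(TRUE, nrow(atoms))
  if (nrow(bonds) > 0) {
    bad <- bonds$order != 1 | bonds$aromatic
    sp3[unique(c(bonds$from[bad], bonds$to[bad]))] <- FALSE
  }
  chain <- atoms$elem == "C" & !atoms$aromatic & !atoms$in_ring & sp3
  # heavy neighbours must all be carbon
  for (a in which(chain)) {
    k <- which(bonds$from == a | bonds$to == a)
    other <- ifelse(bonds$from[k] == a, bonds$to[k], bonds$from[k])
    if (any(atoms$elem[other] != "C")) chain[a] <- FALSE
  }
  idx <- which(chain)
  res <- if (length(idx) == 0) 0L else {
    sub <- igraph::induced_subgraph(mg$graph, idx)
    # chain-carbon subgraph is a forest; longest path = max component diameter
    comps <- igraph::decompose(sub)
    max(vapply(comps, function(g) {
      as.integer(igraph::diameter(g, unconnected = TRUE)) + 1L
    }, 1L))
  }
  cache_set("alkyl", mol$smiles_canonical, res)
}

#' Structural blacklist check against a seed molecule
#'
#' Fails when any fused system contains a ring smaller than 4 or larger
#' than 7 atoms, when a fused system has more than 6 rings, when the longest
#' alkyl chain exceeds 6 carbons, or when the candidate's ring count moves
#' further than `ring_delta_limit` from the seed's.
#'
#' @param mol Candidate [molecule].
#' @param seed Seed [molecule] the campaign started from.
#' @param cfg A [blacklist_config()].
#' @return List with `pass` (logical) and `reasons` (character vector).
#' @export
check_structural <- function(mol, seed, cfg = blacklist_config()) {
  mol <- as_molecule(mol); seed <- as_molecule(seed)
  if (!mol$is_valid || !seed$is_valid) stopf("check_structural: invalid molecule")
  reasons <- character(0)
  systems <- fused_ring_systems(mol)
  for (sys in systems) {
    # the ring-size rule governs rings inside fused systems (>= 2 rings)
    if (sys$n_rings > 1 &&
        any(sys$ring_sizes < cfg$fused_ring_size_min |
              sys$ring_sizes > cfg$fused_ring_size_max)) {
      reasons <- c(reasons, "fused_ring_size")
    }
    if (sys$n_rings > cfg$max_fused_rings) {
      reasons <- c(reasons, "max_fused_rings")
    }
  }
  if (longest_alkyl_chain(mol) > cfg$max_alkyl_chain) {
    reasons <- c(reasons, "alkyl_chain")
  }
  if (abs(ring_count(mol) - ring_count(seed)) > cfg$ring_delta_limit) {
    reasons <- c(reasons, "ring_delta")
  }
  reasons <- unique(reasons)
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Property window
#'
#' Strict open interval for one named property, e.g. the frontier-orbital
#' windows -7.0 eV < HOMO < -5.0 eV and LUMO < 0.0 eV.
#'
#' @param name Property name.
#' @param lower,upper Strict bounds (may be `-Inf` / `Inf`).
#' @return A `property_window` list.
#' @export
property_window <- function(name, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper)
  structure(list(name = name, lower = lower, upper = upper),
            class = "property_window")
}

#' Check a property vector against windows
#'
#' @param props Named list/vector of property values.
#' @param windows List of [property_window()] objects.
#' @return `TRUE` iff every strict inequality holds.
#' @export
check_property_window <- function(props, windows) {
  for (w in windows) {
    if (!(w$name %in% names(props))) {
      stopf("check_property_window: missing property '%s'", w$name)
    }
    v <- as.numeric(props[[w$name]])
    if (!(v > w$lower && v < w$upper)) return(FALSE)
  }
  TRUE
}

#' Remove molecules already present in a reference library
#'
#' @param mols List of [molecule] objects.
#' @param reference Character vector/set of canonical SMILES.
#' @return The input list with known molecules removed, order preserved.
#' @export
dedup_against <- function(mols, reference) {
  keep <- vapply(mols, function(m) {
    !(as_molecule(m)$smiles_canonical %in% reference)
  }, TRUE)
  mols[keep]
}
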