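# Restricted SMILES reader backing the validity inspector and the graph
# operations (Morgan encoding, ring perception, chain search).  It covers the
# organic subset plus bracket atoms, branches, ring-closure labels (including
# %nn), explicit bond symbols and dot-separated components -- the dialect the
# canonicalizer emits for the chemistry this package works in.  Stereo marks
# (/ \ @) are read and ignored; see canonicalize() which strips them.
# Parse problems are reported, never raised, so the inspector can classify
# them.

ORGANIC_ALIPHATIC <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
ORGANIC_AROMATIC <- c("b", "c", "n", "o", "p", "s")

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                   Cl = 17, Br = 35, I = 53)

# Default valences used for implicit-hydrogen assignment (first match whose
# valence covers the bond-order sum; S and P get their common hypervalent
# alternatives).
DEFAULT_VALENCE <- list(B = 3, C = 4, N = c(3, 5), O = 2, F = 1,
                        P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

parse_failure <- function(reason, detail = "") {
  list(ok = FALSE, reason = reason, detail = detail)
}

# Parse a SMILES string into an atom/bond table.
# Returns list(ok, reason, detail, atoms, bonds).
# atoms: data.frame(symbol, elem, aromatic, charge, h_explicit (NA if
# implicit), n_h filled in later)
# bonds: data.frame(from, to, order, aromatic)
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) {
    return(parse_failure("parse", "empty or non-string input"))
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atom_symbol <- character(0)
  atom_elem <- character(0)
  atom_arom <- logical(0)
  atom_charge <- integer(0)
  atom_hexp <- integer(0)      # NA_integer_ => implicit
  bond_from <- integer(0)
  bond_to <- integer(0)
  bond_order <- numeric(0)
  bond_arom <- logical(0)

  prev <- NA_integer_          # index of atom awaiting a bond
  stack <- integer(0)          # branch stack
  pending_bond <- NA_character_
  rings <- list()              # label -> list(atom, bond)
  i <- 1

  add_atom <- function(symbol, elem, aromatic, charge, hexp) {
    atom_symbol[length(atom_symbol) + 1L] <<- symbol
    atom_elem[length(atom_elem) + 1L] <<- elem
    atom_arom[length(atom_arom) + 1L] <<- aromatic
    atom_charge[length(atom_charge) + 1L] <<- charge
    atom_hexp[length(atom_hexp) + 1L] <<- hexp
    length(atom_elem)
  }

  bond_order_of <- function(sym, a, b) {
    # aromatic bond when unspecified between two aromatic atoms
    if (is.na(sym) || sym %in% c("/", "\\")) {
      if (atom_arom[a] && atom_arom[b]) return(c(1.5, TRUE))
      return(c(1, FALSE))
    }
    switch(sym,
           "-" = c(1, FALSE), "=" = c(2, FALSE), "#" = c(3, FALSE),
           "$" = c(4, FALSE), ":" = c(1.5, TRUE),
           c(NA, NA))
  }

  add_bond <- function(a, b, sym) {
    ob <- bond_order_of(sym, a, b)
    bond_from[length(bond_from) + 1L] <<- a
    bond_to[length(bond_to) + 1L] <<- b
    bond_order[length(bond_order) + 1L] <<- ob[1]
    bond_arom[length(bond_arom) + 1L] <<- as.logical(ob[2])
  }

  connect <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, pending_bond)
    prev <<- idx
    pending_bond <<- NA_character_
  }

  handle_ring <- function(label) {
    key <- as.character(label)
    if (is.null(rings[[key]])) {
      if (is.na(prev)) return(parse_failure("parse", "ring label before atom"))
      rings[[key]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- NA_character_
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      if (is.na(prev)) return(parse_failure("parse", "ring label before atom"))
      sym <- if (!is.na(pending_bond)) pending_bond else open$bond
      if (open$atom == prev) {
        return(parse_failure("ring_closure", "self ring bond"))
      }
      add_bond(open$atom, prev, sym)
      pending_bond <<- NA_character_
    }
    NULL
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) return(parse_failure("parse", "branch before any atom"))
      stack <- c(stack, prev)
      i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) {
        return(parse_failure("parentheses", "unmatched close"))
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
      i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      bad <- handle_ring(ch)
      if (!is.null(bad)) return(bad)
      i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1], chars[i + 2]))) {
        return(parse_failure("parse", "bad %nn ring label"))
      }
      bad <- handle_ring(paste0(chars[i + 1], chars[i + 2]))
      if (!is.null(bad)) return(bad)
      i <- i + 3
    } else if (ch == "[") {
      j <- i + 1
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) return(parse_failure("parse", "unclosed bracket atom"))
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      m <- regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2}H?[0-9]*)((?:\\+{1,}|-{1,}|[+-][0-9]+)?)$",
        body)
      parts <- regmatches(body, m)[[1]]
      if (length(parts) == 0) {
        return(parse_failure("parse", paste("bad bracket atom", body)))
      }
      sym <- parts[3]
      aromatic <- sym %in% ORGANIC_AROMATIC
      elem <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      if (!(elem %in% names(ATOMIC_NUMBER))) {
        return(parse_failure("parse", paste("unknown element", elem)))
      }
      hpart <- parts[4]
      hexp <- 0L
      hm <- regmatches(hpart, regexec("H([0-9]*)", hpart))[[1]]
      if (length(hm) > 0) {
        hexp <- if (nzchar(hm[2])) as.integer(hm[2]) else 1L
      }
      cpart <- parts[5]
      charge <- 0L
      if (nzchar(cpart)) {
        if (grepl("^[+-][0-9]+$", cpart)) {
          charge <- as.integer(cpart)
        } else {
          charge <- (nchar(cpart)) * (if (substr(cpart, 1, 1) == "+") 1L else -1L)
        }
      }
      idx <- add_atom(paste0("[", body, "]"), elem, aromatic, charge, hexp)
      connect(idx)
      i <- j + 1
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, two, FALSE, 0L, NA_integer_)
        connect(idx)
        i <- i + 2
      } else if (ch %in% ORGANIC_ALIPHATIC) {
        idx <- add_atom(ch, ch, FALSE, 0L, NA_integer_)
        connect(idx)
        i <- i + 1
      } else if (ch %in% ORGANIC_AROMATIC) {
        idx <- add_atom(ch, toupper(ch), TRUE, 0L, NA_integer_)
        connect(idx)
        i <- i + 1
      } else {
        return(parse_failure("parse", paste("unexpected symbol", ch)))
      }
    } else {
      return(parse_failure("parse", paste("unexpected character", ch)))
    }
  }

  if (length(stack) > 0) return(parse_failure("parentheses", "unmatched open"))
  if (length(rings) > 0) return(parse_failure("ring_closure", "unclosed ring bond"))
  if (length(atom_elem) == 0) return(parse_failure("parse", "no atoms"))
  if (any(is.na(bond_order))) return(parse_failure("parse", "bad bond symbol"))

  atoms <- data.frame(symbol = atom_symbol, elem = atom_elem,
                      aromatic = atom_arom, charge = atom_charge,
                      h_explicit = atom_hexp, stringsAsFactors = FALSE)
  bonds <- if (length(bond_from) > 0) {
    data.frame(from = bond_from, to = bond_to, order = bond_order,
               aromatic = bond_arom)
  } else {
    data.frame(from = integer(0), to = integer(0), order = numeric(0),
               aromatic = logical(0))
  }
  list(ok = TRUE, reason = NA_character_, detail = "", atoms = atoms,
       bonds = bonds)
}

# Implicit hydrogen counts from default valences; bracket atoms use their
# explicit H count.  Aromatic bonds contribute 1.5 to the bond-order sum.
assign_hydrogens <- function(parsed) {
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  bsum <- numeric(nrow(atoms))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$from[k]] <- bsum[bonds$from[k]] + bonds$order[k]
      bsum[bonds$to[k]] <- bsum[bonds$to[k]] + bonds$order[k]
    }
  }
  degree <- tabulate(c(bonds$from, bonds$to), nbins = nrow(atoms))
  nh <- integer(nrow(atoms))
  for (a in seq_len(nrow(atoms))) {
    if (!is.na(atoms$h_explicit[a])) {
      nh[a] <- atoms$h_explicit[a]
      next
    }
    if (atoms$aromatic[a]) {
      # organic-subset aromatic atom: only a two-connected carbon carries an
      # implicit hydrogen (c1ccccc1); heteroaromatics written without
      # brackets are pyridine-like and carry none
      nh[a] <- if (atoms$elem[a] == "C" && degree[a] == 2) 1L else 0L
      next
    }
    vals <- DEFAULT_VALENCE[[atoms$elem[a]]]
    if (is.null(vals)) { nh[a] <- 0L; next }
    need <- ceiling(bsum[a] - 1e-9)
    v <- vals[vals >= need]
    nh[a] <- if (length(v) == 0) 0L else as.integer(v[1] - need)
  }
  atoms$n_h <- nh
  atoms$degree <- degree
  parsed$atoms <- atoms
  parsed
}

# Full molecular graph for a (preferably canonical) SMILES: atoms with
# hydrogen counts, ring membership, and an igraph object for traversals.
mol_graph <- function(smiles) {
  parsed <- parse_smiles(smiles)
  if (!parsed$ok) {
    stopf("cannot build graph: %s (%s)", parsed$reason, parsed$detail)
  }
  parsed <- assign_hydrogens(parsed)
  g <- igraph::make_empty_graph(n = nrow(parsed$atoms), directed = FALSE)
  if (nrow(parsed$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(parsed$bonds$from, parsed$bonds$to))
  }
  ring_edge <- rep(FALSE, nrow(parsed$bonds))
  if (nrow(parsed$bonds) > 0) {
    br <- igraph::bridges(g)
    ring_edge <- !(seq_len(nrow(parsed$bonds)) %in% as.integer(br))
  }
  parsed$bonds$in_ring <- ring_edge
  in_ring <- rep(FALSE, nrow(parsed$atoms))
  if (any(ring_edge)) {
    in_ring[unique(c(parsed$bonds$from[ring_edge],
                     parsed$bonds$to[ring_edge]))] <- TRUE
  }
  parsed$atoms$in_ring <- in_ring
  parsed$graph <- g
  parsed
}
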