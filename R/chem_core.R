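# Molecule parsing/canonicalization, ECFP encoding, validity inspection and
# fingerprint similarity.  OpenBabel (via ChemmineOB) is the parsing and
# canonicalization authority; the validity inspector layers the workflow's
# own grammar checks (parentheses, ring closures, kekulization feasibility)
# on top, because the toolkit silently repairs some of these.

# package-level memo caches (canonical SMILES -> graph / fingerprint / props)
.molevo_cache <- new.env(parent = emptyenv())

cache_get <- function(kind, key) {
  store <- .molevo_cache[[kind]]
  if (is.null(store)) return(NULL)
  store[[key]]
}

cache_set <- function(kind, key, value) {
  store <- .molevo_cache[[kind]]
  if (is.null(store)) {
    store <- new.env(parent = emptyenv())
    .molevo_cache[[kind]] <- store
  }
  store[[key]] <- value
  value
}

#' Clear molevo's internal molecule caches
#' @return Invisibly, `NULL`.
#' @export
clear_mol_cache <- function() {
  rm(list = ls(.molevo_cache), envir = .molevo_cache)
  invisible(NULL)
}

ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text),
                  error = function(e) "")
  out
}

ob_canonical_one <- function(smiles) {
  out <- ob_convert("SMI", "CAN", smiles)
  line <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(line) == 0) return(NA_character_)
  field <- strsplit(line[1], "\t", fixed = TRUE)[[1]]
  if (length(field) == 0 || !nzchar(field[1])) return(NA_character_)
  field[1]
}

new_molecule <- function(input, canonical = NA_character_, valid = FALSE) {
  structure(list(smiles_input = input,
                 smiles_canonical = canonical,
                 is_valid = valid),
            class = "molecule")
}

#' Parse and canonicalize a SMILES string
#'
#' Runs the validity inspection (see [inspect_validity()]) and, on success,
#' converts the string to the toolkit's canonical SMILES form with stereo
#' and isotope annotations stripped (this package treats constitution only).
#' Failure is encoded in the returned object, never raised.
#'
#' @param smiles A single SMILES string (possibly malformed).
#' @return A `molecule` object with fields `smiles_input`,
#'   `smiles_canonical` (`NA` when invalid) and `is_valid`.
#' @examples
#' canonicalize("C1=CC=CC=C1")$smiles_canonical  # "c1ccccc1"
#' canonicalize("C1CC")$is_valid                 # FALSE
#' @export
canonicalize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) {
    return(new_molecule(if (length(smiles) == 1) as.character(smiles)
                        else NA_character_))
  }
  hit <- cache_get("canon", smiles)
  if (!is.null(hit)) return(hit)
  rep <- inspect_validity(smiles)
  if (!rep$valid) return(cache_set("canon", smiles, new_molecule(smiles)))
  can <- ob_canonical_one(smiles)
  if (is.na(can)) return(cache_set("canon", smiles, new_molecule(smiles)))
  if (grepl("[@/\\\\]", can)) {
    stripped <- gsub("@|/|\\\\", "", can)
    can2 <- ob_canonical_one(stripped)
    if (!is.na(can2)) can <- can2
  }
  # canonical form must itself survive the inspector (it defines our dialect)
  rep2 <- inspect_validity(can)
  if (!rep2$valid) return(cache_set("canon", smiles, new_molecule(smiles)))
  cache_set("canon", smiles, new_molecule(smiles, can, TRUE))
}

#' @export
print.molecule <- function(x, ...) {
  if (x$is_valid) {
    cat("<molecule>", x$smiles_canonical, "\n")
  } else {
    cat("<molecule> INVALID input:", x$smiles_input, "\n")
  }
  invisible(x)
}

as_molecule <- function(x) {
  if (inherits(x, "molecule")) return(x)
  if (is.character(x) && length(x) == 1) return(canonicalize(x))
  stopf("expected a molecule or a single SMILES string")
}

# parsed graph of a valid molecule's canonical SMILES, memoised
molecule_graph <- function(mol) {
  mol <- as_molecule(mol)
  if (!mol$is_valid) stopf("invalid molecule: %s", mol$smiles_input)
  key <- mol$smiles_canonical
  hit <- cache_get("graph", key)
  if (!is.null(hit)) return(hit)
  cache_set("graph", key, mol_graph(key))
}

# ---- validity inspection ---------------------------------------------------

# Atoms that must carry one double bond in a Kekule assignment, and the
# pi-electron contribution of each aromatic atom for the per-ring electron
# count.  Covers the C/N/O/S/P aromatic chemistry this package generates.
aromatic_roles <- function(atoms) {
  needs <- rep(FALSE, nrow(atoms))
  electrons <- rep(NA_real_, nrow(atoms))
  for (a in which(atoms$aromatic)) {
    elem <- atoms$elem[a]; ch <- atoms$charge[a]
    conn <- atoms$degree[a] + atoms$n_h[a]
    if (elem == "C") {
      if (ch == -1) { needs[a] <- FALSE; electrons[a] <- 2 }
      else { needs[a] <- TRUE; electrons[a] <- 1 }
    } else if (elem %in% c("N", "P")) {
      if (ch == 1) { needs[a] <- conn == 3; electrons[a] <- if (conn == 3) 1 else 2 }
      else { needs[a] <- conn == 2; electrons[a] <- if (conn == 2) 1 else 2 }
    } else if (elem %in% c("O", "S")) {
      needs[a] <- FALSE; electrons[a] <- 2
    } else {
      needs[a] <- TRUE; electrons[a] <- 1
    }
  }
  list(needs = needs, electrons = electrons)
}

# Perfect matching over the aromatic-bond subgraph restricted to atoms that
# require a double bond; backtracking search (aromatic systems are small).
kekule_matching_exists <- function(need_idx, arom_bonds) {
  if (length(need_idx) == 0) return(TRUE)
  if (length(need_idx) %% 2 == 1) return(FALSE)
  nbrs <- lapply(need_idx, function(a) {
    hit <- unique(c(arom_bonds$to[arom_bonds$from == a],
                    arom_bonds$from[arom_bonds$to == a]))
    intersect(hit, need_idx)
  })
  names(nbrs) <- as.character(need_idx)
  match_rec <- function(unmatched) {
    if (length(unmatched) == 0) return(TRUE)
    a <- unmatched[1]
    cands <- intersect(nbrs[[as.character(a)]], unmatched)
    for (b in cands) {
      if (match_rec(setdiff(unmatched, c(a, b)))) return(TRUE)
    }
    FALSE
  }
  match_rec(need_idx)
}

check_kekulizable <- function(parsed) {
  atoms <- parsed$atoms
  if (!any(atoms$aromatic)) return(TRUE)
  roles <- aromatic_roles(atoms)
  arom_bonds <- parsed$bonds[parsed$bonds$aromatic, , drop = FALSE]
  # every aromatic atom must sit on at least one aromatic bond
  on_arom <- unique(c(arom_bonds$from, arom_bonds$to))
  if (!all(which(atoms$aromatic) %in% on_arom)) return(FALSE)
  if (!kekule_matching_exists(which(roles$needs), arom_bonds)) return(FALSE)
  # ring-bond flags for SSSR perception
  mg <- parsed
  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  if (nrow(parsed$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(parsed$bonds$from, parsed$bonds$to))
  }
  br <- if (nrow(parsed$bonds) > 0) as.integer(igraph::bridges(g)) else integer(0)
  mg$bonds$in_ring <- !(seq_len(nrow(parsed$bonds)) %in% br)
  mg$graph <- g
  # aromatic atoms must lie in rings at all
  in_ring <- rep(FALSE, nrow(atoms))
  if (any(mg$bonds$in_ring)) {
    rb <- mg$bonds[mg$bonds$in_ring, , drop = FALSE]
    in_ring[unique(c(rb$from, rb$to))] <- TRUE
  }
  if (any(atoms$aromatic & !in_ring)) return(FALSE)
  # per-ring electron count (4n + 2) on fully aromatic SSSR rings; counts
  # each ring in isolation, a deliberate approximation documented in the
  # methods vignette (rejects antiaromatic input such as c1ccc1)
  for (path in sssr_rings(mg)) {
    if (all(atoms$aromatic[path])) {
      ne <- sum(roles$electrons[path])
      if (!is.na(ne) && (ne %% 4) != 2) return(FALSE)
    }
  }
  TRUE
}

# Simple valence sanity: bond-order sum may not exceed the maximum default
# valence (adjusted by positive charge).  The toolkit is permissive here.
check_valence <- function(parsed) {
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  bsum <- numeric(nrow(atoms))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$from[k]] <- bsum[bonds$from[k]] + bonds$order[k]
      bsum[bonds$to[k]] <- bsum[bonds$to[k]] + bonds$order[k]
    }
  }
  for (a in seq_len(nrow(atoms))) {
    if (atoms$aromatic[a]) next  # aromatic consistency handled by kekulization
    vals <- DEFAULT_VALENCE[[atoms$elem[a]]]
    if (is.null(vals)) next
    vmax <- max(vals) + max(0L, atoms$charge[a])
    hexp <- atoms$h_explicit[a]
    tot <- bsum[a] + ifelse(is.na(hexp), 0, hexp)
    if (tot > vmax + 1e-9) return(FALSE)
  }
  TRUE
}

#' Inspect the grammatical validity of a SMILES string
#'
#' Classifies a candidate string the way the design loop's inspection step
#' does: balanced parentheses, paired ring-closure labels, parseability, a
#' valence sanity check, and kekulization feasibility of the aromatic
#' subgraph (perfect double-bond matching plus a per-ring electron count).
#' All failures are reported, never raised.
#'
#' @param smiles A single string.
#' @return A list with `valid` (logical) and `reason` (`NA` when valid, else
#'   one of `"parse"`, `"parentheses"`, `"ring_closure"`, `"kekulization"`).
#' @examples
#' inspect_validity("c1ccccc1")$valid      # TRUE
#' inspect_validity("c1ccccc1(")$reason    # "parentheses"
#' inspect_validity("c1ccc1")$reason       # "kekulization"
#' @export
inspect_validity <- function(smiles) {
  fail <- function(reason) list(valid = FALSE, reason = reason)
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) {
    return(fail("parse"))
  }
  hit <- cache_get("validity", smiles)
  if (!is.null(hit)) return(hit)
  cache_set("validity", smiles, inspect_validity_impl(smiles))
}

inspect_validity_impl <- function(smiles) {
  fail <- function(reason) list(valid = FALSE, reason = reason)
  # cheap surface checks first, so the reason is specific
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  depth <- 0
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (depth < 0) return(fail("parentheses"))
  }
  if (depth != 0) return(fail("parentheses"))
  parsed <- parse_smiles(smiles)
  if (!parsed$ok) return(fail(parsed$reason))
  parsed <- assign_hydrogens(parsed)
  if (!check_valence(parsed)) return(fail("parse"))
  if (!check_kekulizable(parsed)) return(fail("kekulization"))
  # final word from the toolkit
  can <- ob_canonical_one(smiles)
  if (is.na(can)) return(fail("parse"))
  list(valid = TRUE, reason = NA_character_)
}

# ---- fingerprints ----------------------------------------------------------

#' Encode a molecule as a binary extended-connectivity fingerprint
#'
#' Morgan-style circular fingerprint: each atom's environment out to
#' `diameter / 2` bonds is iteratively hashed (initial invariants: atomic
#' number, heavy degree, hydrogen count, formal charge, ring membership,
#' aromaticity), duplicate environments covering the same atom set are
#' dropped, and identifiers are folded into `nbits` positions.  Defaults
#' follow the design loop: diameter 6, 5000 bits, binary presence.
#'
#' @param mol A valid [molecule] (or SMILES string).
#' @param diameter Neighbourhood diameter in bonds (radius = diameter / 2).
#' @param nbits Folded fingerprint length.
#' @return Numeric vector of length `nbits` with values in \{0, 1\}.
#' @examples
#' fp <- encode_ecfp(canonicalize("Cc1ccccc1"))
#' sum(fp)  # number of distinct hashed environments
#' @export
encode_ecfp <- function(mol, diameter = 6, nbits = 5000) {
  mol <- as_molecule(mol)
  if (!mol$is_valid) stopf("encode_ecfp: invalid molecule")
  key <- sprintf("%s|%d|%d", mol$smiles_canonical, diameter, nbits)
  hit <- cache_get("fp", key)
  if (!is.null(hit)) return(hit)
  mg <- molecule_graph(mol)
  atoms <- mg$atoms
  bonds <- mg$bonds
  n <- nrow(atoms)
  radius <- as.integer(diameter / 2)

  nbr <- lapply(seq_len(n), function(a) {
    k <- which(bonds$from == a | bonds$to == a)
    other <- ifelse(bonds$from[k] == a, bonds$to[k], bonds$from[k])
    ord <- ifelse(bonds$aromatic[k], 4L, as.integer(bonds$order[k]))
    list(atoms = other, orders = ord)
  })

  ids <- vapply(seq_len(n), function(a) {
    hash_ints(c(ATOMIC_NUMBER[[atoms$elem[a]]], atoms$degree[a],
                atoms$n_h[a], atoms$charge[a], as.integer(atoms$in_ring[a]),
                as.integer(atoms$aromatic[a])))
  }, 1)

  env_atoms <- lapply(seq_len(n), function(a) a)
  seen_envs <- new.env(parent = emptyenv())
  out_ids <- numeric(0)
  register <- function(id, env) {
    envkey <- paste(sort(env), collapse = ",")
    if (is.null(seen_envs[[envkey]])) {
      seen_envs[[envkey]] <- TRUE
      out_ids[length(out_ids) + 1] <<- id
    }
  }
  for (a in seq_len(n)) register(ids[a], env_atoms[[a]])

  if (radius >= 1) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      new_envs <- env_atoms
      for (a in seq_len(n)) {
        na <- nbr[[a]]$atoms
        if (length(na) == 0) next
        pairs <- cbind(nbr[[a]]$orders, ids[na])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        new_ids[a] <- hash_ints(c(r, ids[a], as.numeric(t(pairs))))
        new_envs[[a]] <- sort(unique(c(env_atoms[[a]],
                                       unlist(env_atoms[na]))))
      }
      for (a in seq_len(n)) {
        if (length(nbr[[a]]$atoms) > 0) register(new_ids[a], new_envs[[a]])
      }
      ids <- new_ids
      env_atoms <- new_envs
    }
  }

  fp <- numeric(nbits)
  fp[(out_ids %% nbits) + 1] <- 1
  cache_set("fp", key, fp)
}

fp_binarize <- function(fp) as.numeric(fp >= 0.5)

#' Tanimoto similarity between two fingerprints
#'
#' Real-valued inputs (e.g. post-mutation vectors) are binarized at 0.5
#' before the set comparison.  Two empty bit sets are defined as similarity 1.
#'
#' @param a,b Numeric fingerprint vectors of equal length, values in [0, 1].
#' @return Similarity in [0, 1]: |A and B| / |A or B| over set bits.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stopf("tanimoto: length mismatch")
  ab <- fp_binarize(a); bb <- fp_binarize(b)
  inter <- sum(ab * bb)
  uni <- sum(pmax(ab, bb))
  if (uni == 0) return(1)
  inter / uni
}

# ---- readers / writers -----------------------------------------------------

#' Read molecules from a SMILES list file
#'
#' One SMILES per line, optionally followed by a tab-separated name.
#'
#' @param path File path.
#' @return Data frame with columns `smiles` and `name`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(smiles = vapply(parts, `[`, "", 1),
             name = vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""),
             stringsAsFactors = FALSE)
}

#' Write molecules to a SMILES list file
#' @param smiles Character vector of SMILES.
#' @param path File path.
#' @param names Optional names written tab-separated.
#' @return Invisibly, `path`.
#' @export
write_smiles <- function(smiles, path, names = NULL) {
  lines <- if (is.null(names)) smiles else paste(smiles, names, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a molecule table from CSV
#'
#' Requires a `smiles` column; all other columns are kept (typically named
#' property columns such as `s1`, `homo`, `lumo`).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_molecules_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!("smiles" %in% names(df))) stopf("CSV must have a 'smiles' column")
  df
}

#' Read molecules from an SDF file (convenience)
#' @param path SDF file path.
#' @return Character vector of SMILES strings.
#' @export
read_sdf_smiles <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- ob_convert("SDF", "SMI", txt)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
}
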