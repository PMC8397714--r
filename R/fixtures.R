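# Seeded fragment-based generator of valid drug-like molecules, emulating a
# random public-database sample (molecular weights 200-600 g/mol) at desk
# scale.  Molecules are assembled from curated ring systems, linkers and
# substituents, so validity is guaranteed by construction and the property
# marginals (logP, TPSA, drug-likeness) span the ranges a diverse public
# library covers -- from polyol/sulfonamide-polar to polyaromatic-greasy.

# Ring-system templates: first atom is the attachment point towards the
# parent fragment; "(R1)"/"(R2)" are optional substitution slots.  Ring
# closure digits are renumbered per instance during assembly.
FIXTURE_RINGS <- c(
  benzene      = "c1cc(R2)cc(R1)c1",
  toluene_like = "c1c(C)c(R1)cc(R2)c1",
  pyridine     = "c1cc(R1)cnc1",
  pyridine2    = "c1ncc(R1)cc1",
  pyrimidine   = "c1ncc(R1)cn1",
  pyrazine     = "c1nc(R1)cnc1",
  thiophene    = "c1cc(R1)sc1",
  furan        = "c1cc(R1)oc1",
  pyrrole_nme  = "c1cc(R1)n(C)c1",
  imidazole    = "c1nc(R1)cn1C",
  oxazole      = "c1nc(R1)co1",
  thiazole     = "c1nc(R1)cs1",
  naphthalene  = "c1ccc2cc(R1)ccc2c1",
  quinoline    = "c1ccc2ncc(R1)cc2c1",
  indole_nme   = "c1ccc2c(c1)cc(R1)n2C",
  benzothiophene = "c1ccc2c(c1)cc(R1)s2",
  benzofuran   = "c1ccc2c(c1)cc(R1)o2",
  anthracene   = "c1ccc2cc3cc(R1)ccc3cc2c1",
  pyrene       = "c1cc2ccc3cccc4ccc(c1)c2c34",
  dichlorobenzene = "c1c(Cl)cc(R1)cc1Cl",
  chloronaphthalene = "c1cc(Cl)c2cc(R1)c(Cl)cc2c1",
  cyclohexane  = "C1CC(R1)CCC1",
  cyclopentane = "C1CC(R1)CC1",
  piperidine   = "N1CCC(R1)CC1",
  piperazine   = "N1CCN(R1)CC1",
  morpholine   = "N1CCOCC1",
  oxane        = "C1CC(R1)OCC1",
  pyranose     = "C1OC(CO)C(O)C(O)C1O"
)

# Linkers: first atom bonds to the previous ring system, last atom to the
# next one.
FIXTURE_LINKERS <- c(
  "", "C", "CC", "O", "OC", "OCC", "OCCO", "S",
  "NC", "N(C)C", "NC(=O)", "C(=O)N", "C(=O)", "OC(=O)",
  "S(=O)(=O)", "S(=O)(=O)N", "C=C", "C#C", "CNC(=O)", "COC",
  "CCC", "C(C)C", "C(F)(F)"
)

# Terminal substituents filling unused R slots.
FIXTURE_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "C(C)C", "C(C)(C)C", "CCCCCC",
  "O", "OC", "OCC", "CO", "C(O)CO",
  "N", "NC", "N(C)C", "NC(=O)C", "C(=O)N",
  "F", "Cl", "Br", "C(F)(F)F", "OC(F)(F)F",
  "C#N", "[N+](=O)[O-]", "C(=O)O", "C(=O)OC", "C(=O)C",
  "S(=O)(=O)N", "S(=O)(=O)C", "SC"
)

#' Fixture-generator configuration
#'
#' @param n_molecules Library size.
#' @param rng_seed Seed making the library a pure function of this config.
#' @param fragment_set,linker_set,substituent_set SMILES fragment pools
#'   (defaults ship with the package).
#' @param max_heavy_atoms Upper size bound for assembled molecules.
#' @param mw_range Accepted molecular-weight window in g/mol (the emulated
#'   corpus sampled 200-600).
#' @param property_range Output range of the surrogate oracle, in eV.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_molecules = 500, rng_seed = 1L,
                           fragment_set = FIXTURE_RINGS,
                           linker_set = FIXTURE_LINKERS,
                           substituent_set = FIXTURE_SUBSTITUENTS,
                           max_heavy_atoms = 40,
                           mw_range = c(200, 600),
                           property_range = c(1.5, 7.0)) {
  stopifnot(n_molecules > 0)
  structure(list(n_molecules = n_molecules, rng_seed = rng_seed,
                 fragment_set = fragment_set, linker_set = linker_set,
                 substituent_set = substituent_set,
                 max_heavy_atoms = max_heavy_atoms, mw_range = mw_range,
                 property_range = property_range),
            class = "fixture_config")
}

# renumber ring-closure digits so nested fragments never collide
renumber_rings <- function(frag, counter) {
  chars <- strsplit(frag, "", fixed = TRUE)[[1]]
  labels <- unique(chars[grepl("[0-9]", chars)])
  out <- frag
  for (lb in labels) {
    counter <- counter + 1L
    new <- if (counter <= 9) as.character(counter) else sprintf("%%%02d", counter)
    out <- gsub(lb, new, out, fixed = TRUE)
  }
  list(smiles = out, counter = counter)
}

# one random assembly: ring systems joined by linkers, slots decorated
assemble_molecule <- function(cfg) {
  n_rings <- sample(1:4, 1, prob = c(0.2, 0.35, 0.28, 0.17))
  counter <- 0L
  build <- function(depth) {
    frag <- sample(cfg$fragment_set, 1)
    r <- renumber_rings(frag, counter)
    counter <<- r$counter
    s <- r$smiles
    if (depth < n_rings) {
      linker <- sample(cfg$linker_set, 1)
      child <- build(depth + 1)
      sub <- paste0("(", linker, child, ")")
      if (grepl("(R1)", s, fixed = TRUE)) {
        s <- sub("(R1)", sub, s, fixed = TRUE)
      } else if (grepl("(R2)", s, fixed = TRUE)) {
        s <- sub("(R2)", sub, s, fixed = TRUE)
      } else {
        s <- paste0(s, sub)
      }
    }
    s
  }
  s <- build(1)
  n_sub <- sample(0:3, 1, prob = c(0.3, 0.35, 0.22, 0.13))
  for (k in seq_len(n_sub)) {
    if (!grepl("(R", s, fixed = TRUE)) break
    slot <- if (grepl("(R1)", s, fixed = TRUE)) "(R1)" else "(R2)"
    s <- sub(slot, paste0("(", sample(cfg$substituent_set, 1), ")"),
             s, fixed = TRUE)
  }
  gsub("\\(R[12]\\)", "", s)
}

#' Generate the fixture molecule library
#'
#' Assembles `n_molecules` unique, valid, canonical molecules by seeded
#' random combination of the fragment set; a pure function of the
#' configuration.
#'
#' @param cfg A [fixture_config()].
#' @return List of [molecule] objects.
#' @export
generate_library <- function(cfg = fixture_config()) {
  out <- list()
  seen <- character(0)
  max_attempts <- 80L * cfg$n_molecules
  with_seed(cfg$rng_seed, {
    attempts <- 0L
    while (length(out) < cfg$n_molecules && attempts < max_attempts) {
      attempts <- attempts + 1L
      s <- assemble_molecule(cfg)
      mol <- canonicalize(s)
      if (!mol$is_valid) next
      if (mol$smiles_canonical %in% seen) next
      mg <- tryCatch(molecule_graph(mol), error = function(e) NULL)
      if (is.null(mg) || nrow(mg$atoms) > cfg$max_heavy_atoms) next
      mw <- molecular_weight(mol)
      if (mw < cfg$mw_range[1] || mw > cfg$mw_range[2]) next
      seen <- c(seen, mol$smiles_canonical)
      out[[length(out) + 1]] <- mol
    }
  })
  if (length(out) < cfg$n_molecules) {
    stopf("generate_library: only %d unique molecules reached (wanted %d)",
          length(out), cfg$n_molecules)
  }
  out
}

#' Label a molecule library with a property oracle
#'
#' @param lib List of [molecule] objects.
#' @param oracle Either a function of a fingerprint (e.g. [surrogate_s1()])
#'   or a function of a molecule returning a named list.
#' @param property Name under which a scalar oracle value is stored.
#' @return List of `list(molecule, properties)` pairs; molecules the oracle
#'   fails on are skipped (with a warning summarizing the count).
#' @export
label_library <- function(lib, oracle = surrogate_s1, property = "s1") {
  out <- list()
  failed <- 0L
  for (mol in lib) {
    val <- tryCatch({
      v <- oracle(encode_ecfp(mol))
      setNames(list(as.numeric(v)), property)
    }, error = function(e) NULL)
    if (is.null(val)) { failed <- failed + 1L; next }
    out[[length(out) + 1]] <- list(mol, val)
  }
  if (failed > 0) warning(sprintf("label_library: oracle failed on %d molecules",
                                  failed))
  out
}

#' Build (fingerprint, molecule) or (fingerprint, label) pairs
#'
#' Convenience constructor for the pair lists consumed by the decoders and
#' the predictor: each element is `list(encode_ecfp(mol), mol)` or, when
#' `labels` is given, `list(encode_ecfp(mol), labels[[i]])`.
#'
#' @param lib List of [molecule] objects.
#' @param labels Optional list of per-molecule labels.
#' @return List of pairs.
#' @export
library_pairs <- function(lib, labels = NULL) {
  lapply(seq_along(lib), function(i) {
    if (is.null(labels)) {
      list(encode_ecfp(lib[[i]]), lib[[i]])
    } else {
      list(encode_ecfp(lib[[i]]), labels[[i]])
    }
  })
}
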