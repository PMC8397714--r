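# Analytic descriptor oracles: toolkit descriptors (logP, TPSA, MW, H-bond
# counts) plus in-package drug-likeness composites (QED and the CNS
# multi-parameter-optimization score).  All calls are deterministic and
# memoised per canonical SMILES.

ob_props <- function(mol) {
  mol <- as_molecule(mol)
  if (!mol$is_valid) stopf("descriptors: invalid molecule")
  key <- mol$smiles_canonical
  hit <- cache_get("props", key)
  if (!is.null(hit)) return(hit)
  obm <- ChemmineOB::forEachMol("SMILES", key, identity)
  p <- ChemmineOB::prop_OB(obm)
  cache_set("props", key, p)
}

ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                 Br = 79.904, I = 126.904)

# molecular weight from the parsed graph (implicit hydrogens included)
molecular_weight <- function(mol) {
  mg <- molecule_graph(as_molecule(mol))
  sum(ATOMIC_MASS[mg$atoms$elem]) + sum(mg$atoms$n_h) * ATOMIC_MASS[["H"]]
}

# Rotatable bonds: single, acyclic bonds between two non-terminal heavy
# atoms, excluding bonds adjacent to a triple bond.
rotatable_bonds <- function(mg) {
  bonds <- mg$bonds
  if (nrow(bonds) == 0) return(0L)
  triple_atoms <- unique(c(bonds$from[bonds$order == 3],
                           bonds$to[bonds$order == 3]))
  cand <- bonds$order == 1 & !bonds$aromatic & !bonds$in_ring &
    mg$atoms$degree[bonds$from] > 1 & mg$atoms$degree[bonds$to] > 1 &
    !(bonds$from %in% triple_atoms) & !(bonds$to %in% triple_atoms)
  sum(cand)
}

smarts_count <- function(mol, smarts) {
  mol <- as_molecule(mol)
  key <- paste0(mol$smiles_canonical, "|", smarts)
  hit <- cache_get("smarts", key)
  if (!is.null(hit)) return(hit)
  obm <- ChemmineOB::forEachMol("SMILES", mol$smiles_canonical, identity)
  n <- tryCatch(ChemmineOB::smartsSearch_OB(obm, smarts, uniqueMatches = TRUE),
                error = function(e) 0L)
  cache_set("smarts", key, as.integer(n))
}

# all alert patterns against one parsed molecule (single toolkit parse)
smarts_count_many <- function(mol, patterns) {
  mol <- as_molecule(mol)
  key <- paste0(mol$smiles_canonical, "|#alerts")
  hit <- cache_get("smarts", key)
  if (!is.null(hit)) return(hit)
  obm <- ChemmineOB::forEachMol("SMILES", mol$smiles_canonical, identity)
  counts <- vapply(patterns, function(p) {
    as.integer(tryCatch(
      ChemmineOB::smartsSearch_OB(obm, p, uniqueMatches = TRUE),
      error = function(e) 0L))
  }, 1L)
  cache_set("smarts", key, counts)
}

# Curated structural-alert patterns for the drug-likeness ALERTS term
# (common reactive/unstable motifs; a compact subset of the published alert
# collections -- at the drug-like optimum the count is zero either way).
STRUCTURAL_ALERTS <- c(
  nitro = "[N+](=O)[O-]",
  aldehyde = "[CX3H1](=O)[#6]",
  acyl_halide = "C(=O)[F,Cl,Br,I]",
  peroxide = "[OX2][OX2]",
  azo = "N=N",
  thiol = "[SX2H]",
  isocyanate = "N=C=O",
  hydrazine = "[NX3][NX3]",
  michael_acceptor = "C=CC(=O)",
  alkyl_halide = "[CX4][Cl,Br,I]",
  epoxide = "C1OC1",
  aziridine = "C1NC1",
  imine = "[CX3]=[NX2][#6]",
  phosphorus = "[P]",
  long_chain = "CCCCCCCC"
)

count_alerts <- function(mol) {
  sum(smarts_count_many(mol, STRUCTURAL_ALERTS) > 0)
}

# Asymmetric double-sigmoid desirability (published parameterization of the
# quantitative estimate of drug-likeness; one row per descriptor:
# a, b, c, d, e, f, dmax).
QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.01, 272.4121427, 2.55837997, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.21778897, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.337261),
  ALERTS = c(0.01, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.725314)
)

QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]; dmax <- p[7]
  v <- a + b / (1 + exp(-(x - cc + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - cc - d / 2) / f)))
  v / dmax
}

qed_score <- function(desc) {
  xs <- c(MW = desc$mw, ALOGP = desc$logp, HBA = desc$hba, HBD = desc$hbd,
          PSA = desc$tpsa, ROTB = desc$rotb, AROM = desc$arom,
          ALERTS = desc$alerts)
  d <- vapply(names(xs), function(nm) qed_ads(xs[[nm]], QED_ADS[[nm]]), 1)
  d <- pmax(d, 1e-9)
  w <- QED_WEIGHTS[names(xs)]
  exp(sum(w * log(d)) / sum(w))
}

# piecewise-linear monotone-decreasing desirability: 1 below lo, 0 above hi
t0_desc <- function(x, lo, hi) clip01((hi - x) / (hi - lo))

# hump desirability used for polar surface area in the CNS score
t0_hump <- function(x, lo0, lo1, hi1, hi0) {
  if (x <= lo0 || x >= hi0) return(0)
  if (x < lo1) return((x - lo0) / (lo1 - lo0))
  if (x <= hi1) return(1)
  (hi0 - x) / (hi0 - hi1)
}

# Basic aliphatic amine (proxy for the ionizable centre driving pKa and the
# logD offset); excludes amides and aryl amines.
BASIC_AMINE_SMARTS <- "[NX3;!$(NC=O);!$(N=*);!$(Nc)]"

cns_mpo_components <- function(mol, desc) {
  basic <- smarts_count(mol, BASIC_AMINE_SMARTS) > 0
  # configurable constant-per-class proxies for pKa and logD (documented)
  pka <- if (basic) 9.5 else 5.0
  logd <- if (basic) desc$logp - 1.0 else desc$logp
  c(clogp = t0_desc(desc$logp, 3, 5),
    clogd = t0_desc(logd, 2, 4),
    mw = t0_desc(desc$mw, 360, 500),
    tpsa = t0_hump(desc$tpsa, 20, 40, 90, 120),
    hbd = t0_desc(desc$hbd, 0.5, 3.5),
    pka = t0_desc(pka, 8, 10))
}

#' Descriptor-based properties of a molecule
#'
#' Computes the analytic property vector used by the goal-directed
#' benchmarks: octanol/water partition coefficient (`logp`), topological
#' polar surface area (`tpsa`, A^2), molecular weight (`mw`, g/mol),
#' hydrogen-bond donors/acceptors, rotatable bonds, aromatic ring count,
#' structural-alert count, the quantitative estimate of drug-likeness
#' (`qed`, in (0,1)) and the CNS multi-parameter-optimization score
#' (`cns_mpo`, mean of six desirability components, in [0,1]).
#'
#' @param mol A valid [molecule] (or SMILES string).
#' @return Named list of descriptor values.
#' @examples
#' descriptor_properties("c1ccccc1")$tpsa  # 0
#' @export
descriptor_properties <- function(mol) {
  mol <- as_molecule(mol)
  if (!mol$is_valid) stopf("descriptor_properties: invalid molecule")
  key <- mol$smiles_canonical
  hit <- cache_get("desc", key)
  if (!is.null(hit)) return(hit)
  p <- ob_props(mol)
  mg <- molecule_graph(mol)
  desc <- list(
    logp = as.numeric(p$logP),
    tpsa = as.numeric(p$TPSA),
    mw = as.numeric(p$MW),
    hba = as.numeric(p$HBA1),
    hbd = as.numeric(p$HBD),
    rotb = rotatable_bonds(mg),
    arom = aromatic_ring_count(mg),
    alerts = count_alerts(mol)
  )
  desc$qed <- qed_score(desc)
  desc$cns_mpo <- mean(cns_mpo_components(mol, desc))
  cache_set("desc", key, desc)
}
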