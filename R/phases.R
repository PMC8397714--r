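# Iterative extrapolation beyond the training-property range: each phase
# generates molecules by evolutionary design driven by the current property
# predictor, labels the novel finds with the (surrogate) oracle, retrains
# the models on the accumulated dataset, and reseeds from the lowest-value
# molecules -- the generate -> label -> retrain -> reseed cycle.

#' Phase-loop configuration
#'
#' Defaults follow the published procedure: 30 seed molecules, 300
#' evolution runs per phase, 3 phases, target threshold 1.77 eV, minimized.
#' Desk-scale studies shrink `n_seeds`/`n_repeats` (see the package
#' vignette).
#'
#' @param n_seeds Seed molecules per phase (the extreme molecules of the
#'   accumulated dataset).
#' @param n_repeats Evolution runs per phase, cycling over the seeds.
#' @param n_phases Number of phases.
#' @param threshold_ev Property threshold defining the extrapolation target.
#' @param direction `"minimize"` or `"maximize"`.
#' @param property Name of the labeled property.
#' @return A `phase_config`.
#' @export
phase_config <- function(n_seeds = 30, n_repeats = 300, n_phases = 3,
                         threshold_ev = 1.77,
                         direction = c("minimize", "maximize"),
                         property = "s1") {
  direction <- match.arg(direction)
  stopifnot(n_seeds > 0, n_repeats >= 0, n_phases > 0,
            is.finite(threshold_ev))
  structure(list(n_seeds = n_seeds, n_repeats = n_repeats,
                 n_phases = n_phases, threshold_ev = threshold_ev,
                 direction = direction, property = property),
            class = "phase_config")
}

#' Select seed molecules from a labeled dataset
#'
#' The `n` molecules with the most extreme values in the stated direction;
#' ties broken by canonical-SMILES order.
#'
#' @param labeled List of `list(molecule, value)` pairs (value numeric or a
#'   named list containing the property).
#' @param n Number of seeds.
#' @param direction `"minimize"` (smallest values first) or `"maximize"`.
#' @return List of [molecule] objects.
#' @export
select_phase_seeds <- function(labeled, n, direction = "minimize") {
  if (length(labeled) == 0) stopf("select_phase_seeds: empty dataset")
  if (n > length(labeled)) stopf("select_phase_seeds: n exceeds dataset size")
  vals <- vapply(labeled, function(p) {
    v <- p[[2]]
    as.numeric(if (is.list(v)) v[[1]] else v)
  }, 1)
  sm <- vapply(labeled, function(p) as_molecule(p[[1]])$smiles_canonical, "")
  ord <- if (direction == "minimize") order(vals, sm) else order(-vals, sm)
  lapply(labeled[ord[seq_len(n)]], function(p) as_molecule(p[[1]]))
}

#' Extract the label values / SMILES of a labeled pair list
#' @param labeled List of `list(molecule, value-or-list)` pairs.
#' @return Numeric vector of first label values, or character vector of
#'   canonical SMILES.
#' @export
labeled_values <- function(labeled) {
  vapply(labeled, function(p) {
    v <- p[[2]]; as.numeric(if (is.list(v)) v[[1]] else v)
  }, 1)
}

#' @rdname labeled_values
#' @export
labeled_smiles <- function(labeled) {
  vapply(labeled, function(p) as_molecule(p[[1]])$smiles_canonical, "")
}

#' Run one phase of evolutionary generation
#'
#' Runs `n_repeats` evolution campaigns cycling over the seeds, pools every
#' distinct valid filter-passing molecule, removes molecules already in the
#' accumulated dataset, labels the novel finds with the oracle, and
#' summarizes the phase.
#'
#' @param seeds List of seed molecules.
#' @param decoder Decoder used by the campaigns.
#' @param predictor `predictor_model` supplying fitness.
#' @param oracle Labeling function of a fingerprint (e.g. [surrogate_s1()]).
#' @param known Character vector of canonical SMILES already in the dataset.
#' @param ga_cfg A [ga_config()].
#' @param phase_cfg A [phase_config()].
#' @param seed Integer seed for this phase.
#' @return List with `new_labeled` (list of pairs) and `report` (one-row
#'   data frame: generated, below_threshold, mean, variance).
#' @export
run_phase <- function(seeds, decoder, predictor, oracle, known,
                      ga_cfg = ga_config(), phase_cfg = phase_config(),
                      seed = 1L) {
  objective <- if (phase_cfg$direction == "minimize") {
    "minimize_property"
  } else "maximize_property"
  fit <- fitness_spec(objective, property_name = phase_cfg$property)
  found <- new.env(parent = emptyenv())
  if (phase_cfg$n_repeats > 0) {
    for (r in seq_len(phase_cfg$n_repeats)) {
      sd_mol <- seeds[[((r - 1) %% length(seeds)) + 1]]
      cfg_r <- ga_cfg
      cfg_r$rng_seed <- derive_seed(seed, paste0("phase_run", r))
      res <- evolve(sd_mol, decoder, evaluator = predictor, fitness = fit,
                    cfg = cfg_r)
      for (s in res$candidates$smiles) found[[s]] <- TRUE
    }
  }
  novel <- setdiff(ls(found), known)
  new_labeled <- lapply(novel, function(s) {
    mol <- canonicalize(s)
    setNames(list(mol, setNames(list(oracle(encode_ecfp(mol))),
                                phase_cfg$property)), NULL)
  })
  vals <- labeled_values(new_labeled)
  below <- if (phase_cfg$direction == "minimize") {
    sum(vals < phase_cfg$threshold_ev)
  } else {
    sum(vals > phase_cfg$threshold_ev)
  }
  report <- data.frame(
    generated = length(new_labeled),
    below_threshold = below,
    mean = if (length(vals) > 0) mean(vals) else NA_real_,
    variance = if (length(vals) > 1) var(vals) else NA_real_)
  list(new_labeled = new_labeled, report = report)
}

#' Iterate the generate-label-retrain-reseed phase loop
#'
#' After each phase the predictor is retrained from scratch on the union of
#' the accumulated labeled data (and a sequence decoder, when supplied, is
#' retrained likewise; the nearest-neighbour decoder explores a fixed
#' chemical-space library and is rebuilt as-is), and the seeds are
#' reselected from the accumulated dataset.
#'
#' @param initial_labeled List of `list(molecule, properties)` pairs.
#' @param decoder Decoder (typically an [nn_decoder()] over the explorable
#'   space at desk scale, or a `decoder_model`).
#' @param oracle Labeling oracle on fingerprints.
#' @param ga_cfg,phase_cfg,train_cfg Configurations.
#' @param seed Integer seed for the whole loop.
#' @return List with `report` (one row per phase), `dataset` (accumulated
#'   labeled pairs) and `per_phase` raw results.
#' @export
iterate_phases <- function(initial_labeled, decoder, oracle = surrogate_s1,
                           ga_cfg = ga_config(), phase_cfg = phase_config(),
                           train_cfg = train_config(), seed = 1L) {
  dataset <- initial_labeled
  reports <- list()
  per_phase <- list()
  for (ph in seq_len(phase_cfg$n_phases)) {
    pairs <- lapply(dataset, function(p) {
      list(encode_ecfp(as_molecule(p[[1]])), p[[2]])
    })
    tc <- train_cfg
    tc$seed <- derive_seed(seed, paste0("train", ph))
    predictor <- train_predictor(pairs, tc)
    if (inherits(decoder, "decoder_model")) {
      dtc <- tc
      dtc$seed <- derive_seed(seed, paste0("dectrain", ph))
      dec_pairs <- lapply(dataset, function(p) {
        list(encode_ecfp(as_molecule(p[[1]])), as_molecule(p[[1]]))
      })
      decoder <- train_decoder(dec_pairs, dtc)
    }
    seeds <- select_phase_seeds(dataset, min(phase_cfg$n_seeds,
                                             length(dataset)),
                                phase_cfg$direction)
    known <- labeled_smiles(dataset)
    out <- run_phase(seeds, decoder, predictor, oracle, known,
                     ga_cfg, phase_cfg, seed = derive_seed(seed,
                                                           paste0("ph", ph)))
    dataset <- c(dataset, out$new_labeled)
    reports[[ph]] <- cbind(phase = ph, out$report)
    per_phase[[ph]] <- out
  }
  list(report = do.call(rbind, reports), dataset = dataset,
       per_phase = per_phase)
}
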