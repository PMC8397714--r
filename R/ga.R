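# The evolutionary loop: a population of real-valued fingerprint vectors is
# initialized by mutating the seed molecule's fingerprint, decoded to
# molecules each generation, filtered (validity, structural blacklist,
# property windows, database dedup) and scored; the top three vectors are
# carried unchanged as parents while tournament selection, uniform
# crossover and Gaussian mutation produce the rest of the next population.

#' Genetic-algorithm configuration
#'
#' Defaults are the published operator settings: population 50, crossover
#' rate 0.7, mutation rate 0.3, uniform crossover with mixing ratio 0.2,
#' Gaussian mutation N(0, 0.2^2) applied element-wise with probability 0.01,
#' tournament size 3, top-3 parent retention, at most 500 generations,
#' stopping after 30 generations without improvement.
#'
#' @param pop_size Population size.
#' @param cx_prob Crossover probability per offspring pair.
#' @param mut_prob Mutation probability per offspring.
#' @param tournament_size Tournament size for parent selection.
#' @param mix_ratio Per-position swap probability of the uniform crossover.
#' @param mut_sigma Gaussian mutation standard deviation.
#' @param mut_indpb Per-element mutation probability.
#' @param max_generations Generation cap.
#' @param patience Stagnation window (generations without improvement).
#' @param n_parents_kept Elites carried unchanged each generation.
#' @param init_indpb Elevated per-element mutation probability used to
#'   diversify the initial population.
#' @param n_decode Decode attempts per individual (first valid sample wins).
#' @param reencode_genotype When `TRUE`, a successfully decoded individual's
#'   genotype is replaced by the decoded molecule's fresh fingerprint, so
#'   crossover and mutation act on realized structures.  Recommended with
#'   the stochastic nearest-neighbour decoder, whose genotype-phenotype
#'   coupling is otherwise weak; the default keeps the evolved vector.
#' @param rng_seed Seed for the whole run.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 50, cx_prob = 0.7, mut_prob = 0.3,
                      tournament_size = 3, mix_ratio = 0.2, mut_sigma = 0.2,
                      mut_indpb = 0.01, max_generations = 500, patience = 30,
                      n_parents_kept = 3, init_indpb = 0.05, n_decode = 10,
                      reencode_genotype = FALSE, rng_seed = NULL) {
  stopifnot(pop_size > 0, cx_prob >= 0, cx_prob <= 1, mut_prob >= 0,
            mut_prob <= 1, mix_ratio >= 0, mix_ratio <= 1,
            mut_indpb >= 0, mut_indpb <= 1, tournament_size >= 1)
  structure(list(pop_size = pop_size, cx_prob = cx_prob, mut_prob = mut_prob,
                 tournament_size = tournament_size, mix_ratio = mix_ratio,
                 mut_sigma = mut_sigma, mut_indpb = mut_indpb,
                 max_generations = max_generations, patience = patience,
                 n_parents_kept = n_parents_kept, init_indpb = init_indpb,
                 n_decode = n_decode, reencode_genotype = reencode_genotype,
                 rng_seed = rng_seed),
            class = "ga_config")
}

#' Fitness specification for an evolution run
#'
#' @param objective `"maximize_property"`, `"minimize_property"` (fitness is
#'   the signed relative property change versus the seed) or
#'   `"benchmark_score"` (fitness is `scorer(mol)` in [0, 1], maximized).
#' @param property_name Property targeted by directional objectives.
#' @param scorer Function `molecule -> [0, 1]` for benchmark objectives.
#' @param windows List of [property_window()] constraints.
#' @param reference_library Character set of canonical SMILES; decoded
#'   molecules already present there are rejected as database duplicates.
#' @return A `fitness_spec` list.
#' @export
fitness_spec <- function(objective = c("maximize_property",
                                       "minimize_property",
                                       "benchmark_score"),
                         property_name = NULL, scorer = NULL,
                         windows = list(), reference_library = character(0)) {
  objective <- match.arg(objective)
  if (objective == "benchmark_score" && is.null(scorer)) {
    stopf("fitness_spec: benchmark_score needs a scorer")
  }
  if (objective != "benchmark_score" && is.null(property_name)) {
    stopf("fitness_spec: directional objective needs property_name")
  }
  structure(list(objective = objective, property_name = property_name,
                 scorer = scorer, windows = windows,
                 reference_library = reference_library),
            class = "fitness_spec")
}

#' Gaussian mutation of a fingerprint vector
#'
#' Each element is independently perturbed with probability `indpb` by
#' N(0, sigma^2) noise; the result is clipped to [0, 1].  The input is not
#' modified.
#'
#' @param fp Numeric fingerprint vector.
#' @param sigma Noise standard deviation.
#' @param indpb Per-element mutation probability.
#' @return Mutated fingerprint.
#' @export
mutate_gaussian <- function(fp, sigma = 0.2, indpb = 0.01) {
  stopifnot(sigma >= 0, indpb >= 0, indpb <= 1)
  if (indpb == 0 || sigma == 0) return(fp)
  hit <- runif(length(fp)) < indpb
  fp[hit] <- fp[hit] + rnorm(sum(hit), 0, sigma)
  clip01(fp)
}

#' Uniform crossover of two fingerprint vectors
#'
#' Each position is swapped between the two children with probability
#' `mix_ratio`; jointly the children conserve the parents' values per
#' position.
#'
#' @param a,b Parent vectors of equal length.
#' @param mix_ratio Per-position swap probability.
#' @return List of two children.
#' @export
crossover_uniform <- function(a, b, mix_ratio = 0.2) {
  if (length(a) != length(b)) stopf("crossover_uniform: length mismatch")
  swap <- runif(length(a)) < mix_ratio
  c1 <- a; c2 <- b
  c1[swap] <- b[swap]
  c2[swap] <- a[swap]
  list(c1, c2)
}

#' Tournament selection
#'
#' Draws `k` winners; each is the maximum-fitness member of an independent
#' uniform sample of `tournsize` individuals (ties broken uniformly at
#' random).
#'
#' @param pop List of individuals carrying `$fitness`.
#' @param k Number of winners.
#' @param tournsize Tournament size.
#' @return List of `k` selected individuals.
#' @export
select_tournament <- function(pop, k, tournsize = 3) {
  if (length(pop) == 0) stopf("select_tournament: empty population")
  fits <- vapply(pop, function(ind) ind$fitness %||% -Inf, 1)
  lapply(seq_len(k), function(i) {
    cand <- sample.int(length(pop), min(tournsize, length(pop)),
                       replace = TRUE)
    best <- cand[fits[cand] == max(fits[cand])]
    pop[[if (length(best) == 1) best else sample(best, 1)]]
  })
}

new_individual <- function(fp, generation = 0L, parent_ids = integer(0)) {
  list(fp = fp, smiles = NA_character_, fitness = NULL,
       filter_reason = NA_character_, generation = generation,
       parent_ids = parent_ids)
}

#' Initialize a population from a seed fingerprint
#'
#' The seed vector itself is included once; the remaining individuals are
#' Gaussian mutations of it with the elevated initial per-element rate.
#'
#' @param seed_fp Binary fingerprint of the seed molecule.
#' @param cfg A [ga_config()].
#' @return List of `pop_size` individuals.
#' @export
init_population <- function(seed_fp, cfg = ga_config()) {
  pop <- vector("list", cfg$pop_size)
  pop[[1]] <- new_individual(seed_fp)
  for (i in seq_len(cfg$pop_size - 1)) {
    pop[[i + 1]] <- new_individual(
      mutate_gaussian(seed_fp, cfg$mut_sigma, cfg$init_indpb))
  }
  pop
}

# property evaluation on the decoded molecule's re-encoded fingerprint
eval_properties <- function(evaluator, mol) {
  if (inherits(evaluator, "predictor_model")) {
    as.list(predict(evaluator, encode_ecfp(mol)))
  } else if (is.function(evaluator)) {
    as.list(evaluator(mol, encode_ecfp(mol)))
  } else {
    stopf("evaluator must be a predictor_model or a function")
  }
}

#' Decode and score a population
#'
#' Each unevaluated individual is decoded (first valid sample of
#' `cfg$n_decode` attempts); individuals that fail validity, the structural
#' blacklist, a property window, or that duplicate the reference library
#' receive worst fitness.  Fitness is computed on the decoded molecule's
#' freshly re-encoded fingerprint, not on the evolved vector.
#'
#' @param pop List of individuals.
#' @param decoder A `decoder_model` or [nn_decoder()].
#' @param evaluator A `predictor_model` or a function
#'   `(molecule, fingerprint) -> named numeric`.
#' @param seed_mol The seed [molecule].
#' @param fitness A [fitness_spec()].
#' @param cfg A [ga_config()].
#' @param blacklist A [blacklist_config()].
#' @param decode_seed Seed stream for decoder sampling.
#' @return The population with `smiles`, `fitness` and `filter_reason` set.
#' @export
evaluate_population <- function(pop, decoder, evaluator, seed_mol, fitness,
                                cfg = ga_config(),
                                blacklist = blacklist_config(),
                                decode_seed = NULL) {
  t0 <- NULL
  if (fitness$objective != "benchmark_score") {
    props0 <- eval_properties(evaluator, seed_mol)
    t0 <- as.numeric(props0[[fitness$property_name]])
  }
  score_mol <- function(mol) {
    if (fitness$objective == "benchmark_score") {
      return(as.numeric(fitness$scorer(mol)))
    }
    props <- eval_properties(evaluator, mol)
    if (length(fitness$windows) > 0 &&
        !check_property_window(props, fitness$windows)) {
      return(NA_real_)  # window violation
    }
    t <- as.numeric(props[[fitness$property_name]])
    rel <- (t - t0) / max(abs(t0), 1e-12)
    if (fitness$objective == "minimize_property") -rel else rel
  }
  # batch the similarity computation for the nearest-neighbour decoder: one
  # matrix product per generation instead of one per individual
  sims <- NULL
  if (inherits(decoder, "nn_decoder")) {
    unev <- which(vapply(pop, function(x) is.null(x$fitness), TRUE))
    if (length(unev) > 0) {
      Q <- do.call(rbind, lapply(pop[unev], function(x) fp_binarize(x$fp)))
      inter <- Q %*% decoder$Mt
      uni <- outer(rowSums(Q), decoder$row_bits, "+") - inter
      S <- ifelse(uni == 0, 1, inter / uni)
      sims <- setNames(lapply(seq_along(unev), function(j) S[j, ]),
                       as.character(unev))
    }
  }
  for (i in seq_along(pop)) {
    ind <- pop[[i]]
    if (!is.null(ind$fitness)) next
    mol <- NULL
    ss <- if (!is.null(sims)) {
      nn_sample(decoder, sims[[as.character(i)]], cfg$n_decode,
                seed = derive_seed(decode_seed, i))
    } else {
      decode(decoder, ind$fp, n_samples = cfg$n_decode,
             seed = derive_seed(decode_seed, i))
    }
    for (s in unique(ss)) {
      if (inspect_validity(s)$valid) {
        cand <- canonicalize(s)
        if (cand$is_valid) { mol <- cand; break }
      }
    }
    if (is.null(mol)) {
      ind$fitness <- -Inf; ind$filter_reason <- "invalid"
      pop[[i]] <- ind; next
    }
    ind$smiles <- mol$smiles_canonical
    if (cfg$reencode_genotype) ind$fp <- encode_ecfp(mol)
    verdict <- check_structural(mol, seed_mol, blacklist)
    if (!verdict$pass) {
      ind$fitness <- -Inf
      ind$filter_reason <- paste(verdict$reasons, collapse = "+")
      pop[[i]] <- ind; next
    }
    if (length(fitness$reference_library) > 0 &&
        mol$smiles_canonical %in% fitness$reference_library) {
      ind$fitness <- -Inf; ind$filter_reason <- "duplicate"
      pop[[i]] <- ind; next
    }
    f <- score_mol(mol)
    if (is.na(f)) {
      ind$fitness <- -Inf; ind$filter_reason <- "window"
    } else {
      ind$fitness <- f; ind$filter_reason <- NA_character_
    }
    pop[[i]] <- ind
  }
  pop
}

#' Run one evolutionary design campaign
#'
#' @inheritParams evaluate_population
#' @param seed Seed molecule (SMILES or [molecule]).
#' @return An `evolution_result`: `best_per_generation` (data frame of
#'   generation, SMILES, fitness), `best_overall` individual,
#'   `termination_reason` (`"max_generations"` or `"stagnation"`),
#'   `generations` run, `candidates` (data frame of every distinct valid,
#'   filter-passing molecule encountered, with fitness), and per-generation
#'   `filter_stats`.
#' @export
evolve <- function(seed, decoder, evaluator, fitness, cfg = ga_config(),
                   blacklist = blacklist_config()) {
  seed_mol <- as_molecule(seed)
  if (!seed_mol$is_valid) stopf("evolve: invalid seed molecule")
  seed_fp <- encode_ecfp(seed_mol)

  with_seed(cfg$rng_seed, {
    pop <- init_population(seed_fp, cfg)
    pop <- evaluate_population(pop, decoder, evaluator, seed_mol, fitness,
                               cfg, blacklist,
                               decode_seed = derive_seed(cfg$rng_seed, "g0"))
    candidates <- new.env(parent = emptyenv())
    note_candidates <- function(pop, gen) {
      for (ind in pop) {
        if (is.finite(ind$fitness %||% -Inf) && !is.na(ind$smiles)) {
          old <- candidates[[ind$smiles]]
          if (is.null(old) || old$fitness < ind$fitness) {
            candidates[[ind$smiles]] <- list(fitness = ind$fitness, gen = gen)
          }
        }
      }
    }
    note_candidates(pop, 0L)

    fits <- vapply(pop, function(x) x$fitness, 1)
    best_idx <- which.max(fits)
    best_overall <- pop[[best_idx]]
    best_fit <- fits[best_idx]
    history <- list(list(generation = 0L, smiles = best_overall$smiles,
                         fitness = best_fit))
    filter_stats <- list()
    stagnant <- 0L
    gen <- 0L
    reason <- "max_generations"

    while (gen < cfg$max_generations) {
      gen <- gen + 1L
      elite_ord <- order(-fits)
      elites <- pop[elite_ord[seq_len(min(cfg$n_parents_kept, length(pop)))]]
      n_off <- cfg$pop_size - length(elites)
      parents <- select_tournament(pop, n_off, cfg$tournament_size)
      offspring <- lapply(parents, function(p) p$fp)
      # varAnd convention: crossover then mutation, each probabilistic
      if (n_off >= 2) {
        for (j in seq(1, n_off - 1, by = 2)) {
          if (runif(1) < cfg$cx_prob) {
            ch <- crossover_uniform(offspring[[j]], offspring[[j + 1]],
                                    cfg$mix_ratio)
            offspring[[j]] <- ch[[1]]; offspring[[j + 1]] <- ch[[2]]
          }
        }
      }
      offspring <- lapply(offspring, function(fp) {
        if (runif(1) < cfg$mut_prob) {
          mutate_gaussian(fp, cfg$mut_sigma, cfg$mut_indpb)
        } else fp
      })
      pop <- c(elites, lapply(offspring, function(fp) {
        new_individual(fp, generation = gen)
      }))
      pop <- evaluate_population(pop, decoder, evaluator, seed_mol, fitness,
                                 cfg, blacklist,
                                 decode_seed = derive_seed(cfg$rng_seed,
                                                           paste0("g", gen)))
      note_candidates(pop, gen)
      fits <- vapply(pop, function(x) x$fitness, 1)
      reasons <- vapply(pop, function(x) x$filter_reason, "")
      filter_stats[[gen]] <- table(reasons[!is.na(reasons)])
      gen_best <- which.max(fits)
      if (fits[gen_best] > best_fit) {
        best_fit <- fits[gen_best]
        best_overall <- pop[[gen_best]]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      history[[length(history) + 1]] <-
        list(generation = gen, smiles = pop[[gen_best]]$smiles,
             fitness = best_fit)
      if (stagnant >= cfg$patience) { reason <- "stagnation"; break }
    }

    cand_df <- if (length(ls(candidates)) > 0) {
      sm <- ls(candidates)
      data.frame(smiles = sm,
                 fitness = vapply(sm, function(s) candidates[[s]]$fitness, 1),
                 generation = vapply(sm, function(s) candidates[[s]]$gen, 1L),
                 row.names = NULL, stringsAsFactors = FALSE)
    } else {
      data.frame(smiles = character(0), fitness = numeric(0),
                 generation = integer(0))
    }
    structure(list(
      best_per_generation = do.call(rbind, lapply(history, function(h) {
        data.frame(generation = h$generation, smiles = h$smiles,
                   fitness = h$fitness, stringsAsFactors = FALSE)
      })),
      best_overall = best_overall,
      termination_reason = reason,
      generations = gen,
      candidates = cand_df[order(-cand_df$fitness), ],
      final_population = data.frame(
        smiles = vapply(pop, function(x) x$smiles, ""),
        fitness = vapply(pop, function(x) x$fitness %||% -Inf, 1),
        stringsAsFactors = FALSE),
      filter_stats = filter_stats,
      seed_smiles = seed_mol$smiles_canonical
    ), class = "evolution_result")
  })
}

#' @export
print.evolution_result <- function(x, ...) {
  cat("<evolution_result>", x$generations, "generations,",
      x$termination_reason, "\n")
  cat("  seed:", x$seed_smiles, "\n")
  cat("  best:", x$best_overall$smiles, "fitness",
      format(x$best_overall$fitness, digits = 4), "\n")
  cat("  distinct candidates:", nrow(x$candidates), "\n")
  invisible(x)
}
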