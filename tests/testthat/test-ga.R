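test_that("Gaussian mutation perturbs the configured fraction and clips", {
  fp <- as.numeric(runif(5000) < 0.01)
  expect_identical(mutate_gaussian(fp, sigma = 0, indpb = 1), fp)
  expect_identical(mutate_gaussian(fp, sigma = 0.2, indpb = 0), fp)
  set.seed(21)
  out <- mutate_gaussian(rep(0.5, 5000), sigma = 0.2, indpb = 1)
  expect_true(all(out >= 0 & out <= 1))
  expect_gt(mean(out != 0.5), 0.99)
  # mean perturbation centred at zero (two-sided test)
  expect_gt(t.test(out - 0.5)$p.value, 0.001)
  # changed fraction near indpb for an interior starting point
  set.seed(22)
  frac <- mean(mutate_gaussian(rep(0.5, 5000), 0.2, 0.05) != 0.5)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 5000))
})

test_that("uniform crossover swaps positions at the mixing ratio", {
  a <- rep(1, 5000); b <- rep(0, 5000)
  set.seed(31)
  ch <- crossover_uniform(a, b, 0.2)
  # joint conservation per position
  expect_true(all(ch[[1]] + ch[[2]] == 1))
  swapped <- mean(ch[[1]] == 0)
  expect_lt(abs(swapped - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  same <- crossover_uniform(a, a, 0.5)
  expect_identical(same[[1]], a)
  none <- crossover_uniform(a, b, 0)
  expect_identical(none[[1]], a); expect_identical(none[[2]], b)
  full <- crossover_uniform(a, b, 1)
  expect_identical(full[[1]], b); expect_identical(full[[2]], a)
  expect_error(crossover_uniform(a, numeric(10)), "length")
})

test_that("tournament selection favours fitness and is fair under ties", {
  mk <- function(f) list(fp = numeric(1), fitness = f, smiles = NA)
  pop <- lapply(c(0.1, 0.5, 0.9), mk)
  set.seed(41)
  # a strictly dominant individual wins every tournament containing it
  picks <- select_tournament(pop, 200, tournsize = 3)
  expect_true(all(vapply(picks, function(p) p$fitness, 1) >= 0.1))
  one <- select_tournament(pop[1], 10, tournsize = 3)
  expect_true(all(vapply(one, function(p) p$fitness, 1) == 0.1))
  expect_error(select_tournament(list(), 1), "empty")
})

test_that("population initialization includes the seed and obeys size", {
  fp <- encode_ecfp(small_lib()[[1]])
  cfg <- ga_config(pop_size = 12, rng_seed = 1)
  set.seed(2)
  pop <- init_population(fp, cfg)
  expect_length(pop, 12)
  expect_identical(pop[[1]]$fp, fp)
  cfg0 <- ga_config(pop_size = 6, init_indpb = 0)
  set.seed(3)
  pop0 <- init_population(fp, cfg0)
  expect_true(all(vapply(pop0, function(i) identical(i$fp, fp), TRUE)))
})

test_that("evaluation scores via the decoded molecule's re-encoded fingerprint", {
  lib <- small_lib()
  # deterministic decoding (single-neighbour) so the seed individual is
  # guaranteed to decode to the seed molecule itself
  dec <- nn_decoder(small_pairs(), k_neighbors = 1)
  seed_mol <- lib[[1]]
  ev <- function(mol, fp) c(s1 = surrogate_s1(fp))
  fit <- fitness_spec("maximize_property", property_name = "s1")
  cfg <- ga_config(pop_size = 6, rng_seed = 5, reencode_genotype = TRUE)
  set.seed(5)
  pop <- init_population(encode_ecfp(seed_mol), cfg)
  pop <- evaluate_population(pop, dec, ev, seed_mol, fit, cfg,
                             decode_seed = 99)
  t0 <- surrogate_s1(encode_ecfp(seed_mol))
  for (ind in pop) {
    if (is.finite(ind$fitness) && !is.na(ind$smiles)) {
      want <- (surrogate_s1(encode_ecfp(canonicalize(ind$smiles))) - t0) / abs(t0)
      expect_equal(ind$fitness, want)
    }
  }
  # the seed itself has zero relative change
  expect_equal(pop[[1]]$fitness, 0)
})

test_that("filtered individuals carry worst fitness", {
  lib <- small_lib()
  dec <- small_nn()
  ev <- function(mol, fp) c(s1 = surrogate_s1(fp))
  # an impossible window rejects everything
  fit <- fitness_spec("maximize_property", property_name = "s1",
                      windows = list(property_window("s1", 100, 200)))
  cfg <- ga_config(pop_size = 5, rng_seed = 1)
  set.seed(1)
  pop <- evaluate_population(init_population(encode_ecfp(lib[[1]]), cfg),
                             dec, ev, lib[[1]], fit, cfg, decode_seed = 1)
  expect_true(all(vapply(pop, function(i) i$fitness, 1) == -Inf))
  # duplicates of the reference library are rejected too
  fit2 <- fitness_spec("maximize_property", property_name = "s1",
                       reference_library = vapply(lib, function(m)
                         m$smiles_canonical, ""))
  set.seed(1)
  pop2 <- evaluate_population(init_population(encode_ecfp(lib[[1]]), cfg),
                              dec, ev, lib[[1]], fit2, cfg, decode_seed = 1)
  expect_true(all(vapply(pop2, function(i) i$fitness, 1) == -Inf))
  expect_true(any(vapply(pop2, function(i) identical(i$filter_reason,
                                                     "duplicate"), TRUE)))
})

test_that("evolution contracts: monotone best, constant size, determinism", {
  lib <- small_lib()
  dec <- small_nn()
  ev <- function(mol, fp) c(s1 = surrogate_s1(fp))
  fit <- fitness_spec("maximize_property", property_name = "s1")
  cfg <- ga_config(pop_size = 16, max_generations = 12, patience = 6,
                   reencode_genotype = TRUE, rng_seed = 77)
  res <- evolve(lib[[2]], dec, ev, fit, cfg)
  expect_false(is.unsorted(res$best_per_generation$fitness))
  expect_equal(nrow(res$final_population), 16)
  expect_true(res$termination_reason %in% c("max_generations", "stagnation"))
  res2 <- evolve(lib[[2]], dec, ev, fit, cfg)
  expect_identical(res$best_per_generation, res2$best_per_generation)
  expect_error(evolve("C1CC", dec, ev, fit, cfg), "invalid")
})

test_that("a constant oracle stagnates after exactly the patience window", {
  lib <- small_lib()
  dec <- small_nn()
  cst <- function(mol, fp) c(s1 = 1)
  fit <- fitness_spec("maximize_property", property_name = "s1")
  cfg <- ga_config(pop_size = 8, max_generations = 100, patience = 9,
                   rng_seed = 13)
  res <- evolve(lib[[1]], dec, cst, fit, cfg)
  expect_equal(res$termination_reason, "stagnation")
  expect_equal(res$generations, 9)
})

test_that("every reported candidate passes validity, blacklist and windows", {
  lib <- small_lib()
  dec <- small_nn()
  ev <- function(mol, fp) c(s1 = surrogate_s1(fp))
  fit <- fitness_spec("maximize_property", property_name = "s1",
                      windows = list(property_window("s1", 1.5, 7)))
  cfg <- ga_config(pop_size = 16, max_generations = 10, patience = 5,
                   reencode_genotype = TRUE, rng_seed = 3)
  res <- evolve(lib[[3]], dec, ev, fit, cfg)
  for (s in res$candidates$smiles) {
    expect_true(inspect_validity(s)$valid)
    expect_true(check_structural(canonicalize(s), lib[[3]])$pass)
    expect_true(check_property_window(
      list(s1 = surrogate_s1(encode_ecfp(canonicalize(s)))),
      fit$windows))
  }
})
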