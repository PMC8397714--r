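test_that("phase seeds are the extreme molecules with stable tie-breaking", {
  lib <- small_lib()[1:20]
  vals <- seq_along(lib) / 10
  labeled <- Map(function(m, v) list(m, v), lib, vals)
  seeds <- select_phase_seeds(labeled, 5, "minimize")
  expect_identical(vapply(seeds, function(m) m$smiles_canonical, ""),
                   vapply(lib[1:5], function(m) m$smiles_canonical, ""))
  seeds_max <- select_phase_seeds(labeled, 3, "maximize")
  expect_identical(vapply(seeds_max, function(m) m$smiles_canonical, ""),
                   vapply(lib[20:18], function(m) m$smiles_canonical, ""))
  all_of_them <- select_phase_seeds(labeled, 20)
  expect_length(all_of_them, 20)
  expect_error(select_phase_seeds(labeled, 21), "exceeds")
  # brute-force agreement on random values (with ties)
  set.seed(3)
  vals2 <- sample(c(1, 2, 2, 3), 20, replace = TRUE)
  labeled2 <- Map(function(m, v) list(m, v), lib, vals2)
  got <- vapply(select_phase_seeds(labeled2, 8), function(m)
    m$smiles_canonical, "")
  sm <- vapply(lib, function(m) m$smiles_canonical, "")
  want <- sm[order(vals2, sm)][1:8]
  expect_identical(got, want)
})

test_that("a phase with zero repeats produces nothing, and reports recompute", {
  lib <- small_lib()
  labeled <- label_library(lib[1:30])
  pred <- train_predictor(library_pairs(lib[1:30],
                                        lapply(labeled, `[[`, 2)),
                          train_config(hidden = c(8), epochs = 2, seed = 1))
  out <- run_phase(lib[1:2], small_nn(), pred, surrogate_s1,
                   known = character(0),
                   ga_cfg = ga_config(pop_size = 4, max_generations = 2),
                   phase_cfg = phase_config(n_seeds = 2, n_repeats = 0),
                   seed = 1)
  expect_length(out$new_labeled, 0)
  expect_equal(out$report$generated, 0)
  expect_equal(out$report$below_threshold, 0)
})

test_that("phase outputs are novel and their summary matches recomputation", {
  lib <- small_lib()
  labeled <- label_library(lib)
  vals <- labeled_values(labeled)
  known_idx <- which(vals > 3.5)
  known <- labeled_smiles(labeled[known_idx])
  pred <- train_predictor(library_pairs(lib[known_idx],
                                        lapply(labeled[known_idx], `[[`, 2)),
                          train_config(hidden = c(16), epochs = 15, seed = 2))
  seeds <- select_phase_seeds(labeled[known_idx], 3, "minimize")
  out <- run_phase(seeds, small_nn(), pred, surrogate_s1, known,
                   ga_cfg = ga_config(pop_size = 10, max_generations = 6,
                                      patience = 4,
                                      reencode_genotype = TRUE),
                   phase_cfg = phase_config(n_seeds = 3, n_repeats = 6),
                   seed = 4)
  new_sm <- labeled_smiles(out$new_labeled)
  expect_length(intersect(new_sm, known), 0)
  if (length(out$new_labeled) > 1) {
    vals_new <- labeled_values(out$new_labeled)
    expect_equal(out$report$mean, mean(vals_new))
    expect_equal(out$report$variance, var(vals_new))
    expect_equal(out$report$below_threshold, sum(vals_new < 1.77))
  }
})

test_that("the phase loop accumulates a unique dataset of the right shape", {
  lib <- small_lib()
  labeled <- label_library(lib)
  vals <- labeled_values(labeled)
  init <- labeled[vals > 3.0][1:40]
  res <- iterate_phases(init, small_nn(), surrogate_s1,
                        ga_cfg = ga_config(pop_size = 8, max_generations = 4,
                                           patience = 3,
                                           reencode_genotype = TRUE),
                        phase_cfg = phase_config(n_seeds = 4, n_repeats = 4,
                                                 n_phases = 3),
                        train_cfg = train_config(hidden = c(16), epochs = 10),
                        seed = 6)
  expect_equal(nrow(res$report), 3)
  expect_equal(res$report$phase, 1:3)
  sm <- labeled_smiles(res$dataset)
  expect_equal(anyDuplicated(sm), 0)
  expect_gte(length(res$dataset), length(init))
  # retraining consumes exactly the accumulated labeled set
  expect_equal(length(res$dataset),
               length(init) + sum(res$report$generated))
})

test_that("a constant oracle never crosses the threshold", {
  lib <- small_lib()
  const5 <- function(fp) 5.0
  labeled <- lapply(lib[1:25], function(m) list(m, list(s1 = 5.0)))
  res <- iterate_phases(labeled, small_nn(), const5,
                        ga_cfg = ga_config(pop_size = 6, max_generations = 3,
                                           patience = 2,
                                           reencode_genotype = TRUE),
                        phase_cfg = phase_config(n_seeds = 3, n_repeats = 3,
                                                 n_phases = 2),
                        train_cfg = train_config(hidden = c(8), epochs = 3),
                        seed = 8)
  expect_true(all(res$report$below_threshold == 0))
})
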