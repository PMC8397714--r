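test_that("fused ring systems are perceived by bond sharing", {
  naph <- fused_ring_systems("c1ccc2ccccc2c1")
  expect_length(naph, 1)
  expect_equal(naph[[1]]$ring_sizes, c(6L, 6L))
  expect_equal(naph[[1]]$n_rings, 2L)

  biph <- fused_ring_systems("c1ccc(-c2ccccc2)cc1")
  expect_length(biph, 2)
  expect_true(all(vapply(biph, function(s) s$n_rings, 1L) == 1L))

  # spiro junction shares an atom, not a bond: two systems
  spiro <- fused_ring_systems("C1CCC2(CC1)CCCC2")
  expect_length(spiro, 2)

  expect_length(fused_ring_systems("CCO"), 0)
})

test_that("fused systems and SSSR agree with brute-force graph search", {
  lib <- small_lib()
  set.seed(77)
  ringy <- Filter(function(m) grepl("1", m$smiles_canonical), lib)
  mols <- ringy[sample.int(length(ringy), min(40, length(ringy)))]
  for (m in mols) {
    mg <- mgraph(m$smiles_canonical)
    mine <- lapply(fused_ring_systems(m), function(s) s$ring_sizes)
    oracle <- bf_fused_systems(mg)
    key <- function(l) sort(vapply(l, function(x) paste(x, collapse = ","), ""))
    expect_equal(key(mine), key(oracle), label = m$smiles_canonical)
  }
})

test_that("longest alkyl chain matches exhaustive path search", {
  expect_equal(longest_alkyl_chain("CCCCCC"), 6L)
  expect_equal(longest_alkyl_chain("CCCCCCC"), 7L)
  expect_equal(longest_alkyl_chain("CC(C)C"), 3L)
  expect_equal(longest_alkyl_chain("c1ccccc1"), 0L)
  # ring carbons and heteroatom-adjacent carbons are excluded
  expect_equal(longest_alkyl_chain("C1CCCCC1"), 0L)
  expect_equal(longest_alkyl_chain("OCCO"), 0L)
  set.seed(42)
  mols <- small_lib()[sample.int(length(small_lib()), 40)]
  for (m in mols) {
    expect_equal(longest_alkyl_chain(m),
                 as.integer(bf_longest_alkyl(mgraph(m$smiles_canonical))),
                 label = m$smiles_canonical)
  }
})

test_that("structural blacklist enforces the three rules plus ring delta", {
  cfg <- blacklist_config()
  benz <- canonicalize("c1ccccc1")
  # a molecule always passes against itself
  for (m in small_lib()[1:10]) {
    expect_true(check_structural(m, m, cfg)$pass)
  }
  # fused cyclopropane (3-ring in a fused system)
  v <- check_structural(canonicalize("C1CC2CC2C1"), canonicalize("C1CCCCC1"), cfg)
  expect_false(v$pass)
  expect_true("fused_ring_size" %in% v$reasons)
  # n-heptyl chain
  v <- check_structural(canonicalize("CCCCCCCc1ccccc1"), benz, cfg)
  expect_false(v$pass)
  expect_true("alkyl_chain" %in% v$reasons)
  # hexyl passes
  expect_true(check_structural(canonicalize("CCCCCCc1ccccc1"), benz, cfg)$pass)
  # seven linearly fused rings exceed the six-ring cap
  hepta <- "c1ccc2cc3cc4cc5cc6cc7ccccc7cc6cc5cc4cc3cc2c1"
  v <- check_structural(canonicalize(hepta), canonicalize(hepta), cfg)
  expect_false(v$pass)
  expect_true("max_fused_rings" %in% v$reasons)
  # ring-count drift beyond +/-1 versus the seed
  v <- check_structural(canonicalize("c1ccc2ccccc2c1-c2ccccc2"), benz, cfg)
  expect_false(v$pass)
  expect_true("ring_delta" %in% v$reasons)
  expect_true(check_structural(canonicalize("c1ccc2ccccc2c1"), benz, cfg)$pass)
})

test_that("loosening blacklist limits never turns pass into fail", {
  tight <- blacklist_config()
  loose <- blacklist_config(fused_ring_size_min = 3, fused_ring_size_max = 8,
                            max_fused_rings = 8, max_alkyl_chain = 8,
                            ring_delta_limit = 3)
  seed <- small_lib()[[1]]
  for (m in small_lib()[1:30]) {
    if (check_structural(m, seed, tight)$pass) {
      expect_true(check_structural(m, seed, loose)$pass,
                  label = m$smiles_canonical)
    }
  }
})

test_that("property windows apply strict inequalities", {
  w <- list(property_window("homo", -7, -5), property_window("lumo", upper = 0))
  expect_true(check_property_window(list(homo = -6, lumo = -1), w))
  expect_false(check_property_window(list(homo = -4.5, lumo = -1), w))
  expect_false(check_property_window(list(homo = -7, lumo = -1), w))  # strict
  expect_false(check_property_window(list(homo = -6, lumo = 0), w))
  expect_true(check_property_window(list(homo = -99), list()))
  expect_error(check_property_window(list(lumo = -1), w), "missing")
  expect_error(property_window("x", 2, 2))
})

test_that("deduplication removes exactly the known molecules", {
  lib <- small_lib()
  mols <- lib[1:10]
  ref <- vapply(lib[6:15], function(m) m$smiles_canonical, "")
  kept <- dedup_against(mols, ref)
  expect_equal(
    vapply(kept, function(m) m$smiles_canonical, ""),
    vapply(mols[1:5], function(m) m$smiles_canonical, ""))
  expect_length(dedup_against(mols, character(0)), 10)
  expect_length(dedup_against(mols, vapply(mols, function(m) m$smiles_canonical, "")), 0)
})
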