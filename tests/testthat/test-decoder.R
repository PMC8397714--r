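test_that("tokenization is a stride-1 window with an exact inverse", {
  expect_equal(tokenize_smiles("c1ccccc1"),
               c("c1c", "1cc", "ccc", "ccc", "ccc", "cc1"))
  expect_equal(tokenize_smiles("CC"), "CC~")  # padded short string
  expect_error(tokenize_smiles(""), "empty")
  for (m in small_lib()[1:20]) {
    s <- m$smiles_canonical
    expect_identical(detokenize(tokenize_smiles(s)), s)
  }
})

test_that("training is seeded and its loss trajectory reproducible", {
  mol <- canonicalize("CCOC(=O)c1ccccc1")
  pair <- list(list(encode_ecfp(mol), mol))
  cfg <- train_config(hidden = c(16, 16), epochs = 4, dropout = 0, seed = 9)
  m1 <- train_decoder(pair, cfg)
  m2 <- train_decoder(pair, cfg)
  expect_identical(m1$losses, m2$losses)
  expect_lt(tail(m1$losses, 1), m1$losses[1])
  expect_error(train_decoder(list()), "empty")
})

test_that("an overfit single-pair decoder reconstructs its molecule", {
  mol <- canonicalize("CC(=O)Nc1ccc(O)cc1")
  fp <- encode_ecfp(mol)
  model <- train_decoder(list(list(fp, mol)),
                         train_config(hidden = c(32, 32), epochs = 250,
                                      dropout = 0, lr = 5e-3, seed = 3))
  ss <- decode(model, fp, n_samples = 30, seed = 11)
  expect_gt(mean(ss == mol$smiles_canonical), 0.5)
  expect_equal(reconstructability(model, list(list(fp, mol)),
                                  n_strings = 30, seed = 5), 1.0)
  expect_equal(validity_rate(model, list(fp), n_samples = 20, seed = 6), 1.0)
  # sampling respects n_samples/max_len contracts
  expect_error(decode(model, fp, n_samples = 0), "n_samples")
  short <- decode(model, fp, n_samples = 10, max_len = 5, seed = 2)
  expect_true(all(nchar(short) <= 5))
  expect_identical(decode(model, fp, 5, seed = 4), decode(model, fp, 5, seed = 4))
})

test_that("nearest-neighbour decode matches a brute-force scan", {
  pairs <- small_pairs()
  dec <- nn_decoder(pairs)
  # a library member's own fingerprint returns that member
  for (i in c(1, 7, 20)) {
    got <- nn_decode(dec, pairs[[i]][[1]])
    expect_identical(got$smiles_canonical, pairs[[i]][[2]]$smiles_canonical)
  }
  # agreement with a brute-force maximum (ties by smiles order)
  set.seed(33)
  for (q in 1:50) {
    fp <- as.numeric(runif(5000) < 0.01)
    sims <- vapply(pairs, function(p) bf_tanimoto(p[[1]], fp), 1)
    smiles <- vapply(pairs, function(p) p[[2]]$smiles_canonical, "")
    want <- smiles[order(-sims, smiles)][1]
    expect_identical(nn_decode(dec, fp)$smiles_canonical, want)
  }
  # zero-similarity query: tie broken lexicographically
  fp0 <- numeric(5000)
  fp0[5000] <- 1
  smiles <- sort(vapply(pairs, function(p) p[[2]]$smiles_canonical, ""))
  sims <- vapply(pairs, function(p) bf_tanimoto(p[[1]], fp0), 1)
  if (max(sims) == 0) {
    expect_identical(nn_decode(dec, fp0)$smiles_canonical, smiles[1])
  }
  expect_error(nn_decoder(list()), "empty")
})

test_that("stochastic nn decoding is seeded and stays in the neighbourhood", {
  dec <- small_nn()
  fp <- small_pairs()[[3]][[1]]
  s1 <- decode(dec, fp, n_samples = 25, seed = 10)
  s2 <- decode(dec, fp, n_samples = 25, seed = 10)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% dec$smiles))
  # the decoded set concentrates on the most similar members
  expect_true(nn_decode(dec, fp)$smiles_canonical %in% s1)
})

test_that("decoder metrics are bounded and penalize an untrained model", {
  pairs <- small_pairs()[1:15]
  untrained <- train_decoder(pairs, train_config(hidden = c(8, 8), epochs = 0,
                                                 dropout = 0, seed = 1))
  vr <- validity_rate(untrained, lapply(pairs[1:5], `[[`, 1),
                      n_samples = 5, seed = 2)
  expect_gte(vr, 0); expect_lte(vr, 1)
  rc <- reconstructability(untrained, pairs[1:5], n_strings = 5, seed = 3)
  expect_gte(rc, 0); expect_lte(rc, 1)
  expect_error(validity_rate(untrained, list()), "fingerprints")
  expect_error(reconstructability(untrained, list()), "empty")
})

test_that("model checkpoints round-trip through save/load", {
  mol <- canonicalize("CCO")
  model <- train_decoder(list(list(encode_ecfp(mol), mol)),
                         train_config(hidden = c(8, 8), epochs = 2,
                                      dropout = 0, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$vocab$tokens, model$vocab$tokens)
  expect_identical(decode(back, encode_ecfp(mol), 5, seed = 7),
                   decode(model, encode_ecfp(mol), 5, seed = 7))
})
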