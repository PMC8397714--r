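test_that("canonicalization normalizes spellings and is idempotent", {
  # golden forms pinned to the toolkit shipped with the package
  expect_equal(canonicalize("C1=CC=CC=C1")$smiles_canonical, "c1ccccc1")
  expect_equal(canonicalize("c1ccccc1")$smiles_canonical, "c1ccccc1")
  for (m in small_lib()[1:25]) {
    again <- canonicalize(m$smiles_canonical)
    expect_true(again$is_valid)
    expect_identical(again$smiles_canonical, m$smiles_canonical)
  }
  spellings <- c("Cc1ccccc1", "c1ccccc1C", "C-c1ccccc1")
  canon <- vapply(spellings, function(s) canonicalize(s)$smiles_canonical, "")
  expect_length(unique(canon), 1L)
})

test_that("malformed input is encoded in the molecule, not raised", {
  bad <- canonicalize("C1CC")
  expect_false(bad$is_valid)
  expect_true(is.na(bad$smiles_canonical))
  expect_false(canonicalize("")$is_valid)
  expect_false(canonicalize(NA_character_)$is_valid)
})

test_that("validity inspection classifies failure modes", {
  expect_true(inspect_validity("c1ccccc1")$valid)
  expect_equal(inspect_validity("c1ccccc1(")$reason, "parentheses")
  expect_equal(inspect_validity(")c1ccccc1")$reason, "parentheses")
  expect_equal(inspect_validity("C1CC")$reason, "ring_closure")
  expect_equal(inspect_validity("c1ccc1")$reason, "kekulization")
  expect_equal(inspect_validity("CC(C)(C)(C)C")$reason, "parse")  # 5-valent C
  expect_false(inspect_validity("")$valid)
  # common heteroaromatics must pass
  for (s in c("c1ccncc1", "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "Cn1cccc1",
              "c1ccc2ccccc2c1", "c1cnc[nH]1")) {
    expect_true(inspect_validity(s)$valid, label = s)
  }
  # an odd fully-aromatic fused system cannot be kekulized
  expect_equal(inspect_validity("c1cc2cccc3cccc(c1)c23")$reason,
               "kekulization")
})

test_that("ECFP encoding obeys its contract", {
  fp <- encode_ecfp(canonicalize("Cc1ccccc1"))
  expect_length(fp, 5000)
  expect_true(all(fp %in% c(0, 1)))
  # invariant to the input spelling of the same molecule
  fp2 <- encode_ecfp(canonicalize("c1ccccc1C"))
  expect_identical(fp, fp2)
  # pure function
  expect_identical(fp, encode_ecfp(canonicalize("Cc1ccccc1")))
  # methane has exactly one atom environment (reference-toolkit count)
  expect_equal(sum(encode_ecfp(canonicalize("C"))), 1)
  # invalid molecule is an error
  expect_error(encode_ecfp(canonicalize("C1CC")), "invalid")
  # custom folding length
  expect_length(encode_ecfp(canonicalize("CCO"), nbits = 1024), 1024)
})

test_that("distinct molecules get distinct fingerprints on the fixture set", {
  fps <- lapply(small_lib()[1:30], encode_ecfp)
  keys <- vapply(fps, function(f) paste(which(f == 1), collapse = ","), "")
  expect_equal(length(unique(keys)), 30L)
})

test_that("tanimoto matches brute-force set counting and is symmetric", {
  a <- numeric(50); a[c(1, 2, 3)] <- 1
  b <- numeric(50); b[c(2, 3, 4)] <- 1
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  d <- numeric(50); d[40:45] <- 1
  expect_equal(tanimoto(a, d), 0)
  expect_equal(tanimoto(numeric(10), numeric(10)), 1)
  expect_error(tanimoto(numeric(10), numeric(11)), "length")
  set.seed(101)
  for (i in 1:1000) {
    x <- as.numeric(runif(64) < 0.2)
    y <- as.numeric(runif(64) < 0.2)
    expect_equal(tanimoto(x, y), bf_tanimoto(x, y))
    expect_equal(tanimoto(x, y), tanimoto(y, x))
  }
})

test_that("real-valued fingerprints are binarized at 0.5 for similarity", {
  a <- numeric(20); a[1:4] <- c(0.6, 0.9, 0.51, 0.49)
  b <- numeric(20); b[1:3] <- 1
  expect_equal(tanimoto(a, b), 1)  # 0.49 drops out
})

test_that("SMILES readers and writers round-trip", {
  path <- withr::local_tempfile(fileext = ".smi")
  smiles <- vapply(small_lib()[1:5], function(m) m$smiles_canonical, "")
  write_smiles(smiles, path, names = paste0("m", 1:5))
  back <- read_smiles(path)
  expect_equal(back$smiles, smiles)
  expect_equal(back$name, paste0("m", 1:5))

  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = smiles, s1 = 1:5), csv, row.names = FALSE)
  df <- read_molecules_csv(csv)
  expect_equal(df$smiles, smiles)
  expect_error(read_molecules_csv({
    p <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(x = 1), p, row.names = FALSE); p
  }), "smiles")
})

test_that("in-package fingerprints rank similarity like the toolkit ECFP6", {
  mols <- small_lib()[1:12]
  my_fps <- lapply(mols, encode_ecfp)
  ob_fps <- lapply(mols, function(m) {
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", m$smiles_canonical, identity), "ECFP6")
  })
  mine <- vapply(my_fps, function(a) {
    vapply(my_fps, function(b) tanimoto(a, b), 1)
  }, numeric(12))
  ob <- vapply(ob_fps, function(a) {
    vapply(ob_fps, function(b) bf_tanimoto(a, b), 1)
  }, numeric(12))
  off <- upper.tri(mine)
  expect_gt(cor(mine[off], ob[off], method = "spearman"), 0.7)
})
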