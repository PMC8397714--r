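test_that("the predictor overfits a small set and is deterministic at inference", {
  set.seed(5)
  fps <- lapply(1:20, function(i) as.numeric(runif(5000) < 0.012))
  w <- rnorm(5000)
  pairs <- lapply(fps, function(f) list(f, list(s1 = sum(w * f) / 8)))
  model <- train_predictor(pairs, train_config(hidden = c(32, 32),
                                               epochs = 300, dropout = 0,
                                               seed = 2))
  expect_lt(tail(model$losses, 1), 0.02)
  preds <- vapply(fps, function(f) predict(model, f)[["s1"]], 1)
  labels <- vapply(pairs, function(p) p[[2]]$s1, 1)
  expect_gt(cor(preds, labels), 0.99)
  # repeated inference agrees exactly (dropout off)
  expect_identical(predict(model, fps[[1]]), predict(model, fps[[1]]))
  expect_equal(names(predict(model, fps[[1]])), "s1")
  expect_error(predict(model, numeric(10)), "length")
  expect_error(train_predictor(list()), "empty")
})

test_that("training losses are reproducible under a fixed seed", {
  set.seed(8)
  fps <- lapply(1:15, function(i) as.numeric(runif(200) < 0.1))
  pairs <- lapply(fps, function(f) list(f, list(y = sum(f))))
  cfg <- train_config(hidden = c(8), epochs = 5, dropout = 0.3, seed = 4)
  expect_identical(train_predictor(pairs, cfg)$losses,
                   train_predictor(pairs, cfg)$losses)
})

test_that("inconsistent property names are rejected", {
  p <- list(list(numeric(10), list(a = 1)), list(numeric(10), list(b = 2)))
  expect_error(train_predictor(p), "inconsistent")
})

test_that("cross-validation partitions the data and recovers a learnable map", {
  set.seed(6)
  fps <- lapply(1:150, function(i) as.numeric(runif(60) < 0.15))
  w <- rnorm(60)
  pairs <- lapply(fps, function(f) list(f, list(y = sum(w * f))))
  cv <- crossvalidate(pairs, k = 3,
                      hyper = train_config(hidden = c(32), epochs = 300,
                                           lr = 5e-3, dropout = 0, seed = 1),
                      seed = 2)
  expect_equal(cv$property, "y")
  expect_gt(cv$R, 0.9)
  expect_error(crossvalidate(pairs, k = 151), "larger")
  expect_error(crossvalidate(pairs, k = 1), ">= 2")
})

test_that("fold assignment covers each sample exactly once", {
  n <- 23; k <- 10
  folds <- molevo:::with_seed(9, sample(rep(seq_len(k), length.out = n)))
  expect_length(folds, n)
  expect_setequal(unique(folds), seq_len(k))
})

test_that("surrogate oracle is deterministic, bounded and Lipschitz in bits", {
  fp <- encode_ecfp(small_lib()[[1]])
  expect_identical(surrogate_s1(fp), surrogate_s1(fp))
  expect_equal(surrogate_s1(numeric(5000)), (1.5 + 7) / 2)  # logistic midpoint
  vals <- vapply(small_lib(), function(m) surrogate_s1(encode_ecfp(m)), 1)
  expect_true(all(vals >= 1.5 & vals <= 7.0))
  # flipping 1% of bits moves the output by a bounded amount
  set.seed(12)
  deltas <- replicate(50, {
    f2 <- fp
    flip <- sample.int(5000, 50)
    f2[flip] <- 1 - f2[flip]
    abs(surrogate_s1(f2) - surrogate_s1(fp))
  })
  w <- molevo:::surrogate_weights(5000)
  bound <- 50 * max(abs(w)) / 5
  expect_true(all(deltas <= bound))
})

test_that("descriptor oracle values are sane and pure", {
  d <- descriptor_properties("c1ccccc1")
  expect_equal(d$tpsa, 0)
  expect_gt(d$qed, 0); expect_lt(d$qed, 1)
  expect_gte(d$cns_mpo, 0); expect_lte(d$cns_mpo, 1)
  expect_identical(d, descriptor_properties("c1ccccc1"))
  expect_error(descriptor_properties(canonicalize("C1CC")), "invalid")
  # nitro group triggers a structural alert
  expect_gte(descriptor_properties("O=[N+]([O-])c1ccccc1")$alerts, 1)
  expect_equal(descriptor_properties("CCO")$alerts, 0)
  # rotatable bonds: butylbenzene chain
  expect_equal(descriptor_properties("CCCCc1ccccc1")$rotb, 3)
})
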