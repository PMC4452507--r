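test_that("warm start copies feature rows; dimension mismatch errors", {
  du <- feature_space(c("D1", "D2"), matrix(1:6, 2, byrow = TRUE))
  ds <- feature_space("S1", matrix(c(7, 8, 9), 1))
  m <- init_model(du, ds)
  expect_identical(unname(m$A), unname(du$P))
  expect_identical(unname(m$B), unname(ds$P))
  expect_identical(m$drug_ids, c("D1", "D2"))

  ds8 <- feature_space("S1", matrix(0, 1, 8))
  expect_error(init_model(du, ds8), "k = 3.*k = 8")

  holey <- feature_space("S1", matrix(NA_real_, 1, 3))
  expect_error(init_model(du, holey), "init_missing")
})

test_that("random initialization is bounded, seeded and reproducible", {
  m1 <- init_model_random(sprintf("D%d", 1:4), sprintf("S%d", 1:3), 5,
                          scale = 0.2, seed = 8)
  m2 <- init_model_random(sprintf("D%d", 1:4), sprintf("S%d", 1:3), 5,
                          scale = 0.2, seed = 8)
  expect_identical(m1, m2)
  expect_true(all(abs(m1$A) <= 0.2) && all(abs(m1$B) <= 0.2))
  expect_false(identical(
    m1$A, init_model_random(sprintf("D%d", 1:4), sprintf("S%d", 1:3), 5,
                            scale = 0.2, seed = 9)$A))
})

test_that("prediction is the logistic of the row dot product, strictly in (0,1)", {
  du <- feature_space(c("D1", "D2"), matrix(c(1, 0, 0, 50), 2, byrow = TRUE))
  ds <- feature_space(c("S1", "S2"), matrix(c(0, 1, 0, 50), 2, byrow = TRUE))
  m <- init_model(du, ds)
  expect_identical(predict(m, 1, 1), 0.5)           # orthogonal rows
  # dot product ln(3) -> 0.75
  du2 <- feature_space("D1", matrix(log(3), 1, 1))
  ds2 <- feature_space("S1", matrix(1, 1, 1))
  expect_equal(predict(init_model(du2, ds2), 1, 1), 0.75, tolerance = 1e-12)
  # huge dot product approaches but never reaches 1
  p_big <- predict(m, 2, 2)
  expect_lt(p_big, 1)
  expect_gt(p_big, 1 - 1e-10)
  expect_error(predict(m, 3, 1), "out of range")
})

test_that("sigmoid output is monotone in the dot product", {
  dots <- seq(-40, 40, length.out = 81)
  du <- feature_space(sprintf("D%d", seq_along(dots)), matrix(dots, ncol = 1))
  ds <- feature_space("S1", matrix(1, 1, 1))
  p <- predict(init_model(du, ds), seq_along(dots), rep(1, length(dots)))
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("objective matches direct substitution and the naive oracle", {
  du <- feature_space("D1", matrix(c(1, 0), 1))
  ds <- feature_space("S1", matrix(c(0, 1), 1))
  m0 <- init_model(du, ds, lambda_reg = 0)
  s <- labeled_pairs(1, 1, 1)
  expect_identical(mf_loss(m0, s), 0.5 * (1 - 0.5)^2)  # = 0.125
  expect_identical(mf_loss(m0, s[0, ]), 0)

  rnd <- random_model_and_samples(6, 5, 4, 20, seed = 14)
  expect_equal(mf_loss(rnd$model, rnd$samples),
               naive_loss(rnd$model$A, rnd$model$B, rnd$samples, 2^-7),
               tolerance = 1e-12)
})

test_that("one SGD epoch matches the plain-R reference under the same order", {
  rnd <- random_model_and_samples(6, 5, 4, 25, seed = 21)
  seed <- 77L
  got <- sgd_epoch(rnd$model, rnd$samples, seed = seed)
  ord <- withr::with_seed(seed, sample.int(nrow(rnd$samples)))
  ref <- naive_sgd_epoch(rnd$model$A, rnd$model$B, rnd$samples, ord,
                         eta = 2^-4, lambda = 2^-7)
  expect_equal(unname(got$A), unname(ref$A), tolerance = 1e-13)
  expect_equal(unname(got$B), unname(ref$B), tolerance = 1e-13)
})

test_that("zero-error samples leave rows fixed, or decay them by 1 - eta*lambda", {
  # orthogonal rows with label equal to the prediction: e = 0
  du <- feature_space("D1", matrix(c(1, 0), 1))
  ds <- feature_space("S1", matrix(c(0, 1), 1))
  m <- init_model(du, ds, lambda_reg = 0, eta = 2^-4)
  half <- data.frame(drug = 1L, disease = 1L, label = 0.5)  # y = F exactly
  upd <- sgd_epoch(m, half, seed = 1)
  expect_identical(upd$A, m$A)
  expect_identical(upd$B, m$B)

  lam <- 2^-7
  m2 <- init_model(du, ds, lambda_reg = lam, eta = 2^-4)
  upd2 <- sgd_epoch(m2, half, seed = 1)
  expect_equal(unname(upd2$A), unname(m2$A) * (1 - 2^-4 * lam),
               tolerance = 1e-14)
  expect_equal(unname(upd2$B), unname(m2$B) * (1 - 2^-4 * lam),
               tolerance = 1e-14)
})

test_that("a hand-evaluated single step is reproduced exactly", {
  a <- c(0.4, -0.2)
  b <- c(0.1, 0.3)
  eta <- 0.5
  lam <- 0.01
  y <- 1
  du <- feature_space("D1", matrix(a, 1))
  ds <- feature_space("S1", matrix(b, 1))
  m <- init_model(du, ds, lambda_reg = lam, eta = eta)
  # closed form, simultaneous update from pre-update rows
  f <- 1 / (1 + exp(-sum(a * b)))
  g <- (y - f) * f * (1 - f)
  a_new <- a + eta * (g * b - lam * a)
  b_new <- b + eta * (g * a - lam * b)
  upd <- sgd_epoch(m, labeled_pairs(1, 1, y), seed = 1)
  expect_equal(unname(upd$A)[1, ], a_new, tolerance = 1e-15)
  expect_equal(unname(upd$B)[1, ], b_new, tolerance = 1e-15)
})

test_that("training is deterministic, stops on tol, and is inert on empty data", {
  rnd <- random_model_and_samples(8, 6, 4, 30, seed = 5)
  f1 <- mf_train(rnd$model, rnd$samples, max_epochs = 40, seed = 9)
  f2 <- mf_train(rnd$model, rnd$samples, max_epochs = 40, seed = 9)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$trace, f2$trace)
  expect_length(f1$trace, f1$epochs)

  # huge tolerance: exactly one epoch runs
  f_one <- mf_train(rnd$model, rnd$samples, max_epochs = 50, tol = 1e6,
                    seed = 9)
  expect_identical(f_one$epochs, 1L)
  f_zero <- mf_train(rnd$model, rnd$samples, max_epochs = 7, tol = 0, seed = 9)
  expect_identical(f_zero$epochs, 7L)

  empty <- rnd$samples[0, ]
  f_empty <- mf_train(rnd$model, empty, seed = 1)
  expect_identical(f_empty$model, rnd$model)
  expect_identical(f_empty$trace, numeric(0))
})

test_that("training fits planted low-rank data and reduces the warm-start loss", {
  withr::with_seed(31, {
    A0 <- matrix(stats::rnorm(12 * 3), 12)
    B0 <- matrix(stats::rnorm(8 * 3), 8)
    truth <- (A0 %*% t(B0)) > 0
    grid <- expand.grid(drug = 1:12, disease = 1:8)
  })
  samples <- labeled_pairs(grid$drug, grid$disease, as.numeric(truth))
  m0 <- init_model_random(sprintf("D%d", 1:12), sprintf("S%d", 1:8), 3,
                          lambda_reg = 0, eta = 0.5, seed = 2)
  fit <- mf_train(m0, samples, max_epochs = 300, tol = 0, seed = 4)
  expect_lt(utils::tail(fit$trace, 1), mf_loss(m0, samples))
  auc <- roc_auc(samples$label,
                 predict(fit$model, samples$drug, samples$disease))
  expect_gt(auc, 0.95)
  # loss trace is non-increasing after burn-in
  burn <- fit$trace[-(1:50)]
  expect_true(all(diff(burn) <= 1e-6))
})

test_that("divergent training reports the epoch instead of returning NaN", {
  rnd <- random_model_and_samples(5, 4, 3, 12, seed = 8, lambda = 50,
                                  eta = 10)
  expect_error(mf_train(rnd$model, rnd$samples, max_epochs = 200, tol = 0,
                        seed = 3),
               "diverged.*epoch")
})
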