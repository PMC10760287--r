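test_that("relu clamps negatives elementwise", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(3.5), 3.5)
  expect_equal(relu(c(-1, 2, -0.5)), c(0, 2, 0))
})

test_that("default and custom architectures have the documented shapes", {
  net <- build_mlp(67, seed = 1)
  expect_equal(lapply(net$weights, dim),
               list(c(67L, 50L), c(50L, 30L), c(30L, 20L), c(20L, 1L)))
  small <- build_mlp(5, hidden = c(4, 3), seed = 1)
  expect_equal(lapply(small$weights, dim),
               list(c(5L, 4L), c(4L, 3L), c(3L, 1L)))
  expect_identical(build_mlp(8, seed = 4)$weights,
                   build_mlp(8, seed = 4)$weights)
  expect_error(build_mlp(5, hidden = c(4, 0)), "zero-width")
})

test_that("autoencoder geometry and output range are as designed", {
  ae <- build_autoencoder(57, 67, seed = 1)
  expect_equal(lapply(ae$weights, dim),
               list(c(57L, 67L), c(67L, 67L), c(67L, 67L)))
  X <- with_seed_test(1, matrix(runif(5 * 57, 0, 2), 5, 57))
  out <- network_forward(ae, X)
  expect_true(all(out > 0 & out < 2))
  # zero pre-activation at the output -> exactly 2 * sigmoid(0) = 1
  ae$weights[[3]][] <- 0
  ae$biases[[3]][] <- 0
  expect_equal(unname(network_forward(ae, X)), matrix(1, 5, 67))
  expect_error(build_autoencoder(0, 67), ">= 1")
  expect_error(build_autoencoder(68, 67), "exceeds")
})

test_that("the forward pass matches a per-neuron loop oracle", {
  cases <- list(
    build_mlp(6, hidden = c(4, 3), seed = 2),
    build_mlp(5, hidden = c(7, 3), output_width = 2, seed = 3),
    build_mlp(4, hidden = c(5, 3), skip = TRUE, seed = 4),
    build_autoencoder(3, 6, seed = 5))
  for (net in cases) {
    X <- matrix(rnorm(3 * nrow(net$weights[[1]])), 3)
    expect_equal(network_forward(net, X), forward_oracle(net, X),
                 tolerance = 1e-10)
  }
})

test_that("training drives a constant-label network to that constant", {
  X <- with_seed_test(1, matrix(runif(1000 * 4, 0, 2), 1000, 4))
  y <- rep(1.7, 1000)
  net <- build_mlp(4, hidden = c(8, 4), seed = 1)
  net <- train_regressor(net, X[1:800, ], y[1:800], X[801:1000, ],
                         y[801:1000], fast_cfg(lr = 1e-2, epochs = 10))
  expect_lt(mean((predict(net, X) - 1.7)^2), 1e-3)
})

test_that("an additive PRS is recovered almost perfectly by the network", {
  prs <- random_prs(p = 10, n_int = 0, seed = 21)
  mafs <- with_seed_test(22, runif(10, 0.1, 0.5))
  gm <- simulate_genotypes(
    20000, data.frame(snp_id = prs$snp_ids, effect_allele = "A",
                      maf = mafs), seed = 21)
  y <- evaluate_prs(gm, prs)
  sp <- split_cohort(20000, seed = 21)
  net <- build_mlp(10, seed = 1)
  net <- train_regressor(net, gm$values[sp$train_idx, ], y[sp$train_idx],
                         gm$values[sp$val_idx, ], y[sp$val_idx],
                         train_config(max_epochs = 8))
  expect_gt(spearman_rank(predict(net, gm$values[sp$test_idx, ]),
                          y[sp$test_idx]), 0.99)
})

test_that("training is reproducible and never worse than initialization", {
  X <- with_seed_test(2, matrix(runif(2000 * 5, 0, 2), 2000, 5))
  y <- X %*% c(1, -1, 0.5, 2, 0) + 0.5
  cfg <- fast_cfg(epochs = 2)
  net0 <- build_mlp(5, hidden = c(6, 3), seed = 9)
  a <- train_regressor(net0, X[1:1500, ], y[1:1500], X[1501:2000, ],
                       y[1501:2000], cfg)
  b <- train_regressor(net0, X[1:1500, ], y[1:1500], X[1501:2000, ],
                       y[1501:2000], cfg)
  expect_identical(a$weights, b$weights)
  expect_identical(a$history, b$history)
  init_val <- mean((network_forward(net0, X[1501:2000, ]) -
                    y[1501:2000])^2)
  expect_lte(a$best_val, init_val)
  expect_equal(a$history$val_loss[1], init_val, tolerance = 1e-10)
})

test_that("multi-predictor training reduces every per-output loss", {
  with_seed_test(31, {
    X <- matrix(sample(0:2, 4000 * 8, replace = TRUE), 4000, 8)
    W <- matrix(rnorm(8 * 4), 8, 4)
  })
  Y <- X %*% W
  net <- build_mlp(8, output_width = 4, seed = 2,
                   output_names = paste0("prs", 1:4))
  net <- train_regressor(net, X[1:3000, ], Y[1:3000, ], X[3001:4000, ],
                         Y[3001:4000, ], fast_cfg(lr = 1e-2, epochs = 6))
  hist <- net$history
  for (k in paste0("prs", 1:4))
    expect_lt(hist[[k]][nrow(hist)], 0.2 * hist[[k]][1])
})

test_that("least squares recovers exact linear generating weights", {
  X <- with_seed_test(4, matrix(runif(500 * 6, 0, 2), 500, 6))
  w <- c(0.5, -1, 2, 0, 0.25, 1.5)
  y <- drop(X %*% w) + 3
  fit <- fit_linear(X, y)
  expect_equal(fit$weights, w, tolerance = 1e-8)
  expect_equal(fit$intercept, 3, tolerance = 1e-8)
})

test_that("zero penalties in the elastic-net grid match plain least squares", {
  X <- with_seed_test(5, matrix(runif(400 * 5, 0, 2), 400, 5))
  y <- drop(X %*% c(1, 2, -1, 0.5, 0)) + rnorm(400, sd = 0.1)
  plain <- fit_linear(X[1:300, ], y[1:300])
  grid <- fit_linear(X[1:300, ], y[1:300],
                     elastic_net = list(lambda1 = 0, lambda2 = 0),
                     X_val = X[301:400, ], y_val = y[301:400])
  expect_equal(grid$weights, plain$weights, tolerance = 1e-6)
  expect_equal(grid$lambda1, 0)
})

test_that("elastic-net grid search picks by validation MSE", {
  with_seed_test(6, {
    X <- matrix(runif(300 * 4, 0, 2), 300, 4)
    y <- drop(X %*% c(1, -0.5, 0, 0)) + rnorm(300, sd = 0.05)
  })
  fit <- fit_linear(X[1:200, ], y[1:200], elastic_net = TRUE,
                    X_val = X[201:300, ], y_val = y[201:300])
  base <- fit_linear(X[1:200, ], y[1:200])
  base_val <- mean((X[201:300, ] %*% base$weights + base$intercept -
                    y[201:300])^2)
  expect_lte(fit$val_mse, base_val + 1e-12)
})

test_that("rank deficiency warns and falls back to minimum norm", {
  X <- with_seed_test(7, matrix(runif(100 * 3, 0, 2), 100, 3))
  X <- cbind(X, X[, 3])  # exact collinearity
  y <- drop(X[, 1:3] %*% c(1, 1, 2))
  expect_warning(fit <- fit_linear(X, y), "rank-deficient")
  expect_equal(drop(X %*% fit$weights + fit$intercept), y,
               tolerance = 1e-6)
})

test_that("a pure state-indicator signal defeats the linear model, not the MLP", {
  prs <- prs_definition(
    c("a", "b"), c("A", "C"), c(0, 0),
    data.frame(snp_a = "a", snp_b = "b", mode = "state_indicator",
               state_a = 1L, state_b = 1L, weight = 3))
  gm <- with_seed_test(8, genotype_matrix(
    matrix(sample(0:2, 8000 * 2, replace = TRUE), 8000, 2), c("a", "b")))
  y <- evaluate_prs(gm, prs)
  tr <- 1:6000; va <- 6001:7000; te <- 7001:8000
  lin <- fit_linear(gm$values[tr, ], y[tr])
  lin_mse <- mean((predict(lin, gm$values[te, ]) - y[te])^2)
  net <- build_mlp(2, hidden = c(10, 5), seed = 1)
  net <- train_regressor(net, gm$values[tr, ], y[tr], gm$values[va, ],
                         y[va], fast_cfg(lr = 5e-3, epochs = 10))
  mlp_mse <- mean((predict(net, gm$values[te, ]) - y[te])^2)
  expect_gt(lin_mse, 0.1)
  expect_lt(mlp_mse, 0.5 * lin_mse)
})

test_that("autoencoder reconstructs SNPs when nothing is missing", {
  snps <- data.frame(snp_id = sprintf("s%d", 1:6), effect_allele = "A",
                     maf = with_seed_test(42, runif(6, 0.2, 0.5)))
  gm <- simulate_genotypes(10000, snps, seed = 41)
  sp <- split_cohort(10000, seed = 41)
  ae <- build_autoencoder(6, 6, seed = 1, input_snp_ids = snps$snp_id,
                          output_snp_ids = snps$snp_id)
  ae <- train_autoencoder(ae, gm$values[sp$train_idx, ],
                          gm$values[sp$train_idx, ],
                          gm$values[sp$val_idx, ],
                          gm$values[sp$val_idx, ],
                          train_config(learning_rate = 2e-3,
                                       batch_size = 20, max_epochs = 100,
                                       eval_every = 1000, patience = 10))
  recon <- network_forward(ae, gm$values[sp$test_idx, ])
  for (j in 1:6)
    expect_gt(cor(recon[, j], gm$values[sp$test_idx, j]), 0.95)
})

test_that("AE-MLP composition is faithful when reconstruction is an identity", {
  co <- simulate_template_cohort("T1D10-like", n = 8000, seed = 51)
  d <- nnprs:::cohort_design(co)
  mlp <- build_mlp(10, seed = 1, input_snp_ids = d$snp_ids)
  mlp <- train_regressor(mlp, d$X_train, d$y_train, d$X_val, d$y_val,
                         train_config(max_epochs = 4))
  ae <- build_autoencoder(10, 10, seed = 1, input_snp_ids = d$snp_ids,
                          output_snp_ids = d$snp_ids)
  ae <- train_autoencoder(ae, d$X_train, d$X_train, d$X_val, d$X_val,
                          train_config(learning_rate = 5e-3,
                                       batch_size = 50, max_epochs = 400,
                                       eval_every = 2000, patience = 30))
  direct <- predict(mlp, d$X_test)
  composed <- predict_ae_mlp(ae, mlp, d$X_test)
  expect_gt(spearman_rank(composed, direct), 0.999)
  # zero network with bias c -> constant output c
  zero <- mlp
  for (l in seq_along(zero$weights)) zero$weights[[l]][] <- 0
  for (l in seq_along(zero$biases)) zero$biases[[l]][] <- 0
  zero$biases[[length(zero$biases)]][] <- 4.2
  expect_equal(predict_ae_mlp(ae, zero, d$X_test),
               rep(4.2, nrow(d$X_test)))
  # SNP-order mismatch is an error
  ae2 <- ae
  ae2$output_names <- rev(ae2$output_names)
  expect_error(predict_ae_mlp(ae2, mlp, d$X_test), "order")
})

test_that("non-finite loss aborts with a diagnostic", {
  X <- matrix(1e150, 50, 2)
  y <- rep(1e300, 50)
  net <- build_mlp(2, hidden = c(3), seed = 1)
  expect_error(
    train_regressor(net, X, y, X, y, fast_cfg(lr = 1, epochs = 1)),
    "non-finite")
})
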