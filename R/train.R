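#' Training configuration
#'
#' Defaults follow the standard recipe for these networks: Adam with
#' learning rate 1e-4 (5e-5 for the autoencoder) and batch size 5,
#' remaining Adam hyperparameters at their defaults (betas 0.9/0.999,
#' eps 1e-8), mean-squared-error objective, validation loss evaluated every
#' `eval_every` iterations with early stopping after `patience` evaluations
#' without improvement, and the best-validation parameter state retained.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Minibatch size (>= 1).
#' @param max_epochs Maximum passes over the training data.
#' @param patience Evaluations without validation improvement before
#'   stopping.
#' @param eval_every Iterations between validation evaluations.
#' @param seed Integer seed for batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 5,
                         max_epochs = 30, patience = 3, eval_every = 2000,
                         seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, eval_every >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

run_adam <- function(net, X, Y, Xval, Yval, cfg) {
  stopifnot(inherits(net, "trained_network"), inherits(cfg, "train_config"))
  X <- reconcile_input(net, X)
  Xval <- reconcile_input(net, Xval)
  Y <- as.matrix(Y); Yval <- as.matrix(Yval)
  width_out <- ncol(net$weights[[length(net$weights)]])
  if (ncol(Y) != width_out)
    stopf("labels have %d column(s); network has %d output(s)", ncol(Y),
          width_out)
  fit <- .cpp_train_adam(net$weights, net$biases,
                         act_code(net$activations), net$skip, X, Y, Xval,
                         Yval, cfg$learning_rate, cfg$batch_size,
                         cfg$max_epochs, cfg$eval_every, cfg$patience,
                         cfg$seed)
  hist <- data.frame(iteration = fit$history_iteration,
                     val_loss = fit$history_val_loss)
  per_out <- fit$history_per_output
  colnames(per_out) <- net$output_names %||%
    paste0("out", seq_len(ncol(per_out)))
  hist <- cbind(hist, as.data.frame(per_out))
  new_trained_network(fit$weights, lapply(fit$biases, as.numeric),
                      net$activations, net$skip, net$input_snp_ids,
                      net$output_names, history = hist,
                      best_val = fit$best_val)
}

#' Train a network to regress PRS labels
#'
#' Minimizes the batch mean squared error between network outputs and
#' labels (one column per output neuron; the multi-predictor network takes
#' one column per PRS) with Adam, and returns the parameter state with the
#' lowest validation loss. The per-evaluation validation-loss trace is kept
#' in `$history`.
#'
#' @param net A `trained_network` from [build_mlp()].
#' @param X_train,y_train Training inputs (samples x SNPs) and labels.
#' @param X_val,y_val Validation inputs and labels (model selection only).
#' @param cfg A [train_config()].
#' @return The trained `trained_network`.
#' @export
train_regressor <- function(net, X_train, y_train, X_val, y_val,
                            cfg = train_config()) {
  run_adam(net, X_train, y_train, X_val, y_val, cfg)
}

#' Train the SNP-imputing autoencoder
#'
#' The objective is the MSE between the autoencoder's `n_full`-wide output
#' and the original intact SNP vector, so the model learns to fill in the
#' SNPs absent from its input.
#'
#' @param ae A `trained_network` from [build_autoencoder()].
#' @param X_subset,X_full Training inputs (retained SNPs) and the
#'   corresponding full SNP matrices.
#' @param X_val_subset,X_val_full Validation counterparts.
#' @param cfg A [train_config()]; default learning rate 5e-5, batch 5.
#' @return The trained autoencoder.
#' @export
train_autoencoder <- function(ae, X_subset, X_full, X_val_subset,
                              X_val_full,
                              cfg = train_config(learning_rate = 5e-5)) {
  run_adam(ae, X_subset, X_full, X_val_subset, X_val_full, cfg)
}

#' Score samples through the autoencoder--MLP composition
#'
#' Applies the full-SNP-trained network to the autoencoder's reconstruction
#' of the complete SNP vector: the AE-MLP route for scoring samples with
#' missing SNPs.
#'
#' @param ae Trained autoencoder (input = retained SNPs, output = full set).
#' @param mlp_full Network trained on the full SNP set.
#' @param X_subset Matrix of retained-SNP values (or [genotype_matrix()]).
#' @return Numeric score vector (or matrix for multi-output networks).
#' @export
predict_ae_mlp <- function(ae, mlp_full, X_subset) {
  if (!is.null(ae$output_names) && !is.null(mlp_full$input_snp_ids) &&
      !identical(ae$output_names, mlp_full$input_snp_ids))
    stopf("autoencoder output SNP order does not match the network input")
  if (ncol(ae$weights[[length(ae$weights)]]) !=
      nrow(mlp_full$weights[[1]]))
    stopf("autoencoder output width != network input width")
  recon <- network_forward(ae, X_subset)
  out <- network_forward(mlp_full, recon)
  if (ncol(out) == 1) drop(out) else out
}

#' Fit a linear PRS predictor, optionally with elastic-net regularization
#'
#' Without regularization this is ordinary least squares (with intercept);
#' with `elastic_net`, a grid over L1 weight `lambda1` and L2 weight
#' `lambda2` (objective `||Xw - y||^2 + lambda1 |w|_1 + lambda2 |w|_2^2`) is
#' searched and the pair minimizing validation MSE wins. The penalized fits
#' are computed with glmnet; `lambda1 = lambda2 = 0` falls back to the
#' unpenalized solution. A rank-deficient unpenalized problem triggers a
#' warning and the minimum-norm solution.
#'
#' @param X Training inputs, samples x SNPs (samples > SNPs regime).
#' @param y Training labels.
#' @param elastic_net `NULL` for plain least squares, `TRUE` for the
#'   default grids (`{0}` plus 7 log-spaced points in 1e-4..1), or a list
#'   with numeric vectors `lambda1` and `lambda2`.
#' @param X_val,y_val Validation data (required for the grid search).
#' @return A `linear_predictor`: weights, intercept, chosen penalties and
#'   validation MSE.
#' @export
fit_linear <- function(X, y, elastic_net = NULL, X_val = NULL,
                       y_val = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.null(elastic_net)) {
    fit <- ols_fit(X, y)
    vm <- if (!is.null(X_val))
      mean((as.matrix(X_val) %*% fit$w + fit$b - y_val)^2) else NA_real_
    return(structure(list(weights = fit$w, intercept = fit$b,
                          lambda1 = 0, lambda2 = 0, val_mse = vm),
                     class = "linear_predictor"))
  }
  if (isTRUE(elastic_net))
    elastic_net <- list(lambda1 = c(0, 10^seq(-4, 0, length.out = 7)),
                        lambda2 = c(0, 10^seq(-4, 0, length.out = 7)))
  if (is.null(X_val) || is.null(y_val))
    stopf("elastic-net grid search needs validation data")
  X_val <- as.matrix(X_val); y_val <- as.numeric(y_val)
  n <- nrow(X)
  best <- NULL
  for (l1 in elastic_net$lambda1) for (l2 in elastic_net$lambda2) {
    if (l1 == 0 && l2 == 0) {
      fit <- ols_fit(X, y)
      w <- fit$w; b <- fit$b
    } else {
      # map ||Xw-y||^2 + l1|w|_1 + l2|w|_2^2 onto glmnet's
      # 1/(2n) RSS + lambda (alpha |w|_1 + (1-alpha)/2 |w|_2^2)
      lam <- l1 / (2 * n) + l2 / n
      alpha <- (l1 / (2 * n)) / lam
      g <- glmnet::glmnet(X, y, alpha = alpha, lambda = lam,
                          standardize = FALSE, thresh = 1e-10)
      w <- as.numeric(g$beta); b <- as.numeric(g$a0)
    }
    vm <- mean((X_val %*% w + b - y_val)^2)
    if (is.null(best) || vm < best$val_mse)
      best <- list(weights = w, intercept = b, lambda1 = l1, lambda2 = l2,
                   val_mse = vm)
  }
  structure(best, class = "linear_predictor")
}

ols_fit <- function(X, y) {
  Xi <- cbind(1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    warning("rank-deficient design; using minimum-norm least squares",
            call. = FALSE)
    sv <- svd(Xi)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else {
    coef <- qr.coef(qrx, y)
  }
  list(b = coef[1], w = as.numeric(coef[-1]))
}

#' @param object A `linear_predictor`.
#' @param newdata Input matrix.
#' @param ... Unused.
#' @rdname fit_linear
#' @export
predict.linear_predictor <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$weights + object$intercept)
}
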