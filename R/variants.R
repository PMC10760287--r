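#' Append all pairwise products to a SNP vector or matrix
#'
#' Input features come first, then the products `x_i * x_j` for all `i < j`
#' in lexicographic order: `p` features become `p + p(p-1)/2`. The
#' expansion adds no information but hands pairwise interactions to the
#' model directly.
#'
#' @param x Numeric vector (length p) or matrix (samples x p).
#' @return Expanded vector or matrix.
#' @export
expand_pairwise <- function(x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  p <- ncol(X)
  if (p < 2) return(if (vec) drop(X) else X)
  prods <- matrix(0, nrow(X), p * (p - 1) / 2)
  k <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    k <- k + 1
    prods[, k] <- X[, i] * X[, j]
  }
  out <- cbind(X, prods)
  if (vec) drop(out) else out
}

variant_catalogue_names <- c("Orig", "Hyperparams", "Capacity1",
                             "Capacity2", "Capacity3", "Capacity4", "Skip",
                             "Pairwise")

#' Instantiate a model variant from the fixed catalogue
#'
#' The catalogue used for the performance-limit study: `Orig` (and
#' `Capacity1`) is the standard 50/30/20 network; `Capacity2` a single
#' 200-neuron hidden layer; `Capacity3` seven hidden layers
#' (55,50,40,30,25,15,5); `Capacity4` seven wider layers
#' (200,160,120,90,70,50,10); `Skip` adds an unweighted input passthrough
#' onto the last hidden layer (width 20 + input); `Pairwise` feeds the
#' standard network the pairwise-product expansion of the inputs;
#' `Hyperparams` is the standard network with a learning-rate x batch-size
#' grid (lr 1e-3/1e-4/1e-5 by batch 5/20/100), winner by validation loss.
#'
#' @param name Catalogue name.
#' @param input_width Number of retained SNPs fed to the variant.
#' @return List: `name`, `hidden`, `skip`, `pairwise`, effective
#'   `input_width`, and `grid` (`NULL` except for `Hyperparams`).
#' @export
make_variant <- function(name, input_width) {
  if (!name %in% variant_catalogue_names)
    stopf("unknown variant '%s'", name)
  hidden <- switch(name,
    Capacity2 = 200,
    Capacity3 = c(55, 50, 40, 30, 25, 15, 5),
    Capacity4 = c(200, 160, 120, 90, 70, 50, 10),
    c(50, 30, 20))
  pairwise <- name == "Pairwise"
  eff_width <- if (pairwise) input_width + input_width *
      (input_width - 1) / 2 else input_width
  grid <- if (name == "Hyperparams")
    expand.grid(learning_rate = c(1e-3, 1e-4, 1e-5),
                batch_size = c(5, 20, 100)) else NULL
  list(name = name, hidden = hidden, skip = name == "Skip",
       pairwise = pairwise, input_width = eff_width, grid = grid)
}

#' Average predictions across models
#'
#' @param ... Prediction vectors of equal length, or a single list of them.
#' @return Elementwise arithmetic mean.
#' @export
ensemble_average <- function(...) {
  preds <- list(...)
  if (length(preds) == 1 && is.list(preds[[1]]) &&
      !is.numeric(preds[[1]])) preds <- preds[[1]]
  if (length(unique(lengths(preds))) != 1)
    stopf("prediction vectors differ in length")
  rowMeans(do.call(cbind, preds))
}

#' Train and compare the variant catalogue on one SNP subset
#'
#' Every catalogue variant is trained on the same retained-SNP subset with
#' the full-SNP PRS as label, then evaluated on the test split: Spearman
#' and RMSE against the PRS and case-versus-population AUC, all with
#' bootstrap CIs on shared resamples. Per-variant test predictions are
#' returned (plus a random scatter sample paired with `Orig`) so agreement
#' between variants can be inspected, and the ensemble (mean of all
#' variants) is reported alongside.
#'
#' @param cohort A `prs_cohort`.
#' @param retained Character vector of retained SNP ids (the subset task).
#' @param variants Catalogue names to run (default: all).
#' @param cfg Base [train_config()] (used verbatim except where a variant's
#'   grid overrides learning rate / batch size).
#' @param hyper_grid Optional data.frame(`learning_rate`, `batch_size`)
#'   replacing the default Hyperparams grid.
#' @param n_boot Bootstrap replicates.
#' @param n_scatter Test samples kept in the paired scatter data.
#' @return List of class `variant_study`: `metrics` (tidy data.frame),
#'   `agreement` (Pearson r of each variant vs `Orig`), `scatter`,
#'   `predictions`.
#' @export
run_variant_study <- function(cohort, retained,
                              variants = variant_catalogue_names,
                              cfg = train_config(), hyper_grid = NULL,
                              n_boot = 1000, n_scatter = 500) {
  stopifnot(inherits(cohort, "prs_cohort"))
  d <- cohort_design(cohort, retained)
  p <- length(retained)
  preds_test <- list(); preds_case <- list()
  for (vn in variants) {
    v <- make_variant(vn, p)
    tf <- if (v$pairwise) expand_pairwise else identity
    grid <- if (vn == "Hyperparams" && !is.null(hyper_grid)) hyper_grid
            else v$grid
    configs <- if (is.null(grid)) list(cfg) else
      lapply(seq_len(nrow(grid)), function(i)
        train_config(learning_rate = grid$learning_rate[i],
                     batch_size = grid$batch_size[i],
                     max_epochs = cfg$max_epochs, patience = cfg$patience,
                     eval_every = cfg$eval_every, seed = cfg$seed))
    best <- NULL
    for (ci in configs) {
      net <- build_mlp(v$input_width, hidden = v$hidden, skip = v$skip,
                       seed = ci$seed)
      net <- train_regressor(net, tf(d$X_train), d$y_train, tf(d$X_val),
                             d$y_val, ci)
      if (is.null(best) || net$best_val < best$best_val) best <- net
    }
    preds_test[[vn]] <- drop(network_forward(best, tf(d$X_test)))
    preds_case[[vn]] <- drop(network_forward(best, tf(d$X_case)))
  }
  preds_test$Ensemble <- ensemble_average(preds_test)
  preds_case$Ensemble <- ensemble_average(preds_case)

  out <- list()
  for (m in names(preds_test)) {
    reports <- list(
      bootstrap_ci(spearman_rank, list(preds_test[[m]], d$y_test), n_boot,
                   seed = cfg$seed, metric = "spearman"),
      bootstrap_ci(rmse, list(preds_test[[m]], d$y_test), n_boot,
                   seed = cfg$seed, metric = "rmse"),
      auc_ci(preds_case[[m]], preds_test[[m]], n_boot, seed = cfg$seed))
    for (r in reports)
      out[[length(out) + 1]] <- cbind(
        data.frame(variant = m, stringsAsFactors = FALSE),
        as.data.frame(r))
  }
  metrics <- do.call(rbind, out)

  others <- setdiff(names(preds_test), "Orig")
  agreement <- data.frame(
    variant = others,
    pearson_vs_orig = vapply(others, function(m)
      cor(preds_test[[m]], preds_test$Orig), 0),
    stringsAsFactors = FALSE)

  take <- with_seed(cfg$seed,
                    sample(length(d$y_test),
                           min(n_scatter, length(d$y_test))))
  scatter <- do.call(rbind, lapply(others, function(m)
    data.frame(variant = m, sample = take,
               orig_pred = preds_test$Orig[take],
               pred = preds_test[[m]][take], stringsAsFactors = FALSE)))

  structure(list(metrics = metrics, agreement = agreement,
                 scatter = scatter, predictions = preds_test),
            class = "variant_study")
}
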