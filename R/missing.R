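#' Seeded SNP-removal permutation
#'
#' Draws a uniform random removal order over the eligible SNPs and derives
#' the nested retained sets: step 0 keeps everything, step j removes the
#' first j SNPs of the order. SNPs outside `restrict_to` are never removed.
#'
#' @param snp_ids All SNP ids of the score.
#' @param seed Integer seed.
#' @param restrict_to Optional subset of `snp_ids` eligible for removal
#'   (e.g. only the correlated block).
#' @return A list of class `subset_spec`: `snp_ids`, `removal_order`,
#'   `retained_sets` (list, one per step, step 0 first), `restrict_to`.
#' @export
make_removal_permutation <- function(snp_ids, seed = 1,
                                     restrict_to = NULL) {
  snp_ids <- as.character(snp_ids)
  pool <- restrict_to %||% snp_ids
  bad <- setdiff(pool, snp_ids)
  if (length(bad)) stopf("restrict_to contains unknown SNP '%s'", bad[1])
  order <- with_seed(seed, sample(pool, length(pool)))
  retained <- vector("list", length(order) + 1)
  retained[[1]] <- snp_ids
  for (j in seq_along(order))
    retained[[j + 1]] <- setdiff(retained[[j]], order[j])
  structure(list(snp_ids = snp_ids, removal_order = order,
                 retained_sets = retained, restrict_to = restrict_to),
            class = "subset_spec")
}

#' Evaluate a PRS directly on a reduced SNP set
#'
#' Removed SNPs contribute nothing: their dosages are treated as 0 in the
#' additive part and every interaction term touching a removed SNP is
#' dropped (equivalently, a state indicator requiring a nonzero state can
#' never fire once its input is zeroed). This is the "PRS without the
#' relevant SNPs" baseline the trained models are compared against.
#'
#' @param genotypes A [genotype_matrix()].
#' @param prs A [prs_definition()].
#' @param retained Character vector of retained SNP ids.
#' @return Numeric score vector.
#' @export
prs_on_reduced <- function(genotypes, prs, retained) {
  retained <- as.character(retained)
  removed <- setdiff(prs$snp_ids, retained)
  if (!length(removed)) return(evaluate_prs(genotypes, prs))
  keep_it <- !(prs$interactions$snp_a %in% removed |
               prs$interactions$snp_b %in% removed)
  w <- prs$additive_weights
  w[prs$snp_ids %in% removed] <- 0
  reduced <- prs_definition(prs$snp_ids, prs$effect_alleles, w,
                            interactions =
                              prs$interactions[keep_it, , drop = FALSE],
                            intercept = prs$intercept, name = prs$name)
  # removed columns may be absent from the genotypes entirely; zero-fill
  geno <- as_genotype_matrix(genotypes)
  absent <- setdiff(removed, geno$snp_ids)
  if (length(absent)) {
    pad <- matrix(0, nrow(geno$values), length(absent))
    geno <- genotype_matrix(cbind(geno$values, pad),
                            c(geno$snp_ids, absent))
  } else {
    vals <- geno$values
    vals[, match(removed, geno$snp_ids)] <- 0
    geno <- genotype_matrix(vals, geno$snp_ids)
  }
  evaluate_prs(geno, reduced)
}

#' Run the missing-SNP compensation experiment
#'
#' For each evaluated removal step, trains the requested predictors on the
#' retained SNPs with the full-SNP PRS as the label -- a linear predictor,
#' the standard network, and the autoencoder--network composition -- and
#' evaluates each (plus the reduced-SNP PRS baseline) on the test split:
#' Spearman and RMSE against the full-SNP PRS, and case-versus-population
#' AUC. Bootstrap CIs use the same resamples across methods, so method
#' deltas are paired. Models are retrained from scratch at every step.
#'
#' @param cohort A `prs_cohort`.
#' @param subset A `subset_spec` from [make_removal_permutation()].
#' @param steps Integer vector of removal steps to evaluate (0 = all SNPs).
#' @param cfg [train_config()] for the regression networks.
#' @param ae_cfg [train_config()] for the autoencoder.
#' @param methods Any of `"prs_reduced"`, `"linear"`, `"mlp"`, `"ae_mlp"`.
#' @param n_boot Bootstrap replicates.
#' @param mlp_full Optional pre-trained full-SNP network reused for the
#'   AE-MLP composition (trained here when absent).
#' @return Tidy data.frame: step, n_retained, method, metric, estimate,
#'   ci_low, ci_high.
#' @export
run_subset_experiment <- function(cohort, subset, steps = NULL,
                                  cfg = train_config(),
                                  ae_cfg = train_config(learning_rate = 5e-5),
                                  methods = c("prs_reduced", "linear",
                                              "mlp", "ae_mlp"),
                                  n_boot = 1000, mlp_full = NULL) {
  stopifnot(inherits(cohort, "prs_cohort"), inherits(subset, "subset_spec"))
  methods <- match.arg(methods, several.ok = TRUE)
  max_step <- length(subset$removal_order)
  if (is.null(steps))
    steps <- unique(c(seq(0, max_step, by = 5), max_step))
  d_full <- cohort_design(cohort)
  n_full <- length(subset$snp_ids)
  if ("ae_mlp" %in% methods && is.null(mlp_full)) {
    mlp_full <- build_mlp(n_full, seed = cfg$seed,
                          input_snp_ids = subset$snp_ids)
    mlp_full <- train_regressor(mlp_full, d_full$X_train, d_full$y_train,
                                d_full$X_val, d_full$y_val, cfg)
  }
  sp <- cohort$splits
  out <- list()
  for (s in steps) {
    retained <- subset$retained_sets[[s + 1]]
    if (!length(retained)) {
      warning(sprintf("step %d retains 0 SNPs; skipped", s), call. = FALSE)
      next
    }
    d <- cohort_design(cohort, retained)
    preds <- list()
    if ("prs_reduced" %in% methods) {
      red <- prs_on_reduced(cohort$genotypes, cohort$prs, retained)
      preds$prs_reduced <- list(test = red[sp$test_idx],
                                case = red[sp$case_test_idx[[1]]])
    }
    if ("linear" %in% methods) {
      lin <- fit_linear(d$X_train, d$y_train)
      preds$linear <- list(test = predict(lin, d$X_test),
                           case = predict(lin, d$X_case))
    }
    if ("mlp" %in% methods) {
      net <- build_mlp(length(retained), seed = cfg$seed,
                       input_snp_ids = retained)
      net <- train_regressor(net, d$X_train, d$y_train, d$X_val, d$y_val,
                             cfg)
      preds$mlp <- list(test = predict(net, d$X_test),
                        case = predict(net, d$X_case))
    }
    if ("ae_mlp" %in% methods) {
      ae <- build_autoencoder(length(retained), n_full, seed = ae_cfg$seed,
                              input_snp_ids = retained,
                              output_snp_ids = subset$snp_ids)
      ae <- train_autoencoder(ae, d$X_train, d_full$X_train, d$X_val,
                              d_full$X_val, ae_cfg)
      preds$ae_mlp <- list(test = predict_ae_mlp(ae, mlp_full, d$X_test),
                           case = predict_ae_mlp(ae, mlp_full, d$X_case))
    }
    for (m in names(preds)) {
      reports <- list(
        bootstrap_ci(spearman_rank, list(preds[[m]]$test, d_full$y_test),
                     n_boot, seed = cfg$seed, metric = "spearman"),
        bootstrap_ci(rmse, list(preds[[m]]$test, d_full$y_test), n_boot,
                     seed = cfg$seed, metric = "rmse"),
        auc_ci(preds[[m]]$case, preds[[m]]$test, n_boot, seed = cfg$seed))
      for (r in reports)
        out[[length(out) + 1]] <-
          cbind(data.frame(step = s, n_retained = length(retained),
                           method = m, stringsAsFactors = FALSE),
                as.data.frame(r))
    }
  }
  do.call(rbind, out)
}

#' Leave-one-SNP-out autoencoder predictability
#'
#' For each target SNP, trains an autoencoder on all other SNPs and reports
#' the Pearson correlation between the predicted and actual values of the
#' held-out SNP on the test split -- the analysis that identifies which
#' SNPs (those in tight LD blocks) a network can impute.
#'
#' @param cohort A `prs_cohort`.
#' @param cfg [train_config()] for the autoencoder.
#' @param snps SNP ids to hold out (default: all).
#' @return Data frame: `snp_id`, `r` (0 for degenerate, constant SNPs),
#'   `degenerate` flag.
#' @export
leave_one_out_predictability <- function(cohort,
                                         cfg = train_config(
                                           learning_rate = 5e-5),
                                         snps = NULL) {
  geno <- cohort$genotypes
  snps <- snps %||% geno$snp_ids
  d_full <- cohort_design(cohort)
  out <- data.frame(snp_id = snps, r = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(snps)) {
    target <- snps[k]
    retained <- setdiff(geno$snp_ids, target)
    d <- cohort_design(cohort, retained)
    ae <- build_autoencoder(length(retained), length(geno$snp_ids),
                            seed = cfg$seed, input_snp_ids = retained,
                            output_snp_ids = geno$snp_ids)
    ae <- train_autoencoder(ae, d$X_train, d_full$X_train, d$X_val,
                            d_full$X_val, cfg)
    recon <- network_forward(ae, d$X_test)
    col <- match(target, geno$snp_ids)
    actual <- d_full$X_test[, col]
    pred <- recon[, col]
    if (sd(actual) == 0 || sd(pred) == 0) {
      out$r[k] <- 0
      out$degenerate[k] <- TRUE
    } else {
      out$r[k] <- cor(pred, actual)
    }
  }
  out
}
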