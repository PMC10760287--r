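#' Spearman rank correlation
#'
#' Pearson correlation of ranks, with ties receiving average ranks: the
#' fidelity metric between network scores and the programmed PRS.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  cor(rank(a), rank(b))
}

#' Root mean squared error
#'
#' @param a,b Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
rmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random case outscores a random non-case, with
#' ties counting one half; computed exactly from ranks.
#'
#' @param scores_pos Scores of the positive (case) group.
#' @param scores_neg Scores of the negative (population) group.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples sample indices (jointly across all columns of `data`, so
#' method comparisons on the same resamples stay paired) and reports the
#' percentile interval of the metric over `n_boot` replicates.
#'
#' @param metric_fn Function taking the resampled `data` columns as
#'   separate arguments and returning a scalar.
#' @param data A list (or data.frame) of equal-length vectors.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for resampling.
#' @param metric Metric name recorded in the report.
#' @return A `metric_report`: estimate, `ci_low`, `ci_high`, `n_boot`,
#'   `conf`, `seed`.
#' @export
bootstrap_ci <- function(metric_fn, data, n_boot = 1000, conf = 0.95,
                         seed = 1, metric = "metric") {
  data <- lapply(data, as.numeric)
  n <- unique(lengths(data))
  if (length(n) != 1) stopf("data vectors must share a length")
  est <- do.call(metric_fn, data)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      do.call(metric_fn, lapply(data, `[`, idx))
    }, 0)
  })
  qs <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE,
                 na.rm = TRUE)
  metric_report(metric, est, qs[1], qs[2], n_boot, conf, seed)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Cases and non-cases are resampled independently, preserving both class
#' sizes.
#'
#' @param scores_pos,scores_neg Case and population score vectors.
#' @inheritParams bootstrap_ci
#' @return A `metric_report`.
#' @export
auc_ci <- function(scores_pos, scores_neg, n_boot = 1000, conf = 0.95,
                   seed = 1) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  est <- auc(scores_pos, scores_neg)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      auc(scores_pos[sample.int(n1, n1, replace = TRUE)],
          scores_neg[sample.int(n0, n0, replace = TRUE)])
    }, 0)
  })
  qs <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  metric_report("auc", est, qs[1], qs[2], n_boot, conf, seed)
}

metric_report <- function(metric, estimate, ci_low, ci_high, n_boot, conf,
                          seed) {
  structure(list(metric = metric, estimate = estimate, ci_low = ci_low,
                 ci_high = ci_high, n_boot = n_boot, conf = conf,
                 seed = seed),
            class = "metric_report")
}

#' @export
#' @method print metric_report
print.metric_report <- function(x, ...) {
  cat(sprintf("%s: %.4f (%d%% CI %.4f-%.4f, %d resamples)\n", x$metric,
              x$estimate, round(100 * x$conf), x$ci_low, x$ci_high,
              x$n_boot))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(metric = x$metric, estimate = x$estimate, ci_low = x$ci_low,
             ci_high = x$ci_high, n_boot = x$n_boot, conf = x$conf,
             stringsAsFactors = FALSE)
}

# split a cohort into design matrices/labels used by the experiment drivers
cohort_design <- function(cohort, retained_ids = NULL) {
  geno <- cohort$genotypes
  ids <- retained_ids %||% geno$snp_ids
  idx <- match(ids, geno$snp_ids)
  if (anyNA(idx)) stopf("retained SNP '%s' not in cohort",
                        ids[which(is.na(idx))[1]])
  sp <- cohort$splits
  V <- geno$values
  list(snp_ids = ids,
       X_train = V[sp$train_idx, idx, drop = FALSE],
       X_val = V[sp$val_idx, idx, drop = FALSE],
       X_test = V[sp$test_idx, idx, drop = FALSE],
       X_case = V[sp$case_test_idx[[1]], idx, drop = FALSE],
       y_train = cohort$scores[sp$train_idx],
       y_val = cohort$scores[sp$val_idx],
       y_test = cohort$scores[sp$test_idx])
}

#' Training-set-size sweep for the standard network
#'
#' Retrains the standard PRS network on nested subsamples of the training
#' split and reports test-split Spearman, RMSE (against the ground-truth
#' PRS) and case-versus-population AUC, each with a bootstrap CI. The
#' subsamples are nested: every smaller training set is contained in every
#' larger one.
#'
#' @param cohort A `prs_cohort` from [simulate_template_cohort()].
#' @param sizes Integer vector of training-set sizes.
#' @param cfg A [train_config()].
#' @param n_boot Bootstrap replicates per interval.
#' @return Tidy data.frame: size, metric, estimate, ci_low, ci_high.
#' @export
training_size_sweep <- function(cohort, sizes, cfg = train_config(),
                                n_boot = 1000) {
  d <- cohort_design(cohort)
  perm <- with_seed(cfg$seed, sample(nrow(d$X_train)))
  out <- list()
  for (size in sizes) {
    if (size > length(perm)) stopf("size %d exceeds training split", size)
    take <- perm[seq_len(size)]
    net <- build_mlp(ncol(d$X_train), seed = cfg$seed,
                     input_snp_ids = d$snp_ids)
    net <- train_regressor(net, d$X_train[take, , drop = FALSE],
                           d$y_train[take], d$X_val, d$y_val, cfg)
    pred_test <- predict(net, d$X_test)
    pred_case <- predict(net, d$X_case)
    reports <- list(
      bootstrap_ci(spearman_rank, list(pred_test, d$y_test), n_boot,
                   seed = cfg$seed, metric = "spearman"),
      bootstrap_ci(rmse, list(pred_test, d$y_test), n_boot,
                   seed = cfg$seed, metric = "rmse"),
      auc_ci(pred_case, pred_test, n_boot, seed = cfg$seed))
    for (r in reports)
      out[[length(out) + 1]] <- cbind(data.frame(size = size),
                                      as.data.frame(r))
  }
  do.call(rbind, out)
}
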