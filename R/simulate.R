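#' Simulate effect-allele-count genotypes with LD-block structure
#'
#' Each genotype is the sum of two independent haplotypes. Within a
#' haplotype, allele presence at each SNP derives from a latent standard
#' normal thresholded at the minor-allele-frequency quantile; latent values
#' share an equicorrelation `rho` within a block (a Gaussian copula) and are
#' independent across blocks and for blockless SNPs. This emulates the
#' mutual predictability of SNPs in a tight LD region such as HLA-DQ.
#'
#' @param n Number of samples (>= 1).
#' @param snps Data frame with columns `snp_id`, `effect_allele`, `maf`
#'   (in (0, 0.5\]) and optionally `block_id` (`NA` = independent SNP).
#' @param blocks Optional data frame with columns `block_id` and `rho`
#'   (within-block latent correlation, in \[0, 1)).
#' @param seed Integer seed; the cohort is bit-reproducible from it.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, snps, blocks = NULL, seed = 1) {
  stopifnot(n >= 1)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "maf") %in% names(snps)))
    stopf("snps needs columns snp_id and maf")
  if (any(snps$maf <= 0 | snps$maf > 0.5))
    stopf("maf must lie in (0, 0.5]")
  if (is.null(snps$block_id)) snps$block_id <- NA_character_
  used_blocks <- unique(snps$block_id[!is.na(snps$block_id)])
  rho_of <- setNames(numeric(0), character(0))
  if (length(used_blocks)) {
    if (is.null(blocks)) stopf("block_id used but no blocks given")
    blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
    missing_b <- setdiff(used_blocks, blocks$block_id)
    if (length(missing_b)) stopf("block '%s' not defined", missing_b[1])
    if (any(blocks$rho < 0 | blocks$rho >= 1))
      stopf("rho must lie in [0, 1)")
    rho_of <- setNames(blocks$rho, blocks$block_id)
  }
  p <- nrow(snps)
  thr <- qnorm(snps$maf)
  with_seed(seed, {
    G <- matrix(0, n, p)
    for (hap in 1:2) {
      Z <- matrix(rnorm(n * p), n, p)
      for (b in used_blocks) {
        cols <- which(snps$block_id %in% b)
        rho <- rho_of[[b]]
        u <- rnorm(n)
        Z[, cols] <- sqrt(rho) * u + sqrt(1 - rho) * Z[, cols]
      }
      G <- G + (Z < rep(thr, each = n))
    }
    genotype_matrix(G, snp_ids = snps$snp_id,
                    effect_alleles = snps$effect_allele)
  })
}

#' Assign case status from PRS values under a logistic disease model
#'
#' `P(case | score) = plogis(alpha + beta * z)` with `z` the standardized
#' score; `alpha` is solved numerically so that the mean case probability
#' matches `prevalence_target` to within 1e-4.
#'
#' @param scores Numeric PRS vector.
#' @param beta Effect of one standard deviation of PRS on the log-odds
#'   (>= 0); 0 gives a null model, larger values raise the achievable AUC.
#' @param prevalence_target Mean case probability, in (0, 1).
#' @param seed Integer seed for the Bernoulli draws.
#' @return Logical vector of case labels.
#' @export
assign_disease <- function(scores, beta, prevalence_target, seed = 1) {
  stopifnot(beta >= 0)
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stopf("prevalence_target must lie in (0, 1)")
  s <- scores - mean(scores)
  if (sd(scores) > 0) s <- s / sd(scores)
  f <- function(alpha) mean(plogis(alpha + beta * s)) - prevalence_target
  sol <- tryCatch(uniroot(f, c(-60, 60), tol = 1e-12),
                  error = function(e) NULL)
  if (is.null(sol) || abs(f(sol$root)) > 1e-4)
    stopf("prevalence %g unattainable with beta %g", prevalence_target, beta)
  pr <- plogis(sol$root + beta * s)
  with_seed(seed, rbinom(length(scores), 1, pr) == 1)
}

#' Split a cohort 70/15/15 with case holdout
#'
#' Samples belonging to any case set are removed into dedicated case test
#' sets (a sample may belong to several). The remaining `m` samples are
#' randomly assigned `floor(f_train * m)` to training, `floor(f_val * m)` to
#' validation and the remainder to testing -- the rounding convention that
#' reproduces published UK-Biobank-scale split counts.
#'
#' @param n_total Total sample count.
#' @param case_sets `NULL`, an integer/logical index vector, or a (named)
#'   list of them -- the case samples to hold out.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed for the random assignment.
#' @return A list of class `cohort_splits` with `train_idx`, `val_idx`,
#'   `test_idx` and `case_test_idx` (list).
#' @export
split_cohort <- function(n_total, case_sets = NULL,
                         fractions = c(0.70, 0.15, 0.15), seed = 1) {
  stopifnot(length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  if (is.null(case_sets)) case_sets <- list()
  if (!is.list(case_sets)) case_sets <- list(case_sets)
  case_sets <- lapply(case_sets, function(s) {
    if (is.logical(s)) s <- which(s)
    s <- as.integer(s)
    if (length(s) && (min(s) < 1 || max(s) > n_total))
      stopf("case index out of range 1..%d", n_total)
    sort(unique(s))
  })
  held <- sort(unique(unlist(case_sets)))
  rest <- setdiff(seq_len(n_total), held)
  m <- length(rest)
  if (m < 1) stopf("no samples left after case holdout")
  n_train <- floor(fractions[1] * m)
  n_val <- floor(fractions[2] * m)
  perm <- with_seed(seed, sample(rest, m))
  structure(list(
    train_idx = sort(perm[seq_len(n_train)]),
    val_idx = sort(perm[n_train + seq_len(n_val)]),
    test_idx = sort(perm[(n_train + n_val + 1):m]),
    case_test_idx = case_sets), class = "cohort_splits")
}

#' SNP and block specifications matching a template PRS
#'
#' Builds the simulation inputs for a [make_template_prs()] score: the
#' designated block SNPs form one LD block (`block_id = "HLA_DQ_like"`) with
#' latent correlation `rho` and common-variant frequencies (HLA tag SNPs are
#' common); remaining SNPs are independent with frequencies drawn across the
#' common spectrum.
#'
#' @param prs A template [prs_definition()] carrying a `block_snps`
#'   attribute.
#' @param rho Within-block latent correlation (default 0.9, a tight block).
#' @param seed Integer seed for the frequency draws.
#' @return List with data frames `snps` and `blocks` for
#'   [simulate_genotypes()].
#' @export
template_snp_specs <- function(prs, rho = 0.9, seed = 1) {
  block_ids <- attr(prs, "block_snps") %||% character(0)
  with_seed(seed, {
    maf <- runif(length(prs$snp_ids), 0.05, 0.5)
    maf[prs$snp_ids %in% block_ids] <-
      runif(sum(prs$snp_ids %in% block_ids), 0.2, 0.45)
    list(
      snps = data.frame(
        snp_id = prs$snp_ids, effect_allele = prs$effect_alleles, maf = maf,
        block_id = ifelse(prs$snp_ids %in% block_ids, "HLA_DQ_like",
                          NA_character_),
        stringsAsFactors = FALSE),
      blocks = data.frame(block_id = "HLA_DQ_like", rho = rho,
                          stringsAsFactors = FALSE))
  })
}

#' Simulate a full study cohort for a template PRS
#'
#' One call produces everything an experiment needs: genotypes with a tight
#' LD block, ground-truth PRS values, logistic case labels, and 70/15/15
#' splits with the cases held out as a separate case test set.
#'
#' @param template Template name, see [make_template_prs()].
#' @param n Number of samples.
#' @param seed Integer master seed (sub-seeds are derived from it).
#' @param rho Within-block latent correlation.
#' @param beta Log-odds per PRS standard deviation (default 2, giving
#'   discrimination comparable to a strong clinical PRS, AUC about 0.9).
#' @param prevalence Target disease prevalence (default 0.02, so that
#'   moderate cohorts still hold a few hundred cases for AUC estimation).
#' @return List of class `prs_cohort`: `genotypes`, `prs`, `scores`,
#'   `labels`, `splits`, `snps`, `blocks`.
#' @export
simulate_template_cohort <- function(template = "T1D67-like", n = 20000,
                                     seed = 1, rho = 0.9, beta = 2,
                                     prevalence = 0.02) {
  prs <- make_template_prs(template, seed)
  spec <- template_snp_specs(prs, rho = rho, seed = seed + 1L)
  geno <- simulate_genotypes(n, spec$snps, spec$blocks, seed = seed + 2L)
  scores <- evaluate_prs(geno, prs)
  labels <- assign_disease(scores, beta = beta,
                           prevalence_target = prevalence, seed = seed + 3L)
  splits <- split_cohort(n, case_sets = list(case = which(labels)),
                         seed = seed + 4L)
  structure(list(genotypes = geno, prs = prs, scores = scores,
                 labels = labels, splits = splits, snps = spec$snps,
                 blocks = spec$blocks, seed = seed),
            class = "prs_cohort")
}

#' @export
#' @method print prs_cohort
print.prs_cohort <- function(x, ...) {
  cat(sprintf(paste0("<prs_cohort: %d samples x %d SNPs, PRS '%s', ",
                     "%d cases held out>\n"),
              nrow(x$genotypes$values), ncol(x$genotypes$values),
              x$prs$name, length(x$splits$case_test_idx[[1]])))
  invisible(x)
}
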