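#' Define a polygenic risk score with additive and interaction components
#'
#' A PRS here is `intercept + sum_i w_i g_i + sum_t c_t(g)` where `g_i` is the
#' effect-allele count of SNP `i` (0--2, fractional when imputed) and each
#' interaction term `c_t` is either a weighted product of two SNP dosages
#' (`mode = "product"`) or a weighted indicator that two SNPs sit in specific
#' genotype states (`mode = "state_indicator"`), the form HLA interaction
#' scores take.
#'
#' @param snp_ids Character vector of SNP identifiers (ordered).
#' @param effect_alleles One allele symbol per SNP; counts are of this allele.
#' @param additive_weights Numeric weight per SNP.
#' @param interactions `NULL` or a data.frame with columns `snp_a`, `snp_b`
#'   (SNP ids), `mode` (`"product"` or `"state_indicator"`), `state_a`,
#'   `state_b` (integers in 0:2; `NA` for product terms) and `weight`.
#' @param intercept Scalar added to every score (default 0).
#' @param name Score name used in weight files.
#' @return An object of class `prs_definition`.
#' @export
prs_definition <- function(snp_ids, effect_alleles, additive_weights,
                           interactions = NULL, intercept = 0,
                           name = "prs") {
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(snp_ids))
    stopf("duplicated SNP id: %s", snp_ids[duplicated(snp_ids)][1])
  if (length(effect_alleles) != length(snp_ids))
    stopf("effect_alleles length (%d) != snp_ids length (%d)",
          length(effect_alleles), length(snp_ids))
  if (length(additive_weights) != length(snp_ids))
    stopf("additive_weights length (%d) != snp_ids length (%d)",
          length(additive_weights), length(snp_ids))
  if (is.null(interactions)) {
    interactions <- data.frame(snp_a = character(), snp_b = character(),
                               mode = character(), state_a = integer(),
                               state_b = integer(), weight = numeric(),
                               stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    needed <- c("snp_a", "snp_b", "mode", "state_a", "state_b", "weight")
    miss <- setdiff(needed, names(interactions))
    if (length(miss)) stopf("interactions lacks column(s): %s",
                            paste(miss, collapse = ", "))
    interactions <- interactions[needed]
    for (col in c("snp_a", "snp_b")) {
      bad <- setdiff(interactions[[col]], snp_ids)
      if (length(bad)) stopf("interaction references unknown SNP id '%s'",
                             bad[1])
    }
    if (any(interactions$snp_a == interactions$snp_b))
      stopf("interaction must reference two distinct SNPs")
    if (!all(interactions$mode %in% c("product", "state_indicator")))
      stopf("unknown interaction mode '%s'",
            setdiff(interactions$mode,
                    c("product", "state_indicator"))[1])
    ind <- interactions$mode == "state_indicator"
    st <- c(interactions$state_a[ind], interactions$state_b[ind])
    if (any(is.na(st)) || !all(st %in% 0:2))
      stopf("state_indicator states must be integers in 0:2")
  }
  structure(
    list(name = name, snp_ids = snp_ids,
         effect_alleles = as.character(effect_alleles),
         additive_weights = as.numeric(additive_weights),
         interactions = interactions, intercept = as.numeric(intercept)),
    class = "prs_definition")
}

#' @export
#' @method print prs_definition
print.prs_definition <- function(x, ...) {
  cat(sprintf("<prs_definition '%s': %d SNPs, %d interaction term(s), intercept %g>\n",
              x$name, length(x$snp_ids), nrow(x$interactions), x$intercept))
  invisible(x)
}

#' Evaluate a PRS on a genotype matrix
#'
#' Columns are reconciled by SNP id (never by position); every SNP named in
#' the definition must be present in the genotypes.
#'
#' State-indicator terms match after rounding dosages to the nearest integer,
#' so imputed fractional dosages are handled.
#'
#' @param genotypes A [genotype_matrix()] (or plain numeric matrix with SNP
#'   ids as column names, values in \[0, 2\]).
#' @param prs A [prs_definition()].
#' @return Numeric vector of scores, one per sample.
#' @export
evaluate_prs <- function(genotypes, prs) {
  genotypes <- as_genotype_matrix(genotypes)
  stopifnot(inherits(prs, "prs_definition"))
  idx <- match(prs$snp_ids, genotypes$snp_ids)
  if (anyNA(idx))
    stopf("genotypes lack SNP '%s' required by PRS '%s'",
          prs$snp_ids[which(is.na(idx))[1]], prs$name)
  G <- genotypes$values[, idx, drop = FALSE]
  if (any(G < 0 | G > 2))
    stopf("genotype values outside [0, 2] for PRS evaluation")
  score <- drop(G %*% prs$additive_weights) + prs$intercept
  it <- prs$interactions
  if (nrow(it)) {
    a <- match(it$snp_a, prs$snp_ids)
    b <- match(it$snp_b, prs$snp_ids)
    for (t in seq_len(nrow(it))) {
      ga <- G[, a[t]]; gb <- G[, b[t]]
      contrib <- if (it$mode[t] == "product") {
        it$weight[t] * ga * gb
      } else {
        it$weight[t] * as.numeric(round(ga) == it$state_a[t] &
                                  round(gb) == it$state_b[t])
      }
      score <- score + contrib
    }
  }
  if (!all(is.finite(score))) stopf("non-finite PRS score produced")
  score
}

#' Write a PRS definition to a tab-delimited weight file
#'
#' Format: a `#<name>` header line, then one `A` line per SNP
#' (`A  snp_id  effect_allele  weight`), an optional `C` intercept line, then
#' one `I` line per interaction
#' (`I  snp_a  snp_b  mode  state_a  state_b  weight`), with `.` marking the
#' unused state fields of product terms.
#'
#' @param prs A [prs_definition()].
#' @param path Output file path.
#' @export
write_prs_definition <- function(prs, path) {
  stopifnot(inherits(prs, "prs_definition"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", prs$name), con)
  if (prs$intercept != 0)
    writeLines(sprintf("C\t%.17g", prs$intercept), con)
  writeLines(sprintf("A\t%s\t%s\t%.17g", prs$snp_ids, prs$effect_alleles,
                     prs$additive_weights), con)
  it <- prs$interactions
  if (nrow(it)) {
    sa <- ifelse(is.na(it$state_a), ".", as.character(it$state_a))
    sb <- ifelse(is.na(it$state_b), ".", as.character(it$state_b))
    writeLines(sprintf("I\t%s\t%s\t%s\t%s\t%s\t%.17g", it$snp_a, it$snp_b,
                       it$mode, sa, sb, it$weight), con)
  }
  invisible(path)
}

#' Read a PRS definition written by [write_prs_definition()]
#'
#' @param path Weight file path.
#' @return A [prs_definition()].
#' @export
load_prs_definition <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "prs"
  if (length(lines) && startsWith(lines[1], "#")) {
    name <- sub("^#\\s*", "", lines[1])
    lines <- lines[-1]
  }
  a_rows <- list(); i_rows <- list(); intercept <- 0
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (f[1] == "A") {
      if (length(f) != 4) stopf("line %d: additive line needs 4 fields", k + 1)
      w <- suppressWarnings(as.numeric(f[4]))
      if (is.na(w)) stopf("line %d: bad additive weight '%s'", k + 1, f[4])
      a_rows[[length(a_rows) + 1]] <- list(id = f[2], allele = f[3], w = w)
    } else if (f[1] == "I") {
      if (length(f) != 7) stopf("line %d: interaction line needs 7 fields",
                                k + 1)
      if (!f[4] %in% c("product", "state_indicator"))
        stopf("line %d: unknown interaction mode '%s'", k + 1, f[4])
      parse_state <- function(s) {
        if (s == ".") return(NA_integer_)
        v <- suppressWarnings(as.integer(s))
        if (is.na(v) || !v %in% 0:2)
          stopf("line %d: state '%s' out of range {0,1,2}", k + 1, s)
        v
      }
      w <- suppressWarnings(as.numeric(f[7]))
      if (is.na(w)) stopf("line %d: bad interaction weight '%s'", k + 1, f[7])
      i_rows[[length(i_rows) + 1]] <-
        data.frame(snp_a = f[2], snp_b = f[3], mode = f[4],
                   state_a = parse_state(f[5]), state_b = parse_state(f[6]),
                   weight = w, stringsAsFactors = FALSE)
    } else if (f[1] == "C") {
      intercept <- suppressWarnings(as.numeric(f[2]))
      if (is.na(intercept)) stopf("line %d: bad intercept", k + 1)
    } else {
      stopf("line %d: unknown record type '%s'", k + 1, f[1])
    }
  }
  if (!length(a_rows)) stopf("weight file has no additive (A) lines")
  prs_definition(
    snp_ids = vapply(a_rows, `[[`, "", "id"),
    effect_alleles = vapply(a_rows, `[[`, "", "allele"),
    additive_weights = vapply(a_rows, `[[`, 0, "w"),
    interactions = if (length(i_rows)) do.call(rbind, i_rows) else NULL,
    intercept = intercept, name = name)
}

#' Synthetic template PRSs emulating published interaction-bearing scores
#'
#' The published type 1 diabetes and celiac disease scores this package is
#' designed around are not reprinted here; these templates are synthetic
#' structural stand-ins with the same SNP counts and interaction layout:
#' `"T1D10-like"` (10 SNPs, one two-SNP state-indicator interaction),
#' `"T1D30-like"` (30 SNPs, one interaction), `"T1D67-like"` (67 SNPs, a set
#' of state-indicator interactions concentrated on a designated 14-SNP
#' correlated block, emulating HLA-DQ structure) and `"CD42-like"` (42 SNPs,
#' similar interactions on a 10-SNP block). Weights are drawn reproducibly
#' from `seed`. The ids of the designated block are attached as attribute
#' `"block_snps"`. Real published weights can be supplied instead via
#' [load_prs_definition()].
#'
#' @param template One of `"T1D10-like"`, `"T1D30-like"`, `"T1D67-like"`,
#'   `"CD42-like"`.
#' @param seed Integer seed controlling the drawn weights and ids.
#' @return A [prs_definition()] with attribute `block_snps`.
#' @export
make_template_prs <- function(template = c("T1D67-like", "T1D10-like",
                                           "T1D30-like", "CD42-like"),
                              seed = 1) {
  template <- match.arg(template)
  layout <- switch(template,
    "T1D10-like" = list(n = 10, block = 4, n_int = 1),
    "T1D30-like" = list(n = 30, block = 4, n_int = 1),
    "T1D67-like" = list(n = 67, block = 14, n_int = 10),
    "CD42-like"  = list(n = 42, block = 10, n_int = 6))
  with_seed(seed, {
    n <- layout$n
    ids <- sprintf("rs%07d", sample.int(9999999, n))
    alleles <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    # block SNPs lead the ordering and carry the large (HLA-like) weights
    w <- runif(n, 0.05, 0.5)
    w[seq_len(layout$block)] <- runif(layout$block, 0.3, 1.2)
    block_ids <- ids[seq_len(layout$block)]
    if (layout$n_int == 1) {
      it <- data.frame(snp_a = ids[1], snp_b = ids[2],
                       mode = "state_indicator", state_a = 1L, state_b = 1L,
                       weight = runif(1, 1.5, 2.5), stringsAsFactors = FALSE)
    } else {
      pairs <- utils::combn(layout$block, 2)
      pick <- sample.int(ncol(pairs), layout$n_int)
      it <- data.frame(
        snp_a = ids[pairs[1, pick]], snp_b = ids[pairs[2, pick]],
        mode = "state_indicator",
        state_a = sample(1:2, layout$n_int, replace = TRUE),
        state_b = sample(1:2, layout$n_int, replace = TRUE),
        weight = rnorm(layout$n_int, 0, 1.2), stringsAsFactors = FALSE)
    }
    out <- prs_definition(ids, alleles, w, it, intercept = 0,
                          name = template)
    attr(out, "block_snps") <- block_ids
    out
  })
}
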