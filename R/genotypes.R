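#' Container for effect-allele-count genotypes
#'
#' Values are per-sample counts of the effect allele, in \[0, 2\] (fractional
#' for imputed dosages). Entries flagged in `missing_mask` are held at 0 --
#' the convention used throughout: missing values are set to 0 before any
#' training or scoring.
#'
#' @param values Numeric matrix, samples x SNPs.
#' @param snp_ids Character vector of SNP ids (one per column).
#' @param effect_alleles Optional allele symbol per SNP.
#' @param missing_mask Optional logical matrix, same shape as `values`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snp_ids = colnames(values),
                            effect_alleles = NULL, missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(snp_ids)) stopf("snp_ids required (or set colnames on values)")
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(values))
    stopf("snp_ids length (%d) != number of columns (%d)", length(snp_ids),
          ncol(values))
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    missing_mask <- as.matrix(missing_mask)
    if (!identical(dim(missing_mask), dim(values)))
      stopf("missing_mask shape differs from values")
  }
  values[missing_mask] <- 0
  if (any(values < 0 | values > 2))
    stopf("genotype values must lie in [0, 2]")
  if (!is.null(effect_alleles) && length(effect_alleles) != length(snp_ids))
    stopf("effect_alleles length != snp_ids length")
  colnames(values) <- snp_ids
  structure(list(values = values, snp_ids = snp_ids,
                 effect_alleles = effect_alleles,
                 missing_mask = missing_mask),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d samples x %d SNPs, %d missing entr%s>\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask),
              if (sum(x$missing_mask) == 1) "y" else "ies"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(genotype_matrix(as.matrix(x)))
  stopf("cannot interpret object of class '%s' as genotypes", class(x)[1])
}

#' Read genotypes from a delimited matrix or PLINK-raw-style file
#'
#' Two layouts are supported. `"matrix"`: a delimited table of samples x
#' SNPs with SNP ids in the header. `"plink_raw"`: the `--recode A` style
#' layout with FID/IID/PAT/MAT/SEX/PHENOTYPE columns followed by
#' `SNPID_ALLELE` count columns; `NA` entries are recorded in the missing
#' mask and set to 0. With `format = "auto"` the PLINK layout is detected
#' from its leading header fields.
#'
#' @param path Input file.
#' @param format `"auto"`, `"matrix"` or `"plink_raw"`.
#' @param sep Field separator (default: any whitespace / tab).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "matrix", "plink_raw"),
                           sep = "") {
  format <- match.arg(format)
  if (format == "auto") {
    hdr <- strsplit(readLines(path, n = 1),
                    if (nzchar(sep)) sep else "[ \t]+")[[1]]
    format <- if (length(hdr) >= 6 &&
                  all(toupper(hdr[1:6]) ==
                      c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
      "plink_raw" else "matrix"
  }
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (format == "plink_raw") {
    geno_cols <- setdiff(names(tab),
                         c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
    vals <- as.matrix(tab[geno_cols])
    # header fields are snpid_allele; split on the final underscore
    snp_ids <- sub("_[^_]*$", "", geno_cols)
    alleles <- sub("^.*_", "", geno_cols)
    gm <- genotype_matrix(vals, snp_ids, effect_alleles = alleles)
    rownames(gm$values) <- tab$IID
    gm
  } else {
    genotype_matrix(as.matrix(tab))
  }
}

#' Write genotypes as a tab-delimited samples-x-SNPs matrix
#'
#' Masked (missing) entries are written as 0, matching the preprocessing
#' convention.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output file.
#' @export
write_genotypes <- function(genotypes, path) {
  genotypes <- as_genotype_matrix(genotypes)
  write.table(genotypes$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
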