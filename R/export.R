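#' Export a trained network as a portable plain-text bundle
#'
#' The bundle is line-oriented UTF-8 text: `#` comment lines, a
#' `format_version` line, a `[SNPS n]` section listing the ordered input
#' SNP ids with their effect alleles, an `[OUTPUTS k]` section naming the
#' output columns, and one `[LAYER l rows cols activation]` section per
#' layer holding the weight matrix (one row per line, space-separated) and
#' a final bias line. Values are written with 17 significant digits, so a
#' write--read roundtrip reproduces the doubles bit-exactly. Evaluating the
#' bundle needs only matrix arithmetic and `max` -- see
#' [forward_from_text()] -- which is what makes these models portable
#' across languages, spreadsheets and time.
#'
#' @param net A `trained_network`.
#' @param path Output file path.
#' @param effect_alleles Optional allele per input SNP (written as `.` if
#'   unknown).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, effect_alleles = NULL) {
  stopifnot(inherits(net, "trained_network"))
  p <- nrow(net$weights[[1]])
  ids <- net$input_snp_ids %||% sprintf("snp%03d", seq_len(p))
  alleles <- effect_alleles %||% rep(".", p)
  k_out <- ncol(net$weights[[length(net$weights)]])
  outs <- net$output_names %||%
    (if (k_out == 1) "score" else sprintf("score%d", seq_len(k_out)))
  num <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# nnprs plain-text network bundle",
               "format_version 1",
               sprintf("skip %d", as.integer(net$skip)),
               sprintf("[SNPS %d]", p),
               paste(ids, alleles),
               sprintf("[OUTPUTS %d]", k_out),
               outs), con)
  for (l in seq_along(net$weights)) {
    M <- net$weights[[l]]
    writeLines(sprintf("[LAYER %d %d %d %s]", l, nrow(M), ncol(M),
                       net$activations[l]), con)
    writeLines(apply(M, 1, function(r) paste(num(r), collapse = " ")), con)
    writeLines(paste(num(net$biases[[l]]), collapse = " "), con)
  }
  invisible(path)
}

#' Load a plain-text network bundle
#'
#' Validates the declared shapes against the matrix bodies and the
#' layer-to-layer chaining; any mismatch is a load error.
#'
#' @param path Bundle file written by [export_network()].
#' @return A `trained_network` (with an `effect_alleles` attribute).
#' @export
load_network_bundle <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  pos <- 1
  take <- function() {
    if (pos > length(lines)) stopf("unexpected end of bundle")
    ln <- lines[pos]; pos <<- pos + 1; ln
  }
  ver <- strsplit(take(), " +")[[1]]
  if (ver[1] != "format_version") stopf("missing format_version line")
  skipln <- strsplit(take(), " +")[[1]]
  if (skipln[1] != "skip") stopf("missing skip line")
  skip <- as.integer(skipln[2]) == 1L
  hdr <- take()
  m <- regmatches(hdr, regexec("^\\[SNPS ([0-9]+)\\]$", hdr))[[1]]
  if (!length(m)) stopf("expected [SNPS n] section, got '%s'", hdr)
  p <- as.integer(m[2])
  ids <- character(p); alleles <- character(p)
  for (i in seq_len(p)) {
    f <- strsplit(take(), " +")[[1]]
    ids[i] <- f[1]
    alleles[i] <- if (length(f) > 1) f[2] else "."
  }
  hdr <- take()
  m <- regmatches(hdr, regexec("^\\[OUTPUTS ([0-9]+)\\]$", hdr))[[1]]
  if (!length(m)) stopf("expected [OUTPUTS k] section, got '%s'", hdr)
  outs <- vapply(seq_len(as.integer(m[2])), function(i) take(), "")
  weights <- list(); biases <- list(); acts <- character()
  while (pos <= length(lines)) {
    hdr <- take()
    m <- regmatches(hdr, regexec(
      "^\\[LAYER ([0-9]+) ([0-9]+) ([0-9]+) ([a-z_]+)\\]$", hdr))[[1]]
    if (!length(m)) stopf("expected [LAYER ...] header, got '%s'", hdr)
    nr <- as.integer(m[3]); nc <- as.integer(m[4]); act <- m[5]
    if (!act %in% c("linear", "relu", "sigmoid_times_two"))
      stopf("unknown activation tag '%s'", act)
    M <- matrix(0, nr, nc)
    for (r in seq_len(nr)) {
      vals <- as.numeric(strsplit(trimws(take()), " +")[[1]])
      if (length(vals) != nc || anyNA(vals))
        stopf("layer %s row %d: expected %d values", m[2], r, nc)
      M[r, ] <- vals
    }
    b <- as.numeric(strsplit(trimws(take()), " +")[[1]])
    if (length(b) != nc || anyNA(b))
      stopf("layer %s: bias length != %d", m[2], nc)
    weights[[length(weights) + 1]] <- M
    biases[[length(biases) + 1]] <- b
    acts <- c(acts, act)
  }
  if (!length(weights)) stopf("bundle holds no layers")
  if (nrow(weights[[1]]) != p)
    stopf("first matrix has %d rows but %d SNPs are listed",
          nrow(weights[[1]]), p)
  net <- new_trained_network(weights, biases, acts, skip,
                             input_snp_ids = ids, output_names = outs)
  attr(net, "effect_alleles") <- alleles
  net
}

#' Evaluate a text bundle with matrix arithmetic alone
#'
#' The four-step forward pass, layer by layer:
#' `v_l = act_l(v_{l-1} %*% M_l + b_l)` with ReLU `f(x) = max(0, x)` on
#' hidden layers. No training framework is involved -- only `%*%`, `+`,
#' `pmax` and (for dosage heads) `exp`.
#'
#' @param bundle A bundle file path or a network loaded by
#'   [load_network_bundle()].
#' @param v0 Input row (ordered as the bundle's SNP list) or a samples x
#'   SNPs matrix.
#' @return The predicted score(s): scalar, vector or matrix.
#' @export
forward_from_text <- function(bundle, v0) {
  net <- if (inherits(bundle, "trained_network")) bundle
         else load_network_bundle(bundle)
  X <- if (is.null(dim(v0))) matrix(v0, nrow = 1) else as.matrix(v0)
  if (ncol(X) != nrow(net$weights[[1]]))
    stopf("input has %d values; bundle expects %d", ncol(X),
          nrow(net$weights[[1]]))
  L <- length(net$weights)
  a <- X
  for (l in seq_len(L)) {
    inp <- if (net$skip && l == L) cbind(a, X) else a
    z <- sweep(inp %*% net$weights[[l]], 2, net$biases[[l]], `+`)
    a <- switch(net$activations[l],
                relu = pmax(z, 0),
                sigmoid_times_two = 2 / (1 + exp(-z)),
                linear = z)
  }
  drop(a)
}
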