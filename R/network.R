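#' Rectified linear unit
#'
#' `f(x) = max(0, x)`, applied elementwise; the hidden-layer activation of
#' every network in the package.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

act_code <- function(a) {
  code <- c(linear = 0L, relu = 1L, sigmoid_times_two = 2L)[a]
  if (anyNA(code)) stopf("unknown activation '%s'", a[is.na(code)][1])
  unname(code)
}

new_trained_network <- function(weights, biases, activations, skip,
                                input_snp_ids = NULL, output_names = NULL,
                                history = NULL, best_val = NA_real_) {
  L <- length(weights)
  for (l in seq_len(L)) {
    if (length(biases[[l]]) != ncol(weights[[l]]))
      stopf("layer %d: bias length != matrix columns", l)
    if (l > 1) {
      expected <- ncol(weights[[l - 1]])
      if (skip && l == L) expected <- expected + nrow(weights[[1]])
      if (nrow(weights[[l]]) != expected)
        stopf("layer %d: matrix rows (%d) do not chain (expected %d)", l,
              nrow(weights[[l]]), expected)
    }
  }
  structure(list(weights = weights, biases = biases,
                 activations = activations, skip = skip,
                 input_snp_ids = input_snp_ids,
                 output_names = output_names, history = history,
                 best_val = best_val),
            class = "trained_network")
}

#' Build a multilayer perceptron for PRS regression
#'
#' The default architecture is the standard PRS network: three ReLU hidden
#' layers of 50, 30 and 20 neurons and a linear output neuron. Weights are
#' initialized with the He fan-in scheme for ReLU stacks -- uniform on
#' (-sqrt(6/fan_in), sqrt(6/fan_in)) -- so activations keep their scale
#' through deep variants; biases start uniform on the same interval scaled
#' down. All draws are reproducible from `seed`.
#'
#' @param input_width Number of input SNPs (>= 1).
#' @param hidden Integer vector of hidden-layer widths.
#' @param output_width Number of output neurons (one per predicted PRS).
#' @param output_activation `"linear"` (regression head) or
#'   `"sigmoid_times_two"` (dosage head, range (0, 2)).
#' @param skip If `TRUE`, the input vector is concatenated, unweighted, onto
#'   the last hidden layer's activations before the output layer.
#' @param seed Integer seed for the initialization.
#' @param input_snp_ids,output_names Optional names carried with the model
#'   (SNP order is part of a portable model).
#' @return A `trained_network` (untrained; `history` is `NULL`).
#' @export
build_mlp <- function(input_width, hidden = c(50, 30, 20), output_width = 1,
                      output_activation = c("linear", "sigmoid_times_two"),
                      skip = FALSE, seed = 1, input_snp_ids = NULL,
                      output_names = NULL) {
  output_activation <- match.arg(output_activation)
  stopifnot(input_width >= 1, output_width >= 1)
  if (any(hidden < 1)) stopf("zero-width hidden layer")
  if (!is.null(input_snp_ids) && length(input_snp_ids) != input_width)
    stopf("input_snp_ids length != input_width")
  in_dims <- c(input_width, hidden)
  out_dims <- c(hidden, output_width)
  L <- length(out_dims)
  if (skip) in_dims[L] <- in_dims[L] + input_width
  with_seed(seed, {
    weights <- vector("list", L)
    biases <- vector("list", L)
    for (l in seq_len(L)) {
      bound <- sqrt(6 / in_dims[l])  # He-uniform: Var(w) = 2/fan_in
      weights[[l]] <- matrix(runif(in_dims[l] * out_dims[l], -bound, bound),
                             in_dims[l], out_dims[l])
      biases[[l]] <- runif(out_dims[l], -1 / sqrt(in_dims[l]),
                           1 / sqrt(in_dims[l]))
    }
    new_trained_network(weights, biases,
                        activations = c(rep("relu", L - 1),
                                        output_activation),
                        skip = skip, input_snp_ids = input_snp_ids,
                        output_names = output_names)
  })
}

#' Build the SNP-imputing autoencoder
#'
#' Maps a subset of `n_input` SNPs to a reconstruction of all `n_full`
#' original SNPs: two ReLU hidden layers of `n_full` neurons each and an
#' `n_full`-wide output layer whose activation is a sigmoid multiplied by
#' two, so every predicted dosage lies in (0, 2).
#'
#' @param n_input Number of retained input SNPs (1 <= n_input <= n_full).
#' @param n_full Number of SNPs to reconstruct.
#' @param seed Integer seed for initialization.
#' @param input_snp_ids,output_snp_ids Optional SNP orderings of the input
#'   subset and the reconstructed full set.
#' @return A `trained_network`.
#' @export
build_autoencoder <- function(n_input, n_full, seed = 1,
                              input_snp_ids = NULL, output_snp_ids = NULL) {
  if (n_input < 1) stopf("n_input must be >= 1")
  if (n_input > n_full) stopf("n_input (%d) exceeds n_full (%d)", n_input,
                              n_full)
  net <- build_mlp(n_input, hidden = c(n_full, n_full),
                   output_width = n_full,
                   output_activation = "sigmoid_times_two", seed = seed,
                   input_snp_ids = input_snp_ids,
                   output_names = output_snp_ids)
  net
}

#' Forward pass of a network
#'
#' @param net A `trained_network`.
#' @param X Numeric matrix (samples x input width) or [genotype_matrix()];
#'   genotype columns are reordered to the network's `input_snp_ids`.
#' @return Numeric matrix, samples x output width.
#' @export
network_forward <- function(net, X) {
  stopifnot(inherits(net, "trained_network"))
  X <- reconcile_input(net, X)
  .cpp_forward(net$weights, net$biases, act_code(net$activations),
               net$skip, X)
}

reconcile_input <- function(net, X) {
  if (inherits(X, "genotype_matrix")) {
    if (!is.null(net$input_snp_ids)) {
      idx <- match(net$input_snp_ids, X$snp_ids)
      if (anyNA(idx))
        stopf("genotypes lack SNP '%s' required by the network",
              net$input_snp_ids[which(is.na(idx))[1]])
      X <- X$values[, idx, drop = FALSE]
    } else X <- X$values
  }
  X <- as.matrix(X)
  if (ncol(X) != nrow(net$weights[[1]]))
    stopf("input has %d columns; network expects %d", ncol(X),
          nrow(net$weights[[1]]))
  X
}

#' @param object A `trained_network`.
#' @param newdata Input matrix or [genotype_matrix()].
#' @param ... Unused.
#' @return A vector (single output) or matrix of predictions.
#' @rdname network_forward
#' @export
predict.trained_network <- function(object, newdata, ...) {
  out <- network_forward(object, newdata)
  if (ncol(out) == 1) drop(out) else out
}

#' @export
#' @method print trained_network
print.trained_network <- function(x, ...) {
  dims <- vapply(x$weights, function(w) paste(dim(w), collapse = "x"), "")
  cat(sprintf("<trained_network: %s%s, activations %s%s>\n",
              paste(dims, collapse = " -> "),
              if (x$skip) " (+input skip)" else "",
              paste(x$activations, collapse = "/"),
              if (is.null(x$history)) " [untrained]" else ""))
  invisible(x)
}
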