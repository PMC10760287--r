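# shared fixtures built in code

# quick training configuration for unit tests (not the study defaults)
fast_cfg <- function(lr = 1e-3, batch = 5, epochs = 4, seed = 1,
                     eval_every = 500) {
  train_config(learning_rate = lr, batch_size = batch, max_epochs = epochs,
               eval_every = eval_every, seed = seed)
}

# small random PRS over p SNPs with both interaction modes
random_prs <- function(p = 5, n_int = 2, seed = 1) {
  with_seed_test(seed, {
    ids <- sprintf("rs%04d", sample.int(9999, p))
    it <- NULL
    if (n_int > 0) {
      pairs <- replicate(n_int, sample.int(p, 2))
      it <- data.frame(
        snp_a = ids[pairs[1, ]], snp_b = ids[pairs[2, ]],
        mode = sample(c("product", "state_indicator"), n_int,
                      replace = TRUE),
        state_a = sample(0:2, n_int, replace = TRUE),
        state_b = sample(0:2, n_int, replace = TRUE),
        weight = rnorm(n_int), stringsAsFactors = FALSE)
      it$state_a[it$mode == "product"] <- NA
      it$state_b[it$mode == "product"] <- NA
    }
    prs_definition(ids, sample(c("A", "C", "G", "T"), p, replace = TRUE),
                   rnorm(p), it, intercept = rnorm(1))
  })
}

random_geno <- function(n, prs, seed = 1) {
  with_seed_test(seed, {
    genotype_matrix(matrix(sample(0:2, n * length(prs$snp_ids),
                                  replace = TRUE),
                           n, length(prs$snp_ids)),
                    snp_ids = prs$snp_ids)
  })
}

# slow, explicit double-loop PRS oracle
prs_oracle <- function(G, prs) {
  scores <- numeric(nrow(G))
  for (k in seq_len(nrow(G))) {
    s <- prs$intercept
    for (i in seq_along(prs$snp_ids))
      s <- s + prs$additive_weights[i] * G[k, prs$snp_ids[i]]
    it <- prs$interactions
    if (nrow(it)) for (t in seq_len(nrow(it))) {
      ga <- G[k, it$snp_a[t]]; gb <- G[k, it$snp_b[t]]
      s <- s + if (it$mode[t] == "product") it$weight[t] * ga * gb
      else it$weight[t] * (round(ga) == it$state_a[t] &&
                           round(gb) == it$state_b[t])
    }
    scores[k] <- s
  }
  scores
}

# explicit per-neuron forward-pass oracle
forward_oracle <- function(net, X) {
  L <- length(net$weights)
  out <- matrix(0, nrow(X), ncol(net$weights[[L]]))
  for (k in seq_len(nrow(X))) {
    a <- X[k, ]
    for (l in seq_len(L)) {
      inp <- if (net$skip && l == L) c(a, X[k, ]) else a
      z <- numeric(ncol(net$weights[[l]]))
      for (j in seq_along(z)) {
        acc <- net$biases[[l]][j]
        for (i in seq_along(inp))
          acc <- acc + inp[i] * net$weights[[l]][i, j]
        z[j] <- acc
      }
      a <- switch(net$activations[l],
                  relu = ifelse(z > 0, z, 0),
                  sigmoid_times_two = 2 / (1 + exp(-z)),
                  linear = z)
    }
    out[k, ] <- a
  }
  out
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
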