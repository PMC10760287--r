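test_that("evaluate_prs matches the double-loop oracle on random instances", {
  for (seed in 1:8) {
    prs <- random_prs(p = 5, n_int = 2, seed = seed)
    gm <- random_geno(5, prs, seed = seed + 100)
    expect_equal(evaluate_prs(gm, prs), prs_oracle(gm$values, prs),
                 tolerance = 1e-12)
  }
})

test_that("additive evaluation handles trivial cases by hand", {
  prs <- prs_definition(c("a", "b"), c("A", "C"), c(1, 2))
  gm <- genotype_matrix(matrix(c(0, 1, 0, 2), 2, 2), c("a", "b"))
  expect_equal(evaluate_prs(gm, prs), c(0, 1 * 1 + 2 * 2))
})

test_that("state-indicator term fires only in its genotype state", {
  prs <- prs_definition(
    c("a", "b"), c("A", "C"), c(0, 0),
    data.frame(snp_a = "a", snp_b = "b", mode = "state_indicator",
               state_a = 1L, state_b = 1L, weight = 3))
  combos <- expand.grid(ga = 0:2, gb = 0:2)
  gm <- genotype_matrix(as.matrix(combos), c("a", "b"))
  expected <- ifelse(combos$ga == 1 & combos$gb == 1, 3, 0)
  expect_equal(evaluate_prs(gm, prs), expected)
})

test_that("scores are invariant to genotype column permutation", {
  prs <- random_prs(p = 6, n_int = 3, seed = 3)
  gm <- random_geno(20, prs, seed = 4)
  perm <- with_seed_test(5, sample(6))
  gm2 <- genotype_matrix(gm$values[, perm], gm$snp_ids[perm])
  expect_equal(evaluate_prs(gm, prs), evaluate_prs(gm2, prs))
})

test_that("removing a state-indicator term only changes matching samples", {
  prs <- make_template_prs("T1D67-like", seed = 2)
  gm <- random_geno(200, prs, seed = 5)
  full <- evaluate_prs(gm, prs)
  it <- prs$interactions
  drop_t <- 3
  pruned <- prs_definition(prs$snp_ids, prs$effect_alleles,
                           prs$additive_weights,
                           it[-drop_t, , drop = FALSE])
  delta <- full - evaluate_prs(gm, pruned)
  fires <- gm$values[, it$snp_a[drop_t]] == it$state_a[drop_t] &
    gm$values[, it$snp_b[drop_t]] == it$state_b[drop_t]
  expect_equal(delta[fires], rep(it$weight[drop_t], sum(fires)))
  expect_equal(delta[!fires], rep(0, sum(!fires)))
})

test_that("evaluation errors name the offending SNP and bad values", {
  prs <- prs_definition(c("a", "b"), c("A", "C"), c(1, 2))
  gm <- genotype_matrix(matrix(1, 2, 1), "a")
  expect_error(evaluate_prs(gm, prs), "'b'")
  gm2 <- genotype_matrix(matrix(1, 2, 2), c("a", "b"))
  gm2$values[1, 1] <- 2.5
  expect_error(evaluate_prs(gm2, prs), "\\[0, 2\\]")
})

test_that("weight files roundtrip a 67-SNP interaction definition exactly", {
  prs <- make_template_prs("T1D67-like", seed = 7)
  path <- withr::local_tempfile(fileext = ".prs")
  write_prs_definition(prs, path)
  back <- load_prs_definition(path)
  expect_equal(back$snp_ids, prs$snp_ids)
  expect_identical(back$additive_weights, prs$additive_weights)
  expect_identical(back$interactions$weight, prs$interactions$weight)
  expect_equal(back$interactions, prs$interactions)
  gm <- random_geno(10, prs, seed = 8)
  expect_identical(evaluate_prs(gm, back), evaluate_prs(gm, prs))
})

test_that("weight-file parser rejects malformed content with line numbers", {
  path <- withr::local_tempfile(fileext = ".prs")
  writeLines(c("#bad", "A\trs1\tA\t0.5",
               "I\trs1\trs9\tstate_indicator\t1\t1\t2.0"), path)
  expect_error(load_prs_definition(path), "unknown SNP id 'rs9'")
  writeLines(c("#bad", "A\trs1\tA\t0.5", "A\trs2\tC\t0.2",
               "I\trs1\trs2\tquadratic\t1\t1\t2.0"), path)
  expect_error(load_prs_definition(path), "line 4.*quadratic")
  writeLines(c("#bad", "A\trs1\tA\t0.5", "A\trs2\tC\t0.2",
               "I\trs1\trs2\tstate_indicator\t5\t1\t2.0"), path)
  expect_error(load_prs_definition(path), "out of range")
})

test_that("a purely additive file evaluates as a weighted dot product", {
  path <- withr::local_tempfile(fileext = ".prs")
  writeLines(c("#add", "A\trs1\tA\t0.5", "A\trs2\tC\t-0.25"), path)
  prs <- load_prs_definition(path)
  expect_equal(nrow(prs$interactions), 0)
  gm <- genotype_matrix(matrix(c(2, 1, 1, 2), 2, 2), c("rs1", "rs2"))
  expect_equal(evaluate_prs(gm, prs),
               drop(gm$values %*% c(0.5, -0.25)))
})

test_that("templates have the published SNP counts and interaction layout", {
  expect_length(make_template_prs("T1D10-like", 1)$snp_ids, 10)
  expect_length(make_template_prs("T1D30-like", 1)$snp_ids, 30)
  expect_length(make_template_prs("T1D67-like", 1)$snp_ids, 67)
  expect_length(make_template_prs("CD42-like", 1)$snp_ids, 42)
  expect_equal(nrow(make_template_prs("T1D10-like", 1)$interactions), 1)
  expect_equal(nrow(make_template_prs("T1D30-like", 1)$interactions), 1)
  t67 <- make_template_prs("T1D67-like", 5)
  expect_gt(nrow(t67$interactions), 1)
  block <- attr(t67, "block_snps")
  expect_length(block, 14)
  expect_true(all(t67$interactions$snp_a %in% block))
  expect_true(all(t67$interactions$snp_b %in% block))
  expect_true(all(t67$interactions$mode == "state_indicator"))
  expect_identical(make_template_prs("T1D67-like", 3),
                   make_template_prs("T1D67-like", 3))
  expect_error(make_template_prs("T2D99-like", 1))
})

test_that("genotype files roundtrip and PLINK-raw missing values mask to 0", {
  gm <- random_geno(6, random_prs(4, 0, seed = 9), seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  back <- read_genotypes(path)
  expect_equal(unname(back$values), unname(gm$values))
  expect_equal(back$snp_ids, gm$snp_ids)

  praw <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
               "f1 s1 0 0 1 -9 2 NA",
               "f2 s2 0 0 2 -9 0 1"), praw)
  g2 <- read_genotypes(praw)
  expect_equal(g2$snp_ids, c("rs1", "rs2"))
  expect_equal(g2$effect_alleles, c("A", "G"))
  expect_equal(unname(g2$values), matrix(c(2, 0, 0, 1), 2, 2))
  expect_true(g2$missing_mask[1, 2])
  expect_equal(sum(g2$missing_mask), 1)
})
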