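test_that("block correlation targets are assembled and validated", {
  # perfect within-block correlation: all-ones block
  R1 <- build_block_correlation(list(block_spec("b", c("a", "b", "c"), 1)))
  expect_equal(unname(R1), matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(attr(R1, "repair_delta"), 0)

  # two blocks, no between-block correlation: direct construction
  R2 <- build_block_correlation(list(block_spec("b1", c("a", "b"), 0.8),
                                     block_spec("b2", "c", 0.5)))
  expect_equal(unname(R2),
               matrix(c(1, .8, 0, .8, 1, 0, 0, 0, 1), 3),
               ignore_attr = TRUE)

  # default 12-trait 4-block target is PSD: block-diagonal eigenvalues are
  # the union of the per-block spectra {1 + (k-1) r, 1 - r ...}
  R12 <- build_block_correlation(default_blocks())
  ev <- eigen(R12, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  per_block <- sort(c(1 + 4 * 0.7, rep(0.3, 4),   # 5-trait block
                      1 + 2 * 0.7, rep(0.3, 2),   # 3-trait block
                      1.7, 0.3, 1.7, 0.3), decreasing = TRUE)
  expect_close(sort(ev, decreasing = TRUE), per_block, 1e-10)

  # a trait cannot sit in two blocks
  expect_error(build_block_correlation(list(block_spec("b1", c("a", "b"), .5),
                                            block_spec("b2", c("b"), .5))),
               "more than one block")

  # strongly indefinite request (three mutually negative singletons):
  # repair would move entries too far
  expect_error(build_block_correlation(list(
    block_spec("b1", "a", 0, between_r = -0.9),
    block_spec("b2", "b", 0, between_r = -0.9),
    block_spec("b3", "c", 0, between_r = -0.9))),
    "respecify")
})

test_that("sign patterns encode within-block trade-offs", {
  R <- build_block_correlation(list(
    block_spec("b", c("a", "b", "c"), 0.6, sign_pattern = c(1, 1, -1))))
  expect_equal(R["a", "b"], 0.6)
  expect_equal(R["a", "c"], -0.6)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
})

test_that("simulated trait matrices hit the correlation target", {
  # identity target: all empirical correlations near zero (Fisher-z bound
  # at n = 5000: 3/sqrt(n-3) is about 0.042)
  tm <- simulate_trait_matrix(diag(4), n = 5000, seed = 11)
  r <- cor(tm$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # a 0.7 entry is recovered within its Fisher-z interval
  tgt <- two_block_target(0.7)
  tm2 <- simulate_trait_matrix(tgt, n = 5000, seed = 12)
  expect_gt(cor(tm2$values)["x1", "x2"], 0.65)
  expect_lt(cor(tm2$values)["x1", "x2"], 0.75)

  # determinism and shape
  tm3 <- simulate_trait_matrix(tgt, n = 100, seed = 5)
  tm4 <- simulate_trait_matrix(tgt, n = 100, seed = 5)
  expect_identical(tm3$values, tm4$values)
  expect_equal(dim(tm3), c(100L, 4L))

  # non-PSD target rejected
  bad <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3)
  expect_error(simulate_trait_matrix(bad, 10, seed = 1),
               "not positive semi-definite")
})

test_that("empirical correlation converges to the target with n", {
  tgt <- two_block_target(0.7)
  frob <- function(n) {
    tm <- simulate_trait_matrix(tgt, n, seed = 99)
    norm(cor(tm$values) - tgt, "F")
  }
  expect_lt(frob(5000), frob(500))
})

test_that("raw-scale simulation feeds the preprocessing path", {
  tgt <- two_block_target(0.5)
  tm <- simulate_trait_matrix(tgt, 400, seed = 3, raw_scale = TRUE,
                              mu = c(0, 1, 2, 0), sigma = 0.5)
  expect_identical(tm$transform, "raw")
  expect_true(all(tm$values > 0))
  back <- log_scale_transform(tm)
  # standardisation removes mu/sigma: correlations match the direct draw
  direct <- simulate_trait_matrix(tgt, 400, seed = 3)
  expect_close(cor(back$values), cor(direct$values), 1e-10)
})

test_that("missingness mechanisms respect requested completeness", {
  tm <- random_complete_tm(10000, 1, seed = 21)
  # completeness 1: identity
  sp1 <- missingness_spec(c(t1 = 1), mechanism = "mcar", seed = 1)
  expect_identical(apply_missingness(tm, sp1)$values, tm$values)

  # completeness 0.5 at n = 10000: 3-SD binomial band [4850, 5150]
  sp2 <- missingness_spec(c(t1 = 0.5), mechanism = "mcar", seed = 2)
  n_obs <- sum(!is.na(apply_missingness(tm, sp2)$values))
  expect_gte(n_obs, 4850)
  expect_lte(n_obs, 5150)

  # the compilation-like extremes (58% / 3%) are realised within 3 binomial
  # SDs under both mechanisms
  tm2 <- random_complete_tm(10000, 2, seed = 22)
  for (mech in c("mcar", "stratified")) {
    sp <- missingness_spec(c(t1 = 0.5848, t2 = 0.0313), mechanism = mech,
                           seed = 3,
                           blocks = list(a = "t1", b = "t2"))
    out <- apply_missingness(tm2, sp)
    # count observations over all 10000 original species (dropped species
    # had no observation by construction)
    for (tr in c("t1", "t2")) {
      cc <- sp$completeness[tr]
      got <- sum(!is.na(out$values[, tr]))
      band <- 3 * sqrt(10000 * cc * (1 - cc))
      expect_lt(abs(got - 10000 * cc), band + 1)
    }
  }

  expect_error(missingness_spec(c(t1 = 0)), "> 0")
})

test_that("MCAR deletion is independent of trait values", {
  tm <- random_complete_tm(20000, 1, seed = 31)
  sp <- missingness_spec(c(t1 = 0.4), mechanism = "mcar", seed = 7)
  out <- apply_missingness(tm, sp)
  obs <- out$values[!is.na(out$values[, 1]), 1]
  dropped <- setdiff(rownames(tm$values), rownames(out$values))
  kept_missing <- tm$values[c(dropped,
                              rownames(out$values)[is.na(out$values[, 1])]), 1]
  se <- sqrt(var(obs) / length(obs) + var(kept_missing) / length(kept_missing))
  expect_lt(abs(mean(obs) - mean(kept_missing)), 3 * se)
})

test_that("stratified missingness boosts co-observation across blocks", {
  tm <- random_complete_tm(20000, 4, seed = 41)
  comp <- c(t1 = 0.05, t2 = 0.05, t3 = 0.05, t4 = 0.05)
  blocks <- list(a = c("t1", "t2"), b = c("t3", "t4"))
  sp_m <- missingness_spec(comp, "mcar", seed = 8, blocks = blocks)
  sp_s <- missingness_spec(comp, "stratified", seed = 8, blocks = blocks)
  ov <- function(x, i, j) sum(!is.na(x$values[, i]) & !is.na(x$values[, j]))
  om <- apply_missingness(tm, sp_m)
  os <- apply_missingness(tm, sp_s)
  # within-block and cross-block overlaps both exceed the independence level
  expect_gt(ov(os, "t1", "t2"), 2 * ov(om, "t1", "t2"))
  expect_gt(ov(os, "t1", "t3"), 2 * ov(om, "t1", "t3"))
})

test_that("species with no observed trait are dropped and counted", {
  tm <- random_complete_tm(2000, 2, seed = 51)
  sp <- missingness_spec(c(t1 = 0.05, t2 = 0.05), "mcar", seed = 9)
  out <- apply_missingness(tm, sp)
  expect_equal(nrow(out$values) + attr(out, "n_dropped"), 2000)
  expect_true(all(rowSums(!is.na(out$values)) > 0))
  expect_gt(attr(out, "n_dropped"), 0)
})

test_that("pure-birth phylogenies are valid and reproducible", {
  expect_error(simulate_phylogeny(1, seed = 1), ">= 2")

  tr2 <- simulate_phylogeny(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2L)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr2, f)
  back <- read_newick(f)
  expect_equal(sort(back$tip.label), sort(tr2$tip.label))
  expect_close(sort(back$edge.length), sort(tr2$edge.length), 1e-8)

  tr50a <- simulate_phylogeny(50, seed = 7)
  tr50b <- simulate_phylogeny(50, seed = 7)
  expect_identical(ape::write.tree(tr50a), ape::write.tree(tr50b))
  expect_equal(length(tr50a$tip.label), 50L)
  expect_true(all(tr50a$edge.length > 0))
})

test_that("Brownian-motion simulation matches its evolutionary target", {
  # star tree: tips are i.i.d. with covariance equal to the target
  st <- star_tree(2000)
  tm <- simulate_bm_traits(st, diag(4), seed = 13)
  r <- cor(tm$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.07)  # 3-sigma bound at n = 2000

  # star-tree BM is distributionally the ordinary multivariate draw:
  # matching first/second moments within Monte Carlo error
  tgt <- two_block_target(0.7)
  bm <- simulate_bm_traits(star_tree(4000), tgt, seed = 14)
  iid <- simulate_trait_matrix(tgt, 4000, seed = 15)
  expect_close(colMeans(bm$values), colMeans(iid$values), 0.1)
  expect_close(cov(bm$values), cov(iid$values), 0.1)

  # two-tip tree with disjoint branches: increments independent (r near 0)
  ch <- star_tree(2)
  vals <- t(vapply(1:400, function(s)
    simulate_bm_traits(ch, diag(1), seed = s)$values[, 1], numeric(2)))
  expect_lt(abs(cor(vals)[1, 2]), 0.15)

  # determinism
  a <- simulate_bm_traits(st, diag(2), seed = 3)
  b <- simulate_bm_traits(st, diag(2), seed = 3)
  expect_identical(a$values, b$values)
})

test_that("seed derivation is deterministic, label-sensitive and in range", {
  expect_identical(derive_seed(42, "stage"), derive_seed(42, "stage"))
  expect_false(derive_seed(42, "a") == derive_seed(42, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  s <- vapply(1:50, function(i) derive_seed(i, "x"), integer(1))
  expect_true(all(s >= 0 & s < 2^31 - 1))
})
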