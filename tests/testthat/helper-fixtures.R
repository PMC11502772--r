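# Shared fixtures for the test suite. All data is generated in code; the
# default synthetic compilation at a given (n, seed) is cached per session
# because several tests reuse it.

.fixture_cache <- new.env(parent = emptyenv())

cached_compilation <- function(n, seed, ...) {
  key <- paste0("comp_", n, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_compilation(n, seed, ...)
  .fixture_cache[[key]]
}

# small two-block correlation target used across modules
two_block_target <- function(r = 0.7) {
  build_block_correlation(list(
    block_spec("b1", c("x1", "x2"), r),
    block_spec("b2", c("y1", "y2"), r)
  ))
}

# complete random trait matrix on the standardised scale
random_complete_tm <- function(n, p, seed) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("sp", seq_len(n)),
                              paste0("t", seq_len(p))))
  trait_matrix(v, transform = "log_scaled")
}

# punch MCAR holes into a trait_matrix (plain, mechanism-free helper)
punch_mcar <- function(tm, frac, seed) {
  set.seed(seed)
  v <- tm$values
  v[matrix(runif(length(v)), nrow(v)) < frac] <- NA
  keep <- rowSums(!is.na(v)) > 0
  trait_matrix(v[keep, , drop = FALSE], transform = tm$transform)
}

# naive double-loop pairwise-complete correlation (independent oracle)
naive_pairwise_cor <- function(v) {
  p <- ncol(v)
  r <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- !is.na(v[, i]) & !is.na(v[, j])
    r[i, j] <- r[j, i] <- cor(v[ok, i], v[ok, j])
  }
  dimnames(r) <- list(colnames(v), colnames(v))
  r
}

# star tree over n tips, all depths `depth`, labels sp1..spn
star_tree <- function(n, depth = 1) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("sp%d:%g", seq_len(n), depth), collapse = ","), ");"))
}

expect_close <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
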