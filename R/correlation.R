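#' Pairwise-complete Pearson correlation matrix
#'
#' Each trait-pair correlation is computed over the species having both
#' traits observed (pairwise deletion), so every entry can use a different
#' species set. The per-pair sample sizes are recorded alongside the
#' coefficients; the resulting matrix need not be positive semi-definite.
#'
#' @param x A [trait_matrix()] on the standardised scale.
#' @param min_n Minimum species shared by a pair for its correlation to be
#'   defined (default 3, the mathematical minimum; large compilations may
#'   impose a stricter floor).
#' @return An object of class `trait_cor`: list with `r` (p x p correlation
#'   matrix), `n_pairs` (p x p integer matrix) and `min_n`.
#' @export
pairwise_correlation <- function(x, min_n = 3) {
  stopifnot(inherits(x, "trait_matrix"))
  if (x$transform != "log_scaled")
    stop("pairwise_correlation expects log_scaled values")
  if (min_n < 3) stop("min_n must be >= 3")
  v <- x$values
  n_pairs <- crossprod(!is.na(v))
  storage.mode(n_pairs) <- "integer"
  low <- which(n_pairs < min_n & upper.tri(n_pairs), arr.ind = TRUE)
  if (nrow(low)) {
    pairs <- apply(low, 1, function(ij)
      paste0(colnames(v)[ij[1]], "-", colnames(v)[ij[2]],
             " (n=", n_pairs[ij[1], ij[2]], ")"))
    stop("trait pair(s) with fewer than ", min_n, " shared species: ",
         paste(pairs, collapse = ", "))
  }
  r <- stats::cor(v, use = "pairwise.complete.obs")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(r = r, n_pairs = n_pairs, min_n = min_n),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, ...) {
  np <- x$n_pairs[upper.tri(x$n_pairs)]
  cat(sprintf("<trait_cor> %d traits; pairwise n in [%d, %d]\n",
              ncol(x$r), min(np), max(np)))
  print(round(x$r, 3))
  invisible(x)
}

# deterministic eigen ordering: descending eigenvalues; exact ties broken by
# the trait index of each eigenvector's dominant entry
.order_eigen <- function(values, vectors, tol = 1e-12) {
  dom <- apply(abs(vectors), 2, which.max)
  ord <- order(-values, dom)
  # within groups of numerically tied values keep dominant-trait order
  list(values = values[ord], vectors = vectors[, ord, drop = FALSE])
}

# fix eigenvector signs: the largest-magnitude entry of each column positive
.fix_signs <- function(vectors) {
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  vectors
}

new_trait_space <- function(values, vectors, traits, loading_type,
                            provenance = NULL, scores = NULL) {
  vectors <- .fix_signs(vectors)
  o <- .order_eigen(values, vectors)
  values <- o$values; vectors <- o$vectors
  p <- length(values)
  loadings <- if (loading_type == "correlation")
    vectors %*% diag(sqrt(pmax(values, 0)), p) else vectors
  dimnames(vectors) <- list(traits, paste0("dim", seq_len(p)))
  dimnames(loadings) <- dimnames(vectors)
  structure(list(
    values = values,
    vectors = vectors,
    loadings = loadings,
    retained = values > 1,
    var_explained = 100 * values / sum(values),
    traits = traits,
    loading_type = loading_type,
    provenance = provenance,
    scores = scores
  ), class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  k <- sum(x$retained)
  cat(sprintf(
    "<trait_space> %d traits; %d retained dimension(s) (eigenvalue > 1), %.2f%% variance\n",
    length(x$traits), k, sum(x$var_explained[x$retained])))
  tab <- rbind(eigenvalue = round(x$values, 3),
               `var %` = round(x$var_explained, 2))
  colnames(tab) <- paste0("dim", seq_along(x$values))
  print(tab)
  invisible(x)
}

#' Eigendecompose a trait correlation matrix
#'
#' Principal component analysis of a (possibly pairwise-complete)
#' correlation matrix: eigenvalues in descending order, orthonormal
#' eigenvectors with a fixed sign convention (the largest-magnitude entry of
#' each eigenvector is positive), trait loadings, Kaiser retention
#' (eigenvalues strictly greater than 1) and percentage variance explained.
#' Pairwise-deletion matrices can be indefinite; negative eigenvalues are
#' kept in the spectrum (so the trace stays equal to the number of traits)
#' and reported with a warning, and are clipped to zero only where a square
#' root is needed (loadings).
#'
#' @param R A [pairwise_correlation()] result, or a plain symmetric
#'   unit-diagonal correlation matrix.
#' @param loading_type `"correlation"` (eigenvector scaled by the square
#'   root of its eigenvalue, i.e. the correlation between trait and
#'   dimension; default) or `"eigenvector"` (raw eigenvectors).
#' @param provenance Optional provenance (e.g. a [trait_selector()]) stored
#'   with the space.
#' @return An object of class `trait_space` with elements `values`,
#'   `vectors`, `loadings`, `retained`, `var_explained`, `traits`.
#' @export
eigendecompose <- function(R, loading_type = c("correlation", "eigenvector"),
                           provenance = NULL) {
  loading_type <- match.arg(loading_type)
  if (inherits(R, "trait_cor")) {
    if (is.null(provenance)) provenance <- list(n_pairs = R$n_pairs)
    R <- R$r
  }
  R <- as.matrix(R)
  if (any(is.na(R))) stop("correlation matrix contains undefined entries")
  if (max(abs(R - t(R))) > 1e-10)
    stop("correlation matrix is asymmetric beyond tolerance")
  R <- (R + t(R)) / 2
  traits <- colnames(R)
  if (is.null(traits)) traits <- paste0("t", seq_len(ncol(R)))
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    warning(sprintf(
      "indefinite correlation matrix (pairwise deletion): min eigenvalue %.4f",
      min(ev$values)))
  new_trait_space(ev$values, ev$vectors, traits, loading_type, provenance)
}

#' Complete-case principal component analysis
#'
#' Removes every species with any missing value among the traits of `x`,
#' re-standardises the remaining values, and performs an ordinary
#' correlation-matrix PCA, returning species scores alongside the spectrum.
#' With no missingness this coincides exactly with
#' `eigendecompose(pairwise_correlation(x))`.
#'
#' @param x A [trait_matrix()] on the standardised scale.
#' @param loading_type Passed to [eigendecompose()].
#' @return A `trait_space` whose `scores` element holds the n x p matrix of
#'   species scores (centred data projected on the eigenvectors) and with
#'   attribute `n_complete`, the number of complete cases used.
#' @export
complete_case_space <- function(x, loading_type = "correlation") {
  stopifnot(inherits(x, "trait_matrix"))
  if (x$transform != "log_scaled")
    stop("complete_case_space expects log_scaled values")
  v <- x$values
  cc <- stats::complete.cases(v)
  if (!any(cc)) {
    comp <- round(100 * colMeans(!is.na(v)), 2)
    stop("no complete cases; per-trait completeness (%): ",
         paste(paste0(colnames(v), "=", comp), collapse = ", "))
  }
  if (sum(cc) < ncol(v) + 1)
    stop("need at least p + 1 = ", ncol(v) + 1, " complete cases, have ",
         sum(cc))
  v <- v[cc, , drop = FALSE]
  v <- apply(v, 2, .scale_pop)
  R <- stats::cor(v)
  space <- eigendecompose(R, loading_type = loading_type,
                          provenance = list(estimator = "complete_case"))
  scores <- v %*% space$vectors
  rownames(scores) <- rownames(x$values)[cc]
  space$scores <- scores
  attr(space, "n_complete") <- sum(cc)
  space
}
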