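#' Read a phylogeny from a Newick file
#'
#' Thin validated wrapper around [ape::read.tree()]: the tree must parse,
#' be rooted or rootable, and have uniquely labelled tips with non-negative
#' branch lengths.
#'
#' @param path Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (is.null(tree$tip.label) || any(tree$tip.label == ""))
    stop("tree has unlabelled tip(s)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length(s)")
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Phylogenetic variance-covariance matrix under Brownian motion
#'
#' `C[i, j]` is the total branch length shared by the root-to-tip paths of
#' tips i and j (their common evolutionary history); `C[i, i]` is the depth
#' of tip i. Under Brownian motion this is the covariance of tip values up
#' to the rate constant. Ultrametricity is not required.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric PSD matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv.phylo(tree)
  if (any(diag(C) <= 0))
    stop("zero-depth tip(s): ",
         paste(rownames(C)[diag(C) <= 0], collapse = ", "))
  C
}

#' Phylogenetically-informed principal component analysis
#'
#' PCA of the evolutionary (Brownian-motion-weighted) trait covariance on
#' complete-case data: with phylogenetic covariance C, the generalised
#' least-squares ancestral mean is `a = (1' C^-1 1)^-1 1' C^-1 X`, the
#' evolutionary covariance `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`, and the
#' space is the eigendecomposition of R (covariance mode) or of its
#' correlation rescaling (default). Species scores are `(X - 1a) V`. On a
#' star tree with equal depths C is proportional to the identity and the
#' result coincides with ordinary PCA. Kaiser retention, variance explained
#' and END apply to the resulting spectrum exactly as in the
#' non-phylogenetic path.
#'
#' @param x A complete (no missing values among its traits after
#'   complete-case filtering) [trait_matrix()] on the standardised scale;
#'   rows with any missing value are dropped.
#' @param tree A `phylo` object; species are matched to tips by label and
#'   the intersection is used (a message reports any mismatch).
#' @param mode `"correlation"` (default, comparable with the
#'   correlation-based spaces) or `"covariance"`.
#' @param loading_type Passed to [eigendecompose()]'s convention.
#' @return A `trait_space` with `scores` (GLS-centred projections) and
#'   extra elements `evolutionary_cov` and `gls_mean`.
#' @export
phylogenetic_pca <- function(x, tree, mode = c("correlation", "covariance"),
                             loading_type = "correlation") {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "trait_matrix"), inherits(tree, "phylo"))
  if (x$transform != "log_scaled")
    stop("phylogenetic_pca expects log_scaled values")
  v <- x$values[stats::complete.cases(x$values), , drop = FALSE]
  shared <- intersect(rownames(v), tree$tip.label)
  if (!length(shared)) stop("species ids and tip labels are disjoint")
  if (length(shared) < nrow(v) || length(shared) < length(tree$tip.label))
    message("matching species to tips: ", length(shared), " shared, ",
            nrow(v) - length(shared), " species and ",
            length(tree$tip.label) - length(shared), " tips dropped")
  if (length(shared) <= ncol(v))
    stop("need more species than traits after matching")
  tree <- ape::keep.tip(tree, shared)
  C <- phylo_vcv(tree)
  v <- v[rownames(C), , drop = FALSE]
  n <- nrow(v); p <- ncol(v)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance: ", conditionMessage(e)))
  one <- rep(1, n)
  a <- drop(crossprod(one, Cinv %*% v)) / drop(crossprod(one, Cinv %*% one))
  Xc <- sweep(v, 2, a)
  R_evol <- crossprod(Xc, Cinv %*% Xc) / (n - 1)
  R_evol <- (R_evol + t(R_evol)) / 2
  M <- if (mode == "correlation") stats::cov2cor(R_evol) else R_evol
  traits <- colnames(v)
  ev <- eigen(M, symmetric = TRUE)
  space <- new_trait_space(ev$values, ev$vectors, traits, loading_type,
                           provenance = list(estimator = "phylogenetic",
                                             mode = mode, n = n))
  space$scores <- Xc %*% space$vectors
  space$evolutionary_cov <- R_evol
  space$gls_mean <- a
  space
}
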