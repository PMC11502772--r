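#' Effective number of dimensions of a trait space
#'
#' The inverse Simpson diversity of the eigenvalue spectrum: with relative
#' eigenvalues p_i = lambda_i / sum(lambda), END = 1 / sum(p_i^2). END is a
#' continuous dimensionality measure ranging from 1 (all traits perfectly
#' correlated, rank-1 spectrum) to p (all traits independent, flat
#' spectrum). Negative eigenvalues (possible under pairwise deletion) are
#' clipped to zero by default before forming the relative spectrum; the
#' clipped mass is reported.
#'
#' @param x A `trait_space`, a `trait_cor`, or a numeric eigenvalue
#'   spectrum.
#' @param clip Clip negative eigenvalues to zero (default `TRUE`); with
#'   `clip = FALSE` the raw spectrum is used as-is.
#' @return An object of class `end_result`: list with `end`,
#'   `clipped_negative_mass` and `p` (number of eigenvalues).
#' @examples
#' effective_dimensions(c(2, 1, 1))   # 8/3
#' @export
effective_dimensions <- function(x, clip = TRUE) {
  lambda <- if (inherits(x, "trait_space")) x$values
    else if (inherits(x, "trait_cor")) eigendecompose(x)$values
    else as.numeric(x)
  if (!any(lambda > 0)) stop("spectrum has no positive eigenvalue")
  clipped <- 0
  if (clip) {
    clipped <- sum(abs(lambda[lambda < 0]))
    lambda <- pmax(lambda, 0)
  }
  pr <- lambda / sum(lambda)
  end <- 1 / sum(pr^2)
  structure(list(end = end, clipped_negative_mass = clipped,
                 p = length(lambda)), class = "end_result")
}

#' @export
print.end_result <- function(x, ...) {
  cat(sprintf("<end_result> END = %.4f of %d traits", x$end, x$p))
  if (x$clipped_negative_mass > 0)
    cat(sprintf(" (clipped negative eigenvalue mass %.4f)",
                x$clipped_negative_mass))
  cat("\n")
  invisible(x)
}

#' Uncorrelated-trait null model for dimensionality change
#'
#' Reference distribution for the END change expected when one genuinely
#' uncorrelated trait is added to a space: each replicate appends a column
#' of standard-normal values (observed for every species by default),
#' rebuilds the pairwise-complete correlation matrix, eigendecomposes it and
#' records END. The mean of the null distribution serves as the yardstick
#' against which observed END changes are expressed (see
#' [proportional_increase()]).
#'
#' @param x A [trait_matrix()] on the standardised scale.
#' @param reps Number of replicates (default 500).
#' @param seed Integer seed; the full distribution is reproducible.
#' @param min_n Passed to [pairwise_correlation()].
#' @param completeness Optional fraction in (0, 1]: observe the simulated
#'   trait for only this share of species instead of all of them (matching
#'   realistic trait coverage); default `NULL` = complete column.
#' @param clip Negative-eigenvalue handling as in [effective_dimensions()].
#' @return An object of class `end_null`: list with `end_samples`,
#'   `end_random_mean`, `mc_se` (Monte Carlo standard error of the mean),
#'   `base_end`, `reps`, `seed`.
#' @export
null_uncorrelated_end <- function(x, reps = 500, seed = 1, min_n = 3,
                                  completeness = NULL, clip = TRUE) {
  stopifnot(inherits(x, "trait_matrix"), reps >= 1)
  base_end <- effective_dimensions(
    eigendecompose(pairwise_correlation(x, min_n = min_n))$values,
    clip = clip)$end
  n <- nrow(x$values)
  set.seed(as.integer(seed))
  samples <- vapply(seq_len(reps), function(i) {
    z <- stats::rnorm(n)
    if (!is.null(completeness)) {
      stopifnot(completeness > 0, completeness <= 1)
      z[stats::runif(n) > completeness] <- NA
    }
    v <- cbind(x$values, .rand_trait = z)
    aug <- trait_matrix(v, transform = "log_scaled")
    lam <- eigendecompose(pairwise_correlation(aug, min_n = min_n))$values
    effective_dimensions(lam, clip = clip)$end
  }, numeric(1))
  structure(list(end_samples = samples,
                 end_random_mean = mean(samples),
                 mc_se = stats::sd(samples) / sqrt(reps),
                 base_end = base_end, reps = reps,
                 seed = as.integer(seed)),
            class = "end_null")
}

#' @export
print.end_null <- function(x, ...) {
  cat(sprintf(
    "<end_null> base END = %.4f; null mean = %.4f (MC SE %.4f, %d reps, seed %d)\n",
    x$base_end, x$end_random_mean, x$mc_se, x$reps, x$seed))
  invisible(x)
}

#' Proportional dimensionality increase
#'
#' Expresses an observed END change against the change expected from adding
#' one uncorrelated trait: 100 * (augmented - base) / (null mean - base).
#' Values near 0 mean the added traits brought no new dimension; values near
#' 100 mean they behaved like an uncorrelated trait; values can exceed 100
#' (more than one effective new dimension) or be negative (the additions
#' made the spectrum more concentrated).
#'
#' @param base_end END of the space without the added traits.
#' @param augmented_end END of the space with them.
#' @param end_random_mean Mean null END (see [null_uncorrelated_end()]).
#' @return Percentage (numeric scalar).
#' @examples
#' proportional_increase(5.0, 5.5, 6.0)  # 50
#' @export
proportional_increase <- function(base_end, augmented_end, end_random_mean) {
  denom <- end_random_mean - base_end
  if (denom == 0) stop("null mean equals base END: reference change is zero")
  100 * (augmented_end - base_end) / denom
}
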