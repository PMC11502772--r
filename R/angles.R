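#' Angle between two trait loading vectors
#'
#' Converts the association between two traits' loading vectors (their
#' loadings across the retained dimensions of a reduced space) into an angle
#' in degrees: an association of +1 maps to 0 degrees (common direction), 0
#' to 90 degrees (independence) and -1 to 180 degrees (trade-off). The
#' association is either the Pearson correlation of the two vectors
#' (default) or their uncentred cosine similarity; the two differ because
#' loading vectors are not centred.
#'
#' @param u,v Numeric loading vectors of equal length (length >= 2 for
#'   `"pearson"`, >= 1 for `"cosine"`).
#' @param method `"pearson"` or `"cosine"`.
#' @return Angle in degrees in [0, 180].
#' @export
loading_angle <- function(u, v, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  stopifnot(length(u) == length(v))
  if (all(u == 0) || all(v == 0)) stop("all-zero loading vector")
  if (method == "pearson") {
    if (length(u) < 2)
      stop("pearson angle needs loading vectors of length >= 2")
    if (stats::sd(u) == 0 || stats::sd(v) == 0)
      stop("zero-variance loading vector: pearson angle undefined")
    cc <- stats::cor(u, v)
  } else {
    cc <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  # snap floating-point residue at the boundaries so identical (opposite)
  # vectors map to exactly 0 (180) degrees
  if (cc > 1 - 1e-12) cc <- 1
  if (cc < -1 + 1e-12) cc <- -1
  acos(cc) * 180 / pi
}

#' Pairwise trait angles in a reduced space
#'
#' Computes [loading_angle()] for every trait pair, using each trait's
#' loadings over the retained dimensions only (the reduced space).
#'
#' @param space A `trait_space` (see [eigendecompose()]).
#' @param method `"pearson"` (default) or `"cosine"`.
#' @param dims Which dimensions to use: `"retained"` (default) or `"all"`.
#' @return An object of class `angle_table`: a symmetric p x p matrix of
#'   angles in degrees with zero diagonal and attributes `method` and
#'   `space_id`.
#' @export
angle_table <- function(space, method = c("pearson", "cosine"),
                        dims = c("retained", "all")) {
  method <- match.arg(method)
  dims <- match.arg(dims)
  stopifnot(inherits(space, "trait_space"))
  keep <- if (dims == "retained") space$retained else
    rep(TRUE, length(space$values))
  k <- sum(keep)
  need <- if (method == "pearson") 2L else 1L
  if (k < need)
    stop("angle_table needs >= ", need, " retained dimension(s) for the ",
         method, " method, space has ", k)
  L <- space$loadings[, keep, drop = FALSE]
  p <- nrow(L)
  A <- matrix(0, p, p, dimnames = list(space$traits, space$traits))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    A[i, j] <- A[j, i] <- loading_angle(L[i, ], L[j, ], method = method)
  }
  sid <- if (inherits(space$provenance, "trait_selector"))
    selector_id(space$provenance) else NA_character_
  structure(A, class = c("angle_table", "matrix"), method = method,
            space_id = sid)
}

#' @export
print.angle_table <- function(x, ...) {
  cat(sprintf("<angle_table> %d traits, method = %s\n", nrow(x),
              attr(x, "method")))
  print(round(unclass(x), 1))
  invisible(x)
}

#' Long-format serialisation of an angle table
#'
#' @param x An [angle_table()].
#' @param ... Unused.
#' @return data.frame with columns `trait_a`, `trait_b`, `angle_deg`
#'   (rounded to 2 decimals), `method`, `space_id`; one row per unordered
#'   trait pair.
#' @export
as.data.frame.angle_table <- function(x, ...) {
  tr <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  data.frame(trait_a = tr[idx[, 1]], trait_b = tr[idx[, 2]],
             angle_deg = round(x[idx], 2),
             method = attr(x, "method"),
             space_id = attr(x, "space_id"),
             stringsAsFactors = FALSE)
}

#' Compare the angle structure of two reduced spaces
#'
#' Correlates the pairwise trait angles of two spaces over the traits
#' present in both: the upper-triangle angles of the shared traits are
#' paired by trait labels and their Pearson correlation and two-sided
#' p-value (t distribution, k - 2 degrees of freedom over k angle pairs)
#' returned. A correlation near 1 means the two spaces encode the same
#' trait-relationship structure.
#'
#' @param a,b [angle_table()] objects built with the same method.
#' @return List with `r`, `p_value`, `n_pairs` (number of angle pairs) and
#'   `shared_traits`.
#' @export
compare_angle_tables <- function(a, b) {
  stopifnot(inherits(a, "angle_table"), inherits(b, "angle_table"))
  if (!identical(attr(a, "method"), attr(b, "method")))
    stop("angle tables built with different methods cannot be compared")
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 3)
    stop("need >= 3 shared traits, have ", length(shared))
  A <- a[shared, shared]; B <- b[shared, shared]
  ut <- upper.tri(A)
  ct <- stats::cor.test(A[ut], B[ut], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = sum(ut), shared_traits = shared)
}
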