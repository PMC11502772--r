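#' Construct a species-by-trait matrix
#'
#' The central data container: a numeric matrix with species as rows and
#' traits as columns, missing values allowed, plus a transform state and an
#' optional per-species woodiness classification.
#'
#' @param values Numeric matrix (or data.frame) with unique species row names
#'   and trait column names.
#' @param transform Transform state of the values: `"raw"` (original units,
#'   all observed values strictly positive), `"log"` (log10) or
#'   `"log_scaled"` (log10 then centred and scaled per trait).
#' @param woodiness Optional character vector (one per species, named or in
#'   row order) with values in `"woody"`, `"herbaceous"`, `"unknown"`.
#' @return An object of class `trait_matrix`: a list with elements `values`,
#'   `transform`, `woodiness`.
#' @export
trait_matrix <- function(values, transform = c("raw", "log", "log_scaled"),
                         woodiness = NULL) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sp", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("trait columns must be named")
  dup <- duplicated(rownames(values))
  if (any(dup))
    stop("duplicate species id(s): ",
         paste(unique(rownames(values)[dup]), collapse = ", "))
  if (transform == "raw") {
    bad <- values <= 0 & !is.na(values)
    if (any(bad))
      stop("raw-scale trait values must be strictly positive (",
           sum(bad), " violation(s))")
  }
  if (!is.null(woodiness)) {
    if (is.null(names(woodiness))) {
      stopifnot(length(woodiness) == nrow(values))
      names(woodiness) <- rownames(values)
    }
    woodiness <- woodiness[rownames(values)]
    ok <- woodiness %in% c("woody", "herbaceous", "unknown") | is.na(woodiness)
    if (!all(ok)) stop("woodiness must be 'woody', 'herbaceous' or 'unknown'")
    woodiness[is.na(woodiness)] <- "unknown"
  }
  structure(list(values = values, transform = transform, woodiness = woodiness),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  v <- x$values
  obs <- colMeans(!is.na(v))
  cat(sprintf("<trait_matrix> %d species x %d traits [%s scale]%s\n",
              nrow(v), ncol(v), x$transform,
              if (is.null(x$woodiness)) "" else ", woodiness present"))
  cat(sprintf("  completeness: %.1f%%-%.1f%% per trait (overall %.1f%%)\n",
              100 * min(obs), 100 * max(obs), 100 * mean(!is.na(v))))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Read a species-by-trait table from CSV
#'
#' Expects a header row with a `species_id` column, an optional `woodiness`
#' column, and one column per trait. Empty cells and literal `NA` are both
#' read as missing.
#'
#' @param path Path to a CSV file.
#' @param transform Transform state the stored values are on (default
#'   `"raw"`).
#' @param registry Character vector of recognised trait labels; defaults to
#'   the twelve-trait registry. Columns outside the registry are dropped with
#'   a warning, or rejected when `unknown = "error"`.
#' @param unknown How to treat unknown trait columns: `"warn"` or `"error"`.
#' @return A [trait_matrix()].
#' @export
load_trait_table <- function(path, transform = "raw",
                             registry = trait_registry()$trait,
                             unknown = c("warn", "error")) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (!"species_id" %in% names(df))
    stop("CSV must contain a 'species_id' column")
  dup <- duplicated(df$species_id)
  if (any(dup))
    stop("duplicate species id(s) in ", path, ": ",
         paste(unique(df$species_id[dup]), collapse = ", "))
  woodiness <- NULL
  if ("woodiness" %in% names(df)) {
    woodiness <- as.character(df$woodiness)
    names(woodiness) <- df$species_id
  }
  trait_cols <- setdiff(names(df), c("species_id", "woodiness"))
  unk <- setdiff(trait_cols, registry)
  if (length(unk)) {
    msg <- paste("unknown trait column(s):", paste(unk, collapse = ", "))
    if (unknown == "error") stop(msg)
    warning(msg, "; dropped")
    trait_cols <- intersect(trait_cols, registry)
  }
  if (!length(trait_cols)) stop("no trait columns found")
  values <- as.matrix(df[trait_cols])
  rownames(values) <- df$species_id
  trait_matrix(values, transform = transform, woodiness = woodiness)
}

#' Write a species-by-trait table to CSV
#'
#' Inverse of [load_trait_table()]: columns `species_id`, `woodiness` (when
#' present), then one column per trait; missing values written as `NA`.
#'
#' @param x A [trait_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_matrix"))
  df <- data.frame(species_id = rownames(x$values), stringsAsFactors = FALSE)
  if (!is.null(x$woodiness)) df$woodiness <- unname(x$woodiness)
  # 17 significant digits so numeric values round-trip exactly through text
  num <- as.data.frame(x$values, optional = TRUE)
  for (j in seq_along(num)) {
    s <- formatC(num[[j]], digits = 17, format = "g")
    s[is.na(num[[j]])] <- "NA"
    num[[j]] <- s
  }
  df <- cbind(df, num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# centre and scale a column over its observed entries, population-SD
# convention (sqrt(n) denominator); correlations are invariant to the choice,
# it is fixed only so transformed values are deterministic.
.scale_pop <- function(v) {
  obs <- !is.na(v)
  m <- mean(v[obs])
  s <- sqrt(mean((v[obs] - m)^2))
  if (s == 0) stop("zero-variance trait column cannot be scaled")
  (v - m) / s
}

#' Log-transform and standardise trait values
#'
#' Replaces every observed value by its log10, then centres and scales each
#' trait over its observed entries (population-SD convention). Non-positive
#' raw values cannot be log-transformed and are set to missing with a
#' warning. Any fixed log base gives identical correlations downstream; base
#' 10 is used for readability of transformed values.
#'
#' @param x A raw-scale [trait_matrix()].
#' @return A `trait_matrix` with `transform = "log_scaled"`.
#' @export
log_scale_transform <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  if (x$transform != "raw")
    stop("log_scale_transform expects raw-scale values, got '",
         x$transform, "'")
  v <- x$values
  bad <- !is.na(v) & v <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive value(s) set to missing before log")
    v[bad] <- NA
  }
  v <- log10(v)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 2))
    stop("trait(s) with < 2 observed values cannot be scaled: ",
         paste(colnames(v)[n_obs < 2], collapse = ", "))
  v <- apply(v, 2, .scale_pop)
  rownames(v) <- rownames(x$values)
  trait_matrix(v, transform = "log_scaled", woodiness = x$woodiness)
}

#' Mask outliers on the standardised scale
#'
#' Sets observed entries with |z| above the threshold to missing, per trait,
#' then re-standardises and repeats until no entry is removed (masking is
#' then idempotent at the given threshold), up to `max_iter` passes.
#'
#' @param x A `trait_matrix` on the `log_scaled` scale.
#' @param z_threshold Positive threshold on the absolute standardised value
#'   (default 4).
#' @param max_iter Maximum mask/re-scale passes (default 10).
#' @return A `trait_matrix` with attribute `n_masked`, a per-trait count of
#'   removed entries.
#' @export
mask_outliers <- function(x, z_threshold = 4, max_iter = 10) {
  stopifnot(inherits(x, "trait_matrix"))
  if (x$transform != "log_scaled")
    stop("mask_outliers expects log_scaled values")
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stop("z_threshold must be positive")
  v <- x$values
  n_masked <- integer(ncol(v))
  names(n_masked) <- colnames(v)
  for (i in seq_len(max_iter)) {
    out <- !is.na(v) & abs(v) > z_threshold
    if (!any(out)) break
    n_masked <- n_masked + colSums(out)
    v[out] <- NA
    v <- apply(v, 2, .scale_pop)
  }
  rownames(v) <- rownames(x$values)
  res <- trait_matrix(v, transform = "log_scaled", woodiness = x$woodiness)
  attr(res, "n_masked") <- n_masked
  res
}

#' Subset a trait matrix by trait set and growth form
#'
#' Restricts columns to the traits of a [trait_selector()] (base set plus
#' root-size inclusion) and rows to its growth-form group, then drops species
#' with no observed trait left. Retained columns keep their values as-is; on
#' the standardised scale correlations are unaffected by subsetting, only the
#' per-column mean/SD invariant may loosen (re-apply scaling if exact
#' standardisation is needed).
#'
#' @param x A [trait_matrix()].
#' @param selector A [trait_selector()].
#' @param rescale Re-standardise retained columns over the retained rows
#'   (default `TRUE` for `log_scaled` input).
#' @param warn_min_pairs Warn when some retained trait pair shares fewer than
#'   this many species (default 3, the minimum for a defined correlation).
#' @return A `trait_matrix` restricted to the selection, with attribute
#'   `n_dropped` (species removed because no observed trait remained).
#' @export
subset_traits <- function(x, selector, rescale = x$transform == "log_scaled",
                          warn_min_pairs = 3) {
  stopifnot(inherits(x, "trait_matrix"), inherits(selector, "trait_selector"))
  traits <- selector_traits(selector)
  missing_tr <- setdiff(traits, colnames(x$values))
  if (length(missing_tr))
    stop("selected trait(s) absent from table: ",
         paste(missing_tr, collapse = ", "))
  keep_rows <- rep(TRUE, nrow(x$values))
  if (selector$group != "all") {
    if (is.null(x$woodiness))
      stop("group='", selector$group, "' requires a woodiness classification")
    keep_rows <- x$woodiness == selector$group & !is.na(x$woodiness)
  }
  v <- x$values[keep_rows, traits, drop = FALSE]
  has_obs <- rowSums(!is.na(v)) > 0
  n_dropped <- sum(!has_obs)
  v <- v[has_obs, , drop = FALSE]
  if (rescale && nrow(v) > 1) {
    rn <- rownames(v)
    v <- apply(v, 2, .scale_pop)
    rownames(v) <- rn
  }
  np <- crossprod(!is.na(v))
  if (any(np[upper.tri(np)] < warn_min_pairs))
    warning("some trait pair(s) share fewer than ", warn_min_pairs,
            " species; pairwise correlations will be undefined")
  w <- if (is.null(x$woodiness)) NULL else x$woodiness[rownames(v)]
  res <- trait_matrix(v, transform = x$transform, woodiness = w)
  res$provenance <- selector
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Average duplicate species records
#'
#' Utility for tables holding several records per species: returns the
#' per-species mean of each trait over observed records. Taxonomic name
#' matching is out of scope; species are grouped by exact id.
#'
#' @param df A data.frame with a `species_id` column and numeric trait
#'   columns.
#' @return A data.frame with one row per species.
#' @export
species_means <- function(df) {
  stopifnot("species_id" %in% names(df))
  trait_cols <- setdiff(names(df), c("species_id", "woodiness"))
  agg <- stats::aggregate(df[trait_cols], by = list(species_id = df$species_id),
                          FUN = function(v) {
                            v <- v[!is.na(v)]
                            if (length(v)) mean(v) else NA_real_
                          })
  agg[order(agg$species_id), , drop = FALSE]
}
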