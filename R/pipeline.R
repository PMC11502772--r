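#' Run the full trait-space study grid
#'
#' Orchestrates the whole design: for each growth-form group and estimator,
#' the three base trait sets (UPFS, GSPFF, RES) crossed with the four
#' root-size inclusion levels (none, Dr, Lr, Dr+Lr) give twelve spaces. For
#' every space the function builds the correlation matrix, eigendecomposes
#' it, extracts retained dimensions, loadings, the angle table, END, and the
#' uncorrelated-trait null distribution. Spaces whose trait subset fails a
#' precondition (e.g. insufficient pairwise overlap in a sparse stratum) are
#' recorded as failed with the reason and the run continues.
#'
#' @param x A [trait_matrix()] on the standardised scale holding the twelve
#'   registry traits.
#' @param tree Optional `phylo` object, required for the `"phylogenetic"`
#'   estimator.
#' @param estimator `"pairwise"` (pairwise-complete correlations, default),
#'   `"complete_case"`, or `"phylogenetic"` (complete cases, Brownian
#'   motion).
#' @param groups Growth-form groups to analyse (subset of `"all"`,
#'   `"woody"`, `"herbaceous"`).
#' @param base_sets Base trait sets (default all three).
#' @param inclusions Root-size inclusion levels (default all four).
#' @param reps Null-model replicates per space (default 500).
#' @param seed Global seed; per-space null seeds are derived from it with
#'   [derive_seed()] and recorded in each record.
#' @param min_n Minimum pairwise overlap (see [pairwise_correlation()]).
#' @param angle_method Angle method (see [angle_table()]).
#' @return An object of class `result_bundle`: list of per-space records
#'   (each with `space_id`, `selector`, `space`, `angles`, `end`, `null`,
#'   `error`) plus the run `config`.
#' @export
run_space_suite <- function(x, tree = NULL,
                            estimator = c("pairwise", "complete_case",
                                          "phylogenetic"),
                            groups = "all",
                            base_sets = c("UPFS", "GSPFF", "RES"),
                            inclusions = c("none", "Dr", "Lr", "Dr+Lr"),
                            reps = 500, seed = 1, min_n = 3,
                            angle_method = "pearson") {
  estimator <- match.arg(estimator)
  stopifnot(inherits(x, "trait_matrix"))
  if (estimator == "phylogenetic" && is.null(tree))
    stop("the phylogenetic estimator requires a tree")
  records <- list()
  for (group in groups) for (bs in base_sets) for (inc in inclusions) {
    sel <- trait_selector(bs, inc, group)
    sid <- paste(selector_id(sel), estimator, sep = "_")
    null_seed <- derive_seed(seed, sid)
    rec <- tryCatch({
      sub <- suppressWarnings(subset_traits(x, sel))
      space <- switch(estimator,
        pairwise = eigendecompose(
          suppressWarnings(pairwise_correlation(sub, min_n = min_n)),
          provenance = sel),
        complete_case = complete_case_space(sub),
        phylogenetic = phylogenetic_pca(sub, tree))
      if (estimator != "pairwise") space$provenance <- sel
      ang <- tryCatch(angle_table(space, method = angle_method),
                      error = function(e) NULL)
      end <- effective_dimensions(space$values)
      nul <- if (estimator == "pairwise")
        null_uncorrelated_end(sub, reps = reps, seed = null_seed,
                              min_n = min_n)
      else .null_end_complete(space, sub, estimator, tree, reps, null_seed)
      n_used <- if (!is.null(space$scores)) nrow(space$scores)
                else nrow(sub$values)
      list(space_id = sid, selector = sel, estimator = estimator,
           n_species = n_used, space = space, angles = ang,
           end = end, null = nul, null_seed = null_seed, error = NULL)
    }, error = function(e) {
      list(space_id = sid, selector = sel, estimator = estimator,
           space = NULL, angles = NULL, end = NULL, null = NULL,
           null_seed = null_seed, error = conditionMessage(e))
    })
    records[[sid]] <- rec
  }
  structure(list(records = records,
                 config = list(estimator = estimator, groups = groups,
                               base_sets = base_sets,
                               inclusions = inclusions, reps = reps,
                               seed = seed, min_n = min_n,
                               angle_method = angle_method)),
            class = "result_bundle")
}

# null model for complete-case / phylogenetic estimators: append a complete
# standard-normal column to the complete cases and redo the decomposition
.null_end_complete <- function(space, sub, estimator, tree, reps, seed) {
  v <- sub$values[stats::complete.cases(sub$values), , drop = FALSE]
  base_end <- effective_dimensions(space$values)$end
  set.seed(as.integer(seed))
  samples <- vapply(seq_len(reps), function(i) {
    aug <- trait_matrix(cbind(v, .rand_trait = stats::rnorm(nrow(v))),
                        transform = "log_scaled")
    sp <- if (estimator == "phylogenetic")
      phylogenetic_pca(aug, tree) else complete_case_space(aug)
    effective_dimensions(sp$values)$end
  }, numeric(1))
  structure(list(end_samples = samples, end_random_mean = mean(samples),
                 mc_se = stats::sd(samples) / max(1, sqrt(reps)),
                 base_end = base_end, reps = reps, seed = as.integer(seed)),
            class = "end_null")
}

#' @export
print.result_bundle <- function(x, ...) {
  ok <- vapply(x$records, function(r) is.null(r$error), TRUE)
  cat(sprintf("<result_bundle> %d spaces (%d ok, %d failed), estimator = %s\n",
              length(x$records), sum(ok), sum(!ok), x$config$estimator))
  for (r in x$records[!ok])
    cat("  failed:", r$space_id, "-", r$error, "\n")
  invisible(x)
}

#' Eigenvalue summary table of a result bundle
#'
#' @param bundle A [run_space_suite()] result.
#' @return data.frame with one row per space: retained-dimension count,
#'   variance explained by the retained dimensions, END, null END mean and
#'   proportional increase versus the no-root-size base space of the same
#'   set and group.
#' @export
bundle_summary <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  rows <- lapply(bundle$records, function(r) {
    if (!is.null(r$error))
      return(data.frame(space_id = r$space_id,
                        base_set = r$selector$base_set,
                        inclusion = r$selector$root_size,
                        group = r$selector$group, n_species = NA,
                        retained = NA, var_retained_pct = NA, end = NA,
                        end_random_mean = NA, error = r$error))
    data.frame(space_id = r$space_id, base_set = r$selector$base_set,
               inclusion = r$selector$root_size, group = r$selector$group,
               n_species = r$n_species, retained = sum(r$space$retained),
               var_retained_pct =
                 round(sum(r$space$var_explained[r$space$retained]), 2),
               end = round(r$end$end, 4),
               end_random_mean = round(r$null$end_random_mean, 4),
               error = NA_character_)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Proportional dimensionality increases across the grid
#'
#' For every (base set, group) with a root-size-free base space, expresses
#' the END of each root-size-including space as a percentage of the null
#' reference change (see [proportional_increase()]), using the base space's
#' own uncorrelated-trait null mean.
#'
#' @param bundle A [run_space_suite()] result.
#' @return data.frame with one row per (base set, inclusion != none, group).
#' @export
summarize_proportional_increases <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  recs <- Filter(function(r) is.null(r$error), bundle$records)
  rows <- list()
  for (r in recs) {
    if (r$selector$root_size == "none") next
    base_sel <- trait_selector(r$selector$base_set, "none", r$selector$group)
    base_id <- paste(selector_id(base_sel), r$estimator, sep = "_")
    base <- bundle$records[[base_id]]
    if (is.null(base)) stop("missing base space for ", r$space_id)
    if (!is.null(base$error)) next
    rows[[r$space_id]] <- data.frame(
      base_set = r$selector$base_set, inclusion = r$selector$root_size,
      group = r$selector$group,
      base_end = round(base$end$end, 4),
      augmented_end = round(r$end$end, 4),
      end_random_mean = round(base$null$end_random_mean, 4),
      prop_increase_pct = round(proportional_increase(
        base$end$end, r$end$end, base$null$end_random_mean), 2))
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Angle-structure comparisons across inclusion levels
#'
#' Reproduces the cross-space consistency analysis: within each base set and
#' group, the angle table of every root-size-including space is correlated
#' with that of the root-size-free space; additionally each GSPFF/RES space
#' is compared with the UPFS space at the same inclusion level.
#'
#' @param bundle A [run_space_suite()] result.
#' @return data.frame with columns `space_a`, `space_b`, `r`, `p_value`,
#'   `n_angle_pairs`.
#' @export
compare_bundle_angles <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  recs <- Filter(function(r) is.null(r$error) && !is.null(r$angles),
                 bundle$records)
  rows <- list()
  add <- function(ra, rb) {
    cmp <- tryCatch(compare_angle_tables(ra$angles, rb$angles),
                    error = function(e) NULL)
    if (is.null(cmp)) return()
    rows[[paste(ra$space_id, rb$space_id)]] <<- data.frame(
      space_a = ra$space_id, space_b = rb$space_id,
      r = round(cmp$r, 4), p_value = cmp$p_value,
      n_angle_pairs = cmp$n_pairs)
  }
  if (!length(recs)) return(NULL)
  for (r in recs) {
    s <- r$selector
    if (is.null(s)) next
    if (s$root_size != "none") {
      base_id <- paste(selector_id(trait_selector(s$base_set, "none",
                                                  s$group)),
                       r$estimator, sep = "_")
      if (!is.null(recs[[base_id]])) add(recs[[base_id]], r)
    }
    if (s$base_set != "UPFS") {
      upfs_id <- paste(selector_id(trait_selector("UPFS", s$root_size,
                                                  s$group)),
                       r$estimator, sep = "_")
      if (!is.null(recs[[upfs_id]])) add(recs[[upfs_id]], r)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a result bundle to disk
#'
#' Serialises a bundle as per-space CSV tables (eigenvalues, loadings,
#' correlation and pairwise-n matrices where available, long-format angle
#' tables) plus one machine-readable JSON summary.
#'
#' @param bundle A [run_space_suite()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle_summary(bundle),
                   file.path(dir, "space_summary.csv"), row.names = FALSE)
  pi_tab <- summarize_proportional_increases(bundle)
  if (!is.null(pi_tab))
    utils::write.csv(pi_tab, file.path(dir, "proportional_increases.csv"),
                     row.names = FALSE)
  cmp <- compare_bundle_angles(bundle)
  if (!is.null(cmp))
    utils::write.csv(cmp, file.path(dir, "angle_comparisons.csv"),
                     row.names = FALSE)
  ang_rows <- list(); eig_rows <- list(); load_rows <- list()
  for (r in bundle$records) {
    if (!is.null(r$error)) next
    eig_rows[[r$space_id]] <- data.frame(
      space_id = r$space_id, dim = seq_along(r$space$values),
      eigenvalue = r$space$values,
      var_explained_pct = r$space$var_explained,
      retained = r$space$retained)
    L <- r$space$loadings[, r$space$retained, drop = FALSE]
    if (ncol(L))
      load_rows[[r$space_id]] <- data.frame(
        space_id = r$space_id,
        trait = rep(rownames(L), ncol(L)),
        dim = rep(seq_len(ncol(L)), each = nrow(L)),
        loading = as.vector(L))
    if (!is.null(r$angles))
      ang_rows[[r$space_id]] <- as.data.frame(r$angles)
  }
  utils::write.csv(do.call(rbind, c(eig_rows, make.row.names = FALSE)),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  if (length(load_rows))
    utils::write.csv(do.call(rbind, c(load_rows, make.row.names = FALSE)),
                     file.path(dir, "loadings.csv"), row.names = FALSE)
  if (length(ang_rows))
    utils::write.csv(do.call(rbind, c(ang_rows, make.row.names = FALSE)),
                     file.path(dir, "angles.csv"), row.names = FALSE)
  summary_json <- lapply(bundle$records, function(r) {
    if (!is.null(r$error))
      return(list(space_id = r$space_id, error = r$error))
    list(space_id = r$space_id, n_species = r$n_species,
         retained = sum(r$space$retained),
         eigenvalues = r$space$values,
         var_explained_pct = r$space$var_explained,
         end = r$end$end,
         clipped_negative_mass = r$end$clipped_negative_mass,
         end_random_mean = r$null$end_random_mean,
         null_reps = r$null$reps, null_seed = r$null$seed)
  })
  jsonlite::write_json(list(config = bundle$config, spaces = summary_json),
                       file.path(dir, "bundle.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
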