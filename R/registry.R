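#' Trait registry for the twelve-trait plant functional space
#'
#' The canonical registry of the twelve traits used throughout the package:
#' six aboveground traits (the global spectrum of plant form and function,
#' GSPFF), four fine-root traits (the root economics space, RES), and the two
#' root size traits (maximum rooting depth and maximum one-sided lateral root
#' spread). Units refer to the raw (untransformed) scale.
#'
#' @return A data.frame with columns `trait`, `unit`, `block` (the functional
#'   dimension each trait belongs to: `size`, `leaf_economics`,
#'   `collaboration`, `conservation`) and `description`.
#' @examples
#' trait_registry()
#' @export
trait_registry <- function() {
  data.frame(
    trait = c("ph", "ssd", "sm", "la", "ln", "sla",
              "SRL", "D", "RTD", "RN", "Dr", "Lr"),
    unit = c("m", "g/m3", "mg", "mm2", "mg/g", "mm2/mg",
             "m/g", "mm", "g/cm3", "mg/g", "m", "m"),
    block = c("size", "size", "size",
              "leaf_economics", "leaf_economics", "leaf_economics",
              "collaboration", "collaboration",
              "conservation", "conservation",
              "size", "size"),
    description = c("plant height", "specific stem density", "seed mass",
                    "leaf area", "leaf nitrogen concentration",
                    "specific leaf area", "specific root length",
                    "root diameter", "root tissue density",
                    "root nitrogen concentration", "maximum rooting depth",
                    "maximum lateral root spread"),
    stringsAsFactors = FALSE
  )
}

#' Named trait sets used in the analysis grid
#'
#' @return A named list: `UPFS` (ten traits of the unified plant functional
#'   space, excluding root size), `GSPFF` (six aboveground traits), `RES`
#'   (four fine-root traits) and `root_size` (`Dr`, `Lr`).
#' @export
trait_sets <- function() {
  list(
    UPFS = c("ph", "ssd", "sm", "la", "ln", "sla", "SRL", "D", "RTD", "RN"),
    GSPFF = c("ph", "ssd", "sm", "la", "ln", "sla"),
    RES = c("SRL", "D", "RTD", "RN"),
    root_size = c("Dr", "Lr")
  )
}

#' Define a trait-space selection
#'
#' A selector names one of the twelve analysis spaces: a base trait set
#' crossed with a level of root-size inclusion, optionally restricted to a
#' growth-form group.
#'
#' @param base_set One of `"UPFS"`, `"GSPFF"`, `"RES"`.
#' @param root_size Root-size inclusion level: `"none"`, `"Dr"`, `"Lr"` or
#'   `"Dr+Lr"`.
#' @param group Growth-form restriction: `"all"`, `"woody"` or `"herbaceous"`.
#' @return An object of class `trait_selector`.
#' @examples
#' trait_selector("RES", "Dr+Lr")
#' @export
trait_selector <- function(base_set = c("UPFS", "GSPFF", "RES"),
                           root_size = c("none", "Dr", "Lr", "Dr+Lr"),
                           group = c("all", "woody", "herbaceous")) {
  base_set <- match.arg(base_set)
  root_size <- match.arg(root_size)
  group <- match.arg(group)
  structure(list(base_set = base_set, root_size = root_size, group = group),
            class = "trait_selector")
}

#' Traits named by a selector
#'
#' @param selector A [trait_selector()].
#' @return Character vector of trait labels (base set plus included root-size
#'   traits, in registry order).
#' @export
selector_traits <- function(selector) {
  stopifnot(inherits(selector, "trait_selector"))
  sets <- trait_sets()
  extra <- switch(selector$root_size,
                  none = character(0),
                  Dr = "Dr",
                  Lr = "Lr",
                  "Dr+Lr" = c("Dr", "Lr"))
  c(sets[[selector$base_set]], extra)
}

#' @export
print.trait_selector <- function(x, ...) {
  cat(sprintf("<trait_selector> %s + root size: %s, group: %s (%d traits)\n",
              x$base_set, x$root_size, x$group, length(selector_traits(x))))
  invisible(x)
}

#' Identifier string for a selector
#'
#' @param selector A [trait_selector()].
#' @return A string such as `"UPFS_Dr+Lr_all"`.
#' @export
selector_id <- function(selector) {
  paste(selector$base_set, selector$root_size, selector$group, sep = "_")
}
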