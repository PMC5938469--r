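#' Resource category schema
#'
#' A schema describes the ordered resource categories shared by the
#' species-by-resource-use and habitat-by-resource-availability matrices:
#' each category has a name, a block (`foraging_strata`, `nest_location` or
#' `diet`), a kind (`binary` or `ordinal`) and a maximum level (1 for binary
#' presence/use, 3 for the 0--3 ordinal diet scores). Carrying the schema
#' alongside the data means an all-zero diet column is still treated as
#' ordinal rather than inferred to be binary.
#'
#' @param categories data.frame with columns `name`, `block`, `kind` and
#'   optionally `max_level` (filled from `kind` when absent).
#' @return an object of class `resource_schema` (a validated data.frame).
#' @seealso [default_resource_schema()], [read_resource_schema()]
#' @export
resource_schema <- function(categories) {
  stopifnot(is.data.frame(categories),
            all(c("name", "block", "kind") %in% names(categories)))
  categories$name <- as.character(categories$name)
  categories$block <- as.character(categories$block)
  categories$kind <- as.character(categories$kind)
  bad_block <- setdiff(categories$block,
                       c("foraging_strata", "nest_location", "diet"))
  if (length(bad_block))
    stop_("unknown block(s): %s", paste(bad_block, collapse = ", "))
  bad_kind <- setdiff(categories$kind, c("binary", "ordinal"))
  if (length(bad_kind))
    stop_("unknown kind(s): %s", paste(bad_kind, collapse = ", "))
  if (is.null(categories$max_level))
    categories$max_level <- ifelse(categories$kind == "binary", 1L, 3L)
  categories$max_level <- as.integer(categories$max_level)
  if (any(categories$kind == "binary" & categories$max_level != 1L))
    stop_("binary categories must have max_level 1")
  if (any(categories$kind == "ordinal" & categories$max_level != 3L))
    stop_("ordinal categories must have max_level 3")
  if (anyDuplicated(categories$name))
    stop_("duplicated category name(s): %s",
          paste(unique(categories$name[duplicated(categories$name)]),
                collapse = ", "))
  rownames(categories) <- NULL
  structure(categories[c("name", "block", "kind", "max_level")],
            class = c("resource_schema", "data.frame"))
}

#' Default 38-category resource schema
#'
#' Six binary foraging strata, seven binary nest locations and 25 ordinal
#' (0--3) diet categories, mirroring the structure used to score avian
#' resource use and habitat resource availability.
#'
#' @return a [resource_schema()].
#' @export
default_resource_schema <- function() {
  strata <- c("ground", "understorey", "canopy", "trunk_bark", "aerial",
              "freshwater")
  nest <- c("nest_ground", "nest_shrub", "nest_tree", "nest_cavity",
            "nest_burrow", "nest_cliff", "nest_building")
  diet <- c("seeds_small", "seeds_large", "grain", "fruit", "berries",
            "nectar", "pollen", "foliage", "buds_shoots", "roots_tubers",
            "fungi", "carrion", "terrestrial_inverts", "aerial_inverts",
            "aquatic_inverts", "earthworms", "molluscs", "crustaceans",
            "spiders", "larvae", "fish", "amphibians", "reptiles",
            "small_mammals", "eggs_chicks")
  resource_schema(data.frame(
    name = c(strata, nest, diet),
    block = rep(c("foraging_strata", "nest_location", "diet"),
                c(length(strata), length(nest), length(diet))),
    kind = rep(c("binary", "binary", "ordinal"),
               c(length(strata), length(nest), length(diet)))
  ))
}

#' Read a schema sidecar file (YAML)
#'
#' The file must contain a top-level `categories` list whose entries have
#' `name`, `block` and `kind` keys.
#'
#' @param path path to a YAML file.
#' @return a [resource_schema()].
#' @export
read_resource_schema <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$categories)) stop_("schema file has no 'categories' entry")
  resource_schema(do.call(rbind, lapply(y$categories, function(ct)
    data.frame(name = ct$name, block = ct$block, kind = ct$kind))))
}
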