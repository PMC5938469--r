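#' Resource matrix (components x categories) with provenance labels
#'
#' A resource matrix holds either species-by-resource-use or
#' habitat-by-resource-availability scores: one row per component (species or
#' habitat), one column per schema category, integer values in
#' `[0, max_level]`, and a native/exotic provenance label per component.
#' Missing entries are a validation error: the matrices this pipeline
#' consumes are complete by construction.
#'
#' @param values integer matrix, rownames = component ids, colnames = the
#'   schema's category names (in order).
#' @param provenance character vector (`"native"`/`"exotic"`), one per row.
#' @param component_kind `"species"` or `"habitat"`.
#' @param schema a [resource_schema()]; defaults to the 38-category schema.
#' @return an object of class `resource_matrix` with fields `values`,
#'   `ids`, `provenance`, `component_kind`, `schema`.
#' @export
resource_matrix <- function(values, provenance,
                            component_kind = c("species", "habitat"),
                            schema = default_resource_schema()) {
  component_kind <- match.arg(component_kind)
  stopifnot(inherits(schema, "resource_schema"))
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop_("no components")
  if (is.null(rownames(values))) stop_("values must have component ids as rownames")
  ids <- rownames(values)
  if (anyDuplicated(ids))
    stop_("duplicate component id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (ncol(values) != nrow(schema))
    stop_("matrix has %d categories but schema has %d", ncol(values), nrow(schema))
  if (!is.null(colnames(values)) && !identical(colnames(values), schema$name))
    stop_("category names do not match the schema (in order)")
  colnames(values) <- schema$name
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_("missing value at component '%s', category '%s'",
          ids[bad[1L]], schema$name[bad[2L]])
  }
  if (any(values != round(values))) stop_("values must be integers")
  storage.mode(values) <- "integer"
  for (j in seq_len(ncol(values))) {
    bad <- which(values[, j] < 0L | values[, j] > schema$max_level[j])
    if (length(bad))
      stop_("value %d > max_level %d (or negative) at component '%s', category '%s'",
            values[bad[1L], j], schema$max_level[j], ids[bad[1L]], schema$name[j])
  }
  provenance <- as.character(provenance)
  if (length(provenance) != nrow(values))
    stop_("provenance must have one label per component")
  bad <- setdiff(unique(provenance), c("native", "exotic"))
  if (length(bad))
    stop_("unknown provenance label(s): %s", paste(bad, collapse = ", "))
  names(provenance) <- ids
  structure(list(values = values, ids = ids, provenance = provenance,
                 component_kind = component_kind, schema = schema),
            class = "resource_matrix")
}

#' @export
print.resource_matrix <- function(x, ...) {
  cat(sprintf("resource_matrix: %d %s x %d categories (%d native, %d exotic)\n",
              length(x$ids), x$component_kind, ncol(x$values),
              sum(x$provenance == "native"), sum(x$provenance == "exotic")))
  invisible(x)
}

#' @export
dim.resource_matrix <- function(x) dim(x$values)

#' Read a resource matrix from CSV
#'
#' Expected layout: header row; first column the component id, second column
#' the provenance label (`native`/`exotic`), remaining columns the schema's
#' categories in order, holding integer scores.
#'
#' @param path CSV file path.
#' @param component_kind `"species"` or `"habitat"`.
#' @param schema optional [resource_schema()]; when `NULL`, the default
#'   38-category schema is used if the column count matches, otherwise the
#'   categories are inferred as binary/ordinal from the header block prefixes.
#' @return a [resource_matrix()].
#' @export
read_resource_matrix <- function(path, component_kind = c("species", "habitat"),
                                 schema = NULL) {
  component_kind <- match.arg(component_kind)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_("no components")
  if (ncol(df) < 3L) stop_("CSV needs id, provenance and category columns")
  cats <- names(df)[-(1:2)]
  if (is.null(schema)) {
    def <- default_resource_schema()
    if (identical(cats, def$name)) {
      schema <- def
    } else {
      stop_("CSV categories do not match the default schema; supply `schema` (see read_resource_schema)")
    }
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- as.character(df[[1L]])
  resource_matrix(vals, df[[2L]], component_kind, schema)
}

#' Write a resource matrix to CSV
#'
#' Inverse of [read_resource_matrix()]: `read(write(m))` is the identity on
#' values, ids and provenance.
#'
#' @param m a [resource_matrix()].
#' @param path output CSV path.
#' @export
write_resource_matrix <- function(m, path) {
  stopifnot(inherits(m, "resource_matrix"))
  df <- data.frame(id = m$ids, provenance = unname(m$provenance),
                   m$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a resource matrix by provenance
#'
#' Partitions the components into the native and exotic pools, preserving
#' row order and sharing the schema. A pool with fewer than two components
#' cannot support distance/dendrogram computation downstream; such pools are
#' flagged with a warning and an `insufficient` attribute.
#'
#' @param m a [resource_matrix()].
#' @return named list with elements `native` and `exotic`; an empty pool is
#'   `NULL` (with a warning).
#' @export
split_by_provenance <- function(m) {
  stopifnot(inherits(m, "resource_matrix"))
  out <- lapply(c(native = "native", exotic = "exotic"), function(p) {
    keep <- m$provenance == p
    if (!any(keep)) return(NULL)
    sub <- resource_matrix(m$values[keep, , drop = FALSE],
                           m$provenance[keep], m$component_kind, m$schema)
    attr(sub, "insufficient") <- sum(keep) < 2L
    sub
  })
  for (p in names(out)) {
    if (is.null(out[[p]]) || attr(out[[p]], "insufficient"))
      warn_("provenance group '%s' has < 2 components; FD undefined for this pool", p)
  }
  out
}
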