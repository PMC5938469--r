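#' Gower distance on a mixed binary/ordinal resource matrix
#'
#' Classic Gower dissimilarity for quantitative variables:
#' `d(i,j) = mean_k |x_ik - x_jk| / r_k` over the categories `k` whose
#' observed range `r_k` is positive. Binary categories contribute plain 0/1
#' mismatch terms (joint absence counts as similarity); zero-range
#' categories carry no information and are dropped from both numerator and
#' denominator. By default `r_k` is the observed per-column range
#' (max - min over the matrix's components); set `ranges = "theoretical"`
#' to normalize by the schema's `max_level` instead (sensitivity analysis).
#'
#' @param m a [resource_matrix()] with at least two components.
#' @param ranges `"observed"` (default, classic Gower) or `"theoretical"`.
#' @return an object of class `resource_dist`: list with `ids`, `d`
#'   (symmetric matrix in `[0, 1]` with zero diagonal), `ranges_used`
#'   (per-category range; 0 marks dropped categories) and `dropped`.
#' @export
gower_distance <- function(m, ranges = c("observed", "theoretical")) {
  ranges <- match.arg(ranges)
  stopifnot(inherits(m, "resource_matrix"))
  v <- m$values
  if (nrow(v) < 2L) stop_("need at least 2 components")
  r <- switch(ranges,
              observed = apply(v, 2L, function(col) diff(range(col))),
              theoretical = as.numeric(m$schema$max_level))
  keep <- r > 0
  if (!any(keep)) stop_("no informative categories: every category has zero range")
  vs <- sweep(v[, keep, drop = FALSE], 2L, r[keep], "/")
  d <- as.matrix(stats::dist(vs, method = "manhattan")) / sum(keep)
  dimnames(d) <- list(m$ids, m$ids)
  ru <- r
  ru[!keep] <- 0
  names(ru) <- m$schema$name
  structure(list(ids = m$ids, d = d, ranges_used = ru,
                 dropped = m$schema$name[!keep], ranges = ranges),
            class = "resource_dist")
}

#' Cross-pool Gower distance (e.g. species rows vs habitat rows)
#'
#' Gower distance between every row of `m1` and every row of `m2`, with
#' ranges taken over the pooled rows so the two matrices are measured on a
#' common scale. Requires a shared schema. Used by the synthetic community
#' generator to quantify species-landscape resource overlap.
#'
#' @param m1,m2 [resource_matrix()] objects with identical schemas.
#' @return numeric matrix, `nrow(m1)` x `nrow(m2)`, values in `[0, 1]`.
#' @export
cross_gower <- function(m1, m2) {
  stopifnot(inherits(m1, "resource_matrix"), inherits(m2, "resource_matrix"))
  if (!identical(m1$schema$name, m2$schema$name))
    stop_("matrices must share a schema")
  v <- rbind(m1$values, m2$values)
  r <- apply(v, 2L, function(col) diff(range(col)))
  keep <- r > 0
  if (!any(keep)) stop_("no informative categories: every category has zero range")
  vs <- sweep(v[, keep, drop = FALSE], 2L, r[keep], "/")
  d <- as.matrix(stats::dist(vs, method = "manhattan")) / sum(keep)
  d[seq_len(nrow(m1)), nrow(m1) + seq_len(nrow(m2)), drop = FALSE]
}

#' @export
print.resource_dist <- function(x, ...) {
  cat(sprintf("resource_dist (Gower, %s ranges): %d components, %d categories dropped\n",
              x$ranges, length(x$ids), length(x$dropped)))
  invisible(x)
}

#' @export
as.dist.resource_dist <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$d, diag = diag, upper = upper)

#' Write a square distance matrix to CSV (ids as header row/column)
#'
#' @param dm a `resource_dist`.
#' @param path output CSV path.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "resource_dist"))
  df <- data.frame(id = dm$ids, dm$d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
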