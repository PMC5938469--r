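#' Distance-band spatial weights
#'
#' Neighbors are all units within `threshold_km` of each other
#' (centroid-to-centroid Euclidean distance on the planar km grid, self
#' excluded). The neighbor relation is symmetric; with
#' `style = "row_standardized"` (default) each row of the weight matrix is
#' scaled to sum to 1. Units with no neighbors keep a zero row and are
#' flagged with a warning. The eigenvalues needed for the SAR
#' log-determinant are computed once here (for the row-standardized style
#' via the similar symmetric matrix `D^-1/2 B D^-1/2`, which shares its
#' spectrum with `W`).
#'
#' @param coords two-column matrix/data.frame of unit coordinates in km.
#' @param threshold_km neighborhood distance (default 35).
#' @param style `"row_standardized"` or `"binary"`.
#' @return object of class `spatial_weights`: `n`, `coords`, `W` (dense
#'   weight matrix), `neighbors` (list of index vectors), `cardinality`,
#'   `islands`, `eigenvalues`, `threshold_km`, `style`.
#' @export
build_weights <- function(coords, threshold_km = 35,
                          style = c("row_standardized", "binary")) {
  style <- match.arg(style)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 2L)
  if (anyDuplicated(coords)) stop_("unit coordinates must be unique")
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  B <- (D > 0 & D <= threshold_km) * 1
  deg <- rowSums(B)
  islands <- which(deg == 0)
  if (length(islands))
    warn_("%d unit(s) have no neighbors within %g km (zero weight rows)",
          length(islands), threshold_km)
  if (style == "row_standardized") {
    scale <- ifelse(deg > 0, deg, 1)
    W <- B / scale
    # W = D^-1 B is similar to the symmetric D^-1/2 B D^-1/2: real spectrum
    s <- 1 / sqrt(scale)
    ev <- eigen(B * tcrossprod(s), symmetric = TRUE, only.values = TRUE)$values
  } else {
    W <- B
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  }
  neighbors <- apply(B > 0, 1L, which, simplify = FALSE)
  structure(list(n = n, coords = coords, W = W, neighbors = neighbors,
                 cardinality = as.integer(deg), islands = islands,
                 eigenvalues = ev, threshold_km = threshold_km, style = style),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, %g km band, %s, %d-%d neighbors%s\n",
              x$n, x$threshold_km, x$style, min(x$cardinality),
              max(x$cardinality),
              if (length(x$islands)) sprintf(" (%d islands)", length(x$islands)) else ""))
  invisible(x)
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n/S0) * (z' W z) / (z' z)` with `z` the centered values and `S0`
#' the total weight. The expectation is `-1/(n-1)`; the variance, z-score
#' and two-sided p-value come from the normality approximation (via
#' `ape::Moran.I`). For small n a permutation p-value (seeded, default 999
#' permutations) can be requested instead.
#'
#' @param values per-unit numeric vector with nonzero variance.
#' @param w a [build_weights()] object.
#' @param permutations 0 for the analytic test, else the number of
#'   permutations.
#' @param seed seed for the permutation test.
#' @return list of class `moran_result`: `I`, `expected`, `sd`, `z`,
#'   `p_value`, `method`.
#' @export
morans_i <- function(values, w, permutations = 0L, seed = 1L) {
  stopifnot(inherits(w, "spatial_weights"), length(values) == w$n)
  if (stats::sd(values) == 0) stop_("zero variance: Moran's I undefined")
  W <- w$W
  S0 <- sum(W)
  z <- values - mean(values)
  obs <- (w$n / S0) * drop(crossprod(z, W %*% z)) / sum(z^2)
  ap <- ape::Moran.I(values, W)
  stopifnot(isTRUE(all.equal(obs, ap$observed)))
  if (permutations > 0L) {
    perm <- with_seed(seed, replicate(permutations, {
      zp <- sample(z)
      (w$n / S0) * drop(crossprod(zp, W %*% zp)) / sum(zp^2)
    }))
    p <- (1 + sum(abs(perm - ap$expected) >= abs(obs - ap$expected))) /
      (permutations + 1)
    method <- sprintf("permutation (%d)", permutations)
  } else {
    p <- ap$p.value
    method <- "normality approximation"
  }
  structure(list(I = obs, expected = ap$expected, sd = ap$sd,
                 z = (obs - ap$expected) / ap$sd, p_value = p,
                 method = method),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), z = %.2f, p = %.3g [%s]\n",
              x$I, x$expected, x$z, x$p_value, x$method))
  invisible(x)
}
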