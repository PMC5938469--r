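#' Occupancy-weighted sampling without replacement
#'
#' Draws `k` distinct component ids by the successive-draw scheme: each draw
#' picks id `i` with probability `w_i` over the sum of the remaining
#' weights, then removes it. This is exactly the scheme implemented by
#' `base::sample(x, k, prob = w)`, which is used as the single code path
#' shared by the null models and the synthetic community generator.
#'
#' @param weights named non-negative numeric vector (occupancy counts).
#' @param k number of components to draw; must not exceed the number of
#'   positive-weight components.
#' @return character vector of `k` distinct ids.
#' @export
weighted_sample <- function(weights, k) {
  stopifnot(!is.null(names(weights)), all(weights >= 0))
  eligible <- sum(weights > 0)
  if (k > eligible)
    stop_("cannot draw %d components from a pool with %d positive weights",
          k, eligible)
  sample(names(weights), k, replace = FALSE, prob = weights)
}

#' Null distribution of FD at fixed richness
#'
#' Monte-Carlo null for the FD of a community/landscape of `k` components:
#' `n_iter` occupancy-weighted random draws of `k` components from the pool
#' (probability of selection proportional to the number of quadrats in which
#' the component was recorded), each scored by [fd_subset()] on the pool
#' dendrogram. The mean and standard deviation (denominator `n - 1`) of the
#' resulting FD distribution standardize observed FD into sFD.
#'
#' @param tree pool dendrogram ([upgma()]).
#' @param weights named occupancy weights over (a superset of) the tree's
#'   leaves.
#' @param k richness of the draws (`k >= 1`; quadrat filtering upstream
#'   guarantees `k >= 2` in the pipeline).
#' @param n_iter number of iterations (default 1000).
#' @param include_root_path FD convention flag, see [fd_subset()].
#' @param seed integer seed for this distribution's RNG stream.
#' @param restrict_to optional id set intersected with the pool before
#'   weighting (e.g. an island-specific pool).
#' @param pool_id label recorded on the output.
#' @return an object of class `null_fd`: `k`, `n_iter`, `mean_fd`, `sd_fd`,
#'   `seed`, `pool_id`, `include_root_path`.
#' @export
null_fd_distribution <- function(tree, weights, k, n_iter = 1000L,
                                 include_root_path = FALSE, seed = 1L,
                                 restrict_to = NULL, pool_id = "pool") {
  stopifnot(inherits(tree, "fd_dendrogram"), n_iter >= 2L, k >= 1L)
  w <- weights[names(weights) %in% tree$labels]
  if (!is.null(restrict_to)) w <- w[names(w) %in% restrict_to]
  if (length(w) == 0L) stop_("empty pool after restriction")
  eligible <- names(w)[w > 0]
  if (k > length(eligible))
    stop_("richness %d exceeds the %d positive-weight pool components",
          k, length(eligible))
  leaf_idx <- match(names(w), tree$labels)
  fd <- with_seed(seed, {
    P <- matrix(0, tree$n, n_iter)
    for (it in seq_len(n_iter)) {
      drawn <- sample(seq_along(w), k, replace = FALSE, prob = w)
      P[leaf_idx[drawn], it] <- 1
    }
    fd_subset_many(tree, P, include_root_path)
  })
  structure(list(k = as.integer(k), n_iter = as.integer(n_iter),
                 mean_fd = mean(fd), sd_fd = stats::sd(fd),
                 seed = as.integer(seed), pool_id = pool_id,
                 include_root_path = include_root_path),
            class = "null_fd")
}

#' @export
print.null_fd <- function(x, ...) {
  cat(sprintf("null_fd [%s]: k = %d, n_iter = %d, mean = %.4g, sd = %.4g (seed %d)\n",
              x$pool_id, x$k, x$n_iter, x$mean_fd, x$sd_fd, x$seed))
  invisible(x)
}

#' Standardized functional diversity (sFD)
#'
#' `sFD = (observed - null mean) / null SD`. Negative values indicate less
#' functional diversity than expected at that richness, the signature of
#' environmental filtering. When the null SD is zero (e.g. the community is
#' the entire pool) the sFD is undefined and flagged.
#'
#' @param observed observed FD.
#' @param nd a [null_fd_distribution()].
#' @return list of class `sfd`: `observed`, `sfd` (`NA` when undefined),
#'   `undefined` flag, and the null `mean_fd`/`sd_fd`/`seed`.
#' @export
standardize_fd <- function(observed, nd) {
  stopifnot(inherits(nd, "null_fd"))
  undef <- !is.finite(nd$sd_fd) || nd$sd_fd == 0
  structure(list(observed = as.numeric(observed),
                 sfd = if (undef) NA_real_ else (observed - nd$mean_fd) / nd$sd_fd,
                 undefined = undef, mean_fd = nd$mean_fd, sd_fd = nd$sd_fd,
                 seed = nd$seed),
            class = "sfd")
}

#' One-sample t test
#'
#' Standard one-sample t test of `values` against `mu0`, as applied to a
#' field of quadrat sFD values against the null expectation 0.
#'
#' @param values numeric vector, `n >= 2`, non-constant.
#' @param mu0 null mean (default 0).
#' @return list: `statistic`, `df`, `p_value`, `estimate`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop_("need at least 2 finite values")
  if (stats::sd(values) == 0) stop_("zero variance: t statistic undefined")
  ht <- stats::t.test(values, mu = mu0)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, estimate = unname(ht$estimate),
       n = length(values))
}

#' Paired t test
#'
#' One-sample t test of the paired differences `a - b` against 0 (e.g.
#' native vs exotic sFD across quadrats). Pairs with a missing member are
#' dropped.
#'
#' @param a,b numeric vectors of equal length.
#' @return as [one_sample_t()], computed on `a - b`. Identical series give
#'   `t = 0`; a constant non-zero difference has infinite t and errors as
#'   zero-variance.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop_("a and b must have equal length")
  d <- (a - b)[is.finite(a - b)]
  if (length(d) >= 2L && all(d == 0))
    return(list(statistic = 0, df = length(d) - 1L, p_value = 1,
                estimate = 0, n = length(d)))
  one_sample_t(d, 0)
}
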