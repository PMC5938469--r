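#' UPGMA functional dendrogram
#'
#' Unweighted pair-group average-linkage clustering of a distance matrix,
#' producing an ultrametric dendrogram: leaves at height 0, each internal
#' node at the unweighted mean of the pairwise distances between all leaf
#' pairs spanning the two merged clusters, and the cophenetic distance of
#' two leaves equal to the merge height of their lowest common ancestor.
#' Edge lengths are parent height minus child height.
#'
#' Ties (several cluster pairs at the minimal distance) are broken
#' deterministically in favour of the pair whose member labels are
#' lexicographically smallest, so builds are reproducible regardless of
#' input order.
#'
#' @param dm a [gower_distance()] result, or any symmetric matrix /
#'   `dist` with labels.
#' @return an object of class `fd_dendrogram`; see Details.
#' @details The object carries the hclust-style `merge`/`height`/`order`
#'   fields plus a flattened edge list used by [fd_subset()]:
#'   `edge` (parent, child node ids; leaves `1..n`, internal `n+1..2n-1`
#'   in merge order, root `2n-1`), `edge_length`, `node_height`, and
#'   `inc`, the (edge x leaf) incidence matrix marking which leaves sit
#'   below each edge.
#' @export
upgma <- function(dm) {
  if (inherits(dm, "resource_dist")) {
    d <- dm$d
  } else if (inherits(dm, "dist")) {
    d <- as.matrix(dm)
  } else {
    d <- as.matrix(dm)
  }
  n <- nrow(d)
  if (n < 2L) stop_("need at least 2 components")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  if (!all(is.finite(d))) stop_("non-finite distances")
  if (!isTRUE(all.equal(d, t(d)))) stop_("distance matrix must be symmetric")

  # active clusters: hclust codes (-leaf or +merge row), sizes, min label key
  cd <- d
  code <- -seq_len(n)
  size <- rep(1L, n)
  key <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n)) # leaf index sets per active cluster

  merge_members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- nrow(cd)
    diag(cd) <- Inf
    mn <- min(cd)
    cand <- which(cd == mn & upper.tri(cd), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      # lexicographic tie-break on the sorted pair of cluster keys
      k1 <- pmin(key[cand[, 1L]], key[cand[, 2L]])
      k2 <- pmax(key[cand[, 1L]], key[cand[, 2L]])
      cand <- cand[order(k1, k2)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    # record merge in hclust convention: singletons first, ascending
    pair <- c(code[i], code[j])
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[s, ] <- pair
    height[s] <- mn
    merge_members[[s]] <- c(members[[i]], members[[j]])
    # UPGMA (unweighted average) Lance-Williams update
    new_d <- (size[i] * cd[i, ] + size[j] * cd[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    code <- c(code[keep], s)
    size <- c(size[keep], size[i] + size[j])
    key <- c(key[keep], min(key[i], key[j]))
    members <- c(members[keep], list(merge_members[[s]]))
  }

  # leaf display order by recursive expansion of the merge matrix
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  ord <- expand(n - 1L)

  # flattened rooted-tree representation: leaves 1..n, internal n+s
  node_height <- c(rep(0, n), height)
  child_of <- function(code) if (code < 0L) -code else n + code
  parent <- integer(2L * n - 1L)
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  for (s in seq_len(n - 1L)) {
    for (k in 1:2) {
      ch <- child_of(merge[s, k])
      e <- 2L * (s - 1L) + k
      edges[e, ] <- c(n + s, ch)
      elen[e] <- height[s] - node_height[ch]
      parent[ch] <- n + s
    }
  }
  if (any(elen < -1e-12))
    stop_("non-monotone merge heights (not a valid UPGMA result)")
  elen[elen < 0] <- 0
  # incidence: which leaves lie below each edge (below = in child's subtree)
  leafset <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) leafset[[i]] <- i
  for (s in seq_len(n - 1L)) leafset[[n + s]] <- merge_members[[s]]
  inc <- matrix(0, nrow(edges), n)
  for (e in seq_len(nrow(edges))) inc[e, leafset[[edges[e, 2L]]]] <- 1
  colnames(inc) <- labels

  structure(list(labels = labels, n = n, merge = merge, height = height,
                 order = ord, edge = edges, edge_length = elen,
                 node_height = node_height, parent = parent, inc = inc,
                 total_length = sum(elen)),
            class = "fd_dendrogram")
}

#' @export
print.fd_dendrogram <- function(x, ...) {
  cat(sprintf("fd_dendrogram: %d leaves, root height %.4g, total branch length %.4g\n",
              x$n, max(x$height), x$total_length))
  invisible(x)
}

#' @export
as.hclust.fd_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

#' Functional diversity of a component subset
#'
#' FD of the components `present` on dendrogram `tree`: the total length of
#' the branches of the minimal subtree connecting them. With
#' `include_root_path = FALSE` (default) the subtree is rooted at the lowest
#' common ancestor of the present leaves, so a singleton has FD 0; with
#' `TRUE` the edges from that ancestor up to the global root are added. The
#' convention is recorded on the result.
#'
#' @param tree an [upgma()] dendrogram.
#' @param present character vector of leaf ids (non-empty, no unknowns).
#' @param include_root_path logical FD convention flag.
#' @return non-negative scalar with attribute `include_root_path`.
#' @export
fd_subset <- function(tree, present, include_root_path = FALSE) {
  stopifnot(inherits(tree, "fd_dendrogram"))
  if (length(present) == 0L) stop_("empty component set")
  idx <- match(present, tree$labels)
  if (anyNA(idx))
    stop_("unknown leaf id(s): %s", paste(present[is.na(idx)], collapse = ", "))
  idx <- unique(idx)
  z <- numeric(tree$n)
  z[idx] <- 1
  cnt <- drop(tree$inc %*% z)
  k <- length(idx)
  keep <- cnt > 0 & (include_root_path | cnt < k)
  structure(sum(tree$edge_length[keep]), include_root_path = include_root_path)
}

# Vectorized FD over the columns of a leaf-indicator matrix (leaves x m).
# Internal fast path for null distributions.
fd_subset_many <- function(tree, P, include_root_path = FALSE) {
  cnt <- tree$inc %*% P
  k <- colSums(P)
  keep <- cnt > 0
  if (!include_root_path)
    keep <- keep & sweep(cnt, 2L, k, "<")
  drop(crossprod(keep, tree$edge_length))
}

#' Total branch length of a dendrogram
#'
#' Sum of all edge lengths; equals [fd_subset()] over the full leaf set
#' under either root convention.
#'
#' @param tree an [upgma()] dendrogram.
#' @return non-negative scalar.
#' @export
total_length <- function(tree) {
  stopifnot(inherits(tree, "fd_dendrogram"))
  tree$total_length
}

#' Convert a dendrogram to an ape `phylo` object
#'
#' Branch lengths are the dendrogram edge lengths (parent height minus
#' child height), so the tree renders with leaves aligned at height 0 and
#' the root at the deepest merge height. Note this differs from
#' `ape::as.phylo.hclust`, which halves heights so that patristic
#' (tip-to-tip path) distances equal cophenetic distances.
#'
#' @param tree an [upgma()] dendrogram.
#' @return an `ape::phylo`.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "fd_dendrogram"))
  n <- tree$n
  root <- 2L * n - 1L
  # renumber internal nodes in preorder (ape convention: root = n + 1)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  new_id <- integer(2L * n - 1L)
  new_id[seq_len(n)] <- seq_len(n)
  nxt <- n
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  erow <- 0L
  # iterative preorder traversal (stack of internal nodes)
  stack <- root
  while (length(stack)) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    nxt <- nxt + 1L
    new_id[node] <- nxt
    for (ch in children[[as.character(node)]]) {
      erow <- erow + 1L
      edge[erow, 1L] <- node # old ids; remap after traversal
      edge[erow, 2L] <- ch
      elen[erow] <- tree$node_height[node] - tree$node_height[ch]
      if (ch > n) stack <- c(ch, stack)
    }
  }
  # remap to preorder numbering; reorder edges so parents precede children
  pre <- order(new_id[edge[, 1L]], new_id[edge[, 2L]])
  edge <- cbind(new_id[edge[pre, 1L]], new_id[edge[pre, 2L]])
  elen <- elen[pre]
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = tree$labels, Nnode = n - 1L),
                   class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a dendrogram to a Newick file
#'
#' Branch lengths are edge lengths; heights round-trip through
#' [ape::read.tree()] to better than 1e-9 relative precision.
#'
#' @param tree an [upgma()] dendrogram.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path, digits = 12)
  invisible(path)
}
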