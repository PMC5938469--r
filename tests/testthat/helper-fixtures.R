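# Shared fixtures and independent oracles, all built in code.

# minimal 3-category schema: two binary foraging strata + one diet item
toy_schema <- function() {
  resource_schema(data.frame(
    name = c("b1", "b2", "d1"),
    block = c("foraging_strata", "foraging_strata", "diet"),
    kind = c("binary", "binary", "ordinal")))
}

# the hand-worked A/B/C example: Gower d(A,B)=2/3, d(A,C)=8/9, d(B,C)=4/9
toy_matrix_abc <- function() {
  v <- matrix(c(1L, 0L, 3L,
                1L, 1L, 0L,
                0L, 1L, 1L), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("b1", "b2", "d1")))
  resource_matrix(v, rep("native", 3), "species", toy_schema())
}

hand_tree <- function() upgma(gower_distance(toy_matrix_abc()))

# random valid resource matrix on the default 38-category schema
random_resource_matrix <- function(n, seed, n_native = ceiling(n / 2),
                                   kind = "species") {
  sch <- default_resource_schema()
  withr::with_seed(seed, {
    v <- sapply(seq_len(nrow(sch)), function(k)
      sample.int(sch$max_level[k] + 1L, n, replace = TRUE) - 1L)
    colnames(v) <- sch$name
    rownames(v) <- sprintf("c%03d", seq_len(n))
    resource_matrix(v, rep(c("native", "exotic"), c(n_native, n - n_native)),
                    kind, sch)
  })
}

# random ultrametric dendrogram via random points -> distances -> UPGMA
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    pts <- matrix(runif(n * 4), n)
    rownames(pts) <- sprintf("t%03d", seq_len(n))
    upgma(stats::dist(pts))
  })
}

# Brute-force FD oracle: union of root-ward edge paths of the present
# leaves, trimmed above their lowest common ancestor (edges identified by
# their child node). Independent of the incidence-matrix implementation.
fd_oracle <- function(tree, present, include_root_path = FALSE) {
  idx <- match(present, tree$labels)
  stopifnot(!anyNA(idx))
  root <- 2L * tree$n - 1L
  node_path <- function(leaf) {
    nodes <- leaf
    while (nodes[length(nodes)] != root)
      nodes <- c(nodes, tree$parent[nodes[length(nodes)]])
    nodes
  }
  paths <- lapply(idx, node_path)
  union_children <- setdiff(unique(unlist(paths)), root)
  if (!include_root_path) {
    common <- Reduce(intersect, paths) # ancestors shared by all present leaves
    union_children <- setdiff(union_children, common)
  }
  elen <- stats::setNames(tree$edge_length, tree$edge[, 2L])
  sum(elen[as.character(union_children)])
}

# factorial-enumeration LMG oracle: average incremental R2 over all
# predictor orderings (independent of the Shapley-subset implementation)
lmg_oracle <- function(y, X) {
  p <- ncol(X)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    M <- cbind(1, X[, cols, drop = FALSE])
    1 - sum(stats::lm.fit(M, y)$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(Recall(v[-i]), function(q) c(v[i], q)))
    out
  }
  shares <- stats::setNames(numeric(p), colnames(X))
  for (ord in perms(seq_len(p))) {
    for (j in seq_len(p)) {
      inc <- r2(ord[seq_len(j)]) - r2(ord[seq_len(j - 1)])
      shares[ord[j]] <- shares[ord[j]] + inc
    }
  }
  shares / factorial(p)
}

grid_coords <- function(nx, ny, cell = 10)
  as.matrix(expand.grid(x_km = (seq_len(nx) - 0.5) * cell,
                        y_km = (seq_len(ny) - 0.5) * cell))

# tiny quadrat system over the A/B/C species pool plus an exotic pair,
# with two native and two exotic habitats, for pipeline unit tests
toy_system <- function() {
  sch <- toy_schema()
  spv <- rbind(toy_matrix_abc()$values,
               D = c(0L, 0L, 2L), E = c(1L, 1L, 3L))
  species <- resource_matrix(spv, c(rep("native", 3), rep("exotic", 2)),
                             "species", sch)
  hbv <- matrix(c(1L, 0L, 1L,
                  0L, 1L, 3L,
                  1L, 1L, 0L,
                  0L, 0L, 2L), 4, 3, byrow = TRUE,
                dimnames = list(c("h1", "h2", "h3", "h4"),
                                c("b1", "b2", "d1")))
  habitats <- resource_matrix(hbv, c("native", "native", "exotic", "exotic"),
                              "habitat", sch)
  all_h <- c("h1", "h2", "h3", "h4")
  info <- data.frame(id = c("q1", "q2", "q3"),
                     x_km = c(5, 15, 25), y_km = c(5, 5, 5),
                     effort = c(4, 9, 16), sea_fraction = 0)
  q <- quadrat_table(info,
                     species = list(q1 = c("B", "C", "D", "E"),
                                    q2 = c("A", "B", "D", "E"),
                                    q3 = c("A", "B", "C", "D", "E")),
                     habitats = list(q1 = all_h, q2 = all_h, q3 = all_h))
  list(species = species, habitats = habitats, quadrats = q)
}
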