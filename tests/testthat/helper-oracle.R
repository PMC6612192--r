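# Independent dense-matrix MCL oracle.
#
# Deliberately coded apart from the package implementation: the transition
# matrix is assembled entry by entry from the edge list, the loop works on
# the transpose (row-stochastic form), and clusters are read off as the
# connected components of the limit's non-zero pattern instead of through
# attractor assignment. For converged MCL runs both readings give the same
# partition, which is exactly what the agreement tests check.
oracle_mcl <- function(g, expansion = 2, inflation = 2, pruning = 0.02,
                       tol = 1e-10, maxit = 500) {
  nm <- sort(igraph::V(g)$name)
  n <- length(nm)
  A <- matrix(0, n, n, dimnames = list(nm, nm))
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) {
      w <- if (is.null(el$weight)) 1 else el$weight[i]
      A[el$from[i], el$to[i]] <- A[el$from[i], el$to[i]] + w
      A[el$to[i], el$from[i]] <- A[el$to[i], el$from[i]] + w
    }
  }
  for (i in seq_len(n)) A[i, i] <- A[i, i] + 1
  # row-stochastic transpose of the package's column-stochastic matrix
  R <- t(sweep(A, 2, colSums(A), "/"))
  for (it in seq_len(maxit)) {
    prev <- R
    P <- R
    for (k in seq_len(expansion - 1)) P <- P %*% R
    P <- P^inflation
    P <- P / rowSums(P)
    P[P < pruning] <- 0
    P <- P / rowSums(P)
    R <- P
    if (max(abs(R - prev)) < tol) break
  }
  # clusters = connected components of the limit's support
  supp <- (R > 0) | t(R > 0)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(supp, mode = "undirected"))
  stats::setNames(comp$membership, nm)
}

# canonical form of a partition for comparison: sorted list of sorted sets
partition_sets <- function(labels) {
  unname(lapply(sort(unique(labels)), function(l) sort(names(labels)[labels == l])))
}

same_partition <- function(a, b) {
  sa <- partition_sets(a)
  sb <- partition_sets(b)
  setequal(
    vapply(sa, paste, character(1), collapse = "|"),
    vapply(sb, paste, character(1), collapse = "|")
  )
}
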