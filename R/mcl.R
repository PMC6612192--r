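#' Markov Cluster algorithm parameters
#'
#' Parameters of the MCL loop: `expansion` is the matrix power applied each
#' iteration (flow spreading), `inflation` the entrywise power followed by
#' column renormalization (flow sharpening; larger values give finer
#' clusters), `pruning` the threshold below which entries are zeroed after
#' each inflation (with column renormalization after pruning). The reference
#' run for keyword co-trend networks uses expansion 2, inflation 2.0,
#' pruning 0.02.
#'
#' @param expansion Integer matrix power, >= 2 (default 2).
#' @param inflation Entrywise power, > 1 (default 2.0).
#' @param pruning Entries below this are zeroed each iteration, in `[0, 1)`
#'   (default 0.02).
#' @param max_iterations Iteration cap (default 100).
#' @param convergence_tol Maximum absolute entry change defining convergence
#'   (default 1e-6).
#' @param self_loops Self-loop policy applied before normalization:
#'   `"one"` adds weight 1 to every diagonal entry (classic MCL default),
#'   `"max"` adds each node's maximum incident edge weight, `"none"` adds
#'   nothing (isolated nodes then still receive a unit loop so their column
#'   is stochastic).
#' @return A list of class `mcl_params`.
#' @export
mcl_params <- function(expansion = 2L, inflation = 2.0, pruning = 0.02,
                       max_iterations = 100L, convergence_tol = 1e-6,
                       self_loops = c("one", "max", "none")) {
  self_loops <- match.arg(self_loops)
  stopifnot(expansion >= 2, inflation > 1, pruning >= 0, pruning < 1,
            max_iterations >= 1, convergence_tol > 0)
  structure(list(expansion = as.integer(expansion), inflation = inflation,
                 pruning = pruning,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 self_loops = self_loops),
            class = "mcl_params")
}

normalize_columns <- function(M, context = "matrix") {
  cs <- colSums(M)
  if (any(cs == 0)) {
    bad <- colnames(M)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("column collapsed to all-zero (", context, "): ",
         paste(bad, collapse = ", "),
         "; pruning threshold may be too aggressive", call. = FALSE)
  }
  sweep(M, 2L, cs, "/")
}

#' Column-stochastic transition matrix of a weighted graph
#'
#' Builds the matrix MCL iterates on: the weighted adjacency matrix with
#' self-loops added per the policy in `params`, columns normalized to sum
#' to one. Node order is fixed (lexicographic by name) for determinism;
#' isolated nodes become pure self-loop columns.
#'
#' @param g An undirected weighted igraph graph with named vertices.
#' @param params An [mcl_params()] object.
#' @return A column-stochastic matrix with node names on both dimnames.
#' @export
to_stochastic <- function(g, params = mcl_params()) {
  stopifnot(inherits(g, "igraph"))
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph is empty", call. = FALSE)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  ord <- order(nm)
  A <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g) > 0 &&
      "weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
      sparse = FALSE)
  dimnames(A) <- list(nm, nm)
  A <- A[ord, ord, drop = FALSE]
  loop <- switch(params$self_loops,
    one = rep(1, n),
    max = {
      mx <- apply(A, 2L, max)
      ifelse(mx > 0, mx, 1)
    },
    none = ifelse(colSums(A) > 0, 0, 1)
  )
  diag(A) <- diag(A) + loop
  normalize_columns(A, context = "to_stochastic")
}

#' Iterate the MCL process to its limit
#'
#' Repeats expansion (matrix power), inflation (entrywise power + column
#' renormalization) and pruning (zero entries below the threshold, then
#' renormalize) until the largest entry change between consecutive
#' iterations falls below `convergence_tol` or the iteration cap is hit.
#'
#' @param M A column-stochastic matrix (e.g. from [to_stochastic()]).
#' @param params An [mcl_params()] object.
#' @return The limit matrix, column-stochastic, with attributes
#'   `iterations` (count performed) and `converged` (logical).
#' @export
mcl_iterate <- function(M, params = mcl_params()) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(colSums(M) - 1)) > 1e-8) {
    stop("input matrix is not column-stochastic", call. = FALSE)
  }
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iterations)) {
    iters <- it
    prev <- M
    # expansion: M <- M^e
    E <- M
    for (p in seq_len(params$expansion - 1L)) E <- E %*% M
    # inflation: entrywise power, renormalize
    M <- normalize_columns(E^params$inflation, context = "inflation")
    # pruning: zero small entries, renormalize
    if (params$pruning > 0) {
      M[M < params$pruning] <- 0
      M <- normalize_columns(M, context = "pruning")
    }
    if (max(abs(M - prev)) < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", params$max_iterations,
            " iterations", call. = FALSE)
  }
  attr(M, "iterations") <- iters
  attr(M, "converged") <- converged
  M
}

#' Read clusters off an MCL limit matrix
#'
#' Attractors are nodes with positive diagonal mass in the limit. Attractor
#' rows whose supports overlap in any column belong to one attractor system
#' (overlap resolution, via union-find); every node is then assigned to the
#' system of the attractor carrying the largest value in its column, with
#' ties broken toward the lexicographically smallest attractor. The result
#' is an exact partition of the nodes.
#'
#' @param limit Limit matrix from [mcl_iterate()] (dimnames = node names).
#' @param nodes Optional node-name vector (defaults to `rownames(limit)`).
#' @return An object of class `clustering`: list with `clusters` (list of
#'   character vectors, ordered by decreasing size then by smallest member)
#'   and `labels` (named integer vector, node → cluster index).
#' @export
extract_clusters <- function(limit, nodes = rownames(limit)) {
  stopifnot(is.matrix(limit), nrow(limit) == ncol(limit))
  n <- nrow(limit)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  attractors <- which(diag(limit) > 0)
  if (length(attractors) == 0L) {
    stop("limit matrix has no attractors (no positive diagonal)",
         call. = FALSE)
  }
  # union-find over attractors sharing column support
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (j in seq_len(n)) {
    sup <- attractors[limit[attractors, j] > 0]
    if (length(sup) > 1L) {
      r <- find(sup[1])
      for (s in sup[-1]) {
        rs <- find(s)
        if (rs != r) parent[rs] <- r
      }
    }
  }
  att_system <- vapply(attractors, find, integer(1))
  # assign each node to the system of its strongest attractor
  assign_sys <- integer(n)
  for (j in seq_len(n)) {
    w <- limit[attractors, j]
    if (all(w <= 0)) {
      stop("node '", nodes[j], "' has no positive attractor entry in its ",
           "column", call. = FALSE)
    }
    best <- which(w == max(w))
    if (length(best) > 1L) {
      best <- best[order(nodes[attractors[best]])][1]
    }
    assign_sys[j] <- att_system[best]
  }
  sys_ids <- unique(assign_sys)
  clusters <- lapply(sys_ids, function(sid) sort(nodes[assign_sys == sid]))
  # deterministic ordering: size desc, then lexicographically smallest member
  ord <- order(-lengths(clusters),
               vapply(clusters, `[[`, character(1), 1L))
  clusters <- clusters[ord]
  labels <- integer(n)
  names(labels) <- nodes
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  structure(list(clusters = clusters, labels = labels),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat("Clustering with", length(x$clusters), "cluster(s) over",
      length(x$labels), "node(s)\n")
  for (k in seq_along(x$clusters)) {
    members <- x$clusters[[k]]
    shown <- paste(utils::head(members, 8), collapse = ", ")
    if (length(members) > 8) shown <- paste0(shown, ", ...")
    cat(sprintf("  %2d (n=%d): %s\n", k, length(members), shown))
  }
  invisible(x)
}

#' Cluster a co-trend network with MCL
#'
#' Composition of [to_stochastic()], [mcl_iterate()] and
#' [extract_clusters()]; deterministic for a fixed graph and parameter set.
#' Isolated nodes come out as singleton clusters.
#'
#' @param g An undirected weighted igraph graph with named vertices.
#' @param params An [mcl_params()] object.
#' @return A `clustering` (see [extract_clusters()]).
#' @export
mcl_cluster <- function(g, params = mcl_params()) {
  M <- to_stochastic(g, params)
  limit <- mcl_iterate(M, params)
  extract_clusters(limit)
}
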