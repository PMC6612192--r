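#' Build the keyword co-trend network
#'
#' Nodes are keywords whose total frequency reaches `min_freq`; an
#' undirected edge connects two keywords when the weighted Jaccard
#' similarity of their annual frequency rows is at least `min_sim` (closed
#' bounds on both thresholds). The edge weight is that similarity, so two
#' keywords are linked when their appearance counts track each other over
#' the years — similarity of temporal behaviour, not within-article
#' co-occurrence. Qualifying nodes with no qualifying edge are retained as
#' isolates (high-volume keywords whose trajectory resembles nothing else
#' end up as singleton clusters).
#'
#' Pairwise similarities are computed exactly from row sums and Manhattan
#' distances: for non-negative rows,
#' `sum(pmin) = (r_i + r_j - d_ij)/2` and `sum(pmax) = (r_i + r_j + d_ij)/2`
#' with `d_ij` the L1 distance, so no explicit pair loop is needed.
#'
#' @param m An [build_annual_matrix()] result.
#' @param min_freq Minimum total keyword frequency for a node (default 100).
#' @param min_sim Minimum row similarity for an edge (default 0.57).
#' @return An undirected [igraph::igraph] graph with vertex attributes
#'   `name` and `frequency` and edge attribute `weight`.
#' @export
build_cotrend_network <- function(m, min_freq = 100, min_sim = 0.57) {
  stopifnot(inherits(m, "annual_matrix"), min_freq >= 1,
            min_sim >= 0, min_sim <= 1)
  totals <- rowSums(m$counts)
  keep <- totals >= min_freq
  A <- m$counts[keep, , drop = FALSE]
  totals <- totals[keep]
  k <- nrow(A)
  verts <- data.frame(name = rownames(A), frequency = as.integer(totals),
                      stringsAsFactors = FALSE)
  if (k < 2L) {
    return(igraph::graph_from_data_frame(
      data.frame(from = character(0), to = character(0), weight = numeric(0)),
      directed = FALSE, vertices = verts))
  }
  d <- as.matrix(stats::dist(A, method = "manhattan"))
  rs <- outer(totals, totals, `+`)
  jac <- (rs - d) / (rs + d)            # rs + d > 0 since totals >= min_freq
  pairs <- which(upper.tri(jac) & jac >= min_sim, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(A)[pairs[, 1]],
    to = rownames(A)[pairs[, 2]],
    weight = jac[pairs],
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Export / import a co-trend network
#'
#' Writes the network in one of three interchange formats: `"graphml"`
#' (via igraph, loadable by Gephi), `"gexf"` (GEXF 1.2, written directly,
#' with the node `frequency` attribute declared and edge weights on the
#' `weight` attribute) or `"edgelist"` (TSV of `from`, `to`, `weight`,
#' preceded by `#node <name> <frequency>` comment lines so isolated nodes
#' survive the round trip). `import_network()` reads all three back;
#' export followed by import preserves the node set, edge set and weights
#' to at least six decimals.
#'
#' @param g An igraph graph with `name`/`frequency` vertex attributes and a
#'   `weight` edge attribute.
#' @param path Output (input) file path.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist"`; inferred from
#'   the extension on import when `"auto"`.
#' @return `path` invisibly (export); an igraph graph (import).
#' @export
export_network <- function(g, path, format = c("graphml", "gexf",
                                               "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "gexf") {
    write_gexf(g, path)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    vn <- igraph::V(g)$name
    vf <- igraph::V(g)$frequency
    writeLines(sprintf("#node\t%s\t%d", vn, vf), con)
    el <- igraph::as_data_frame(g, what = "edges")
    writeLines("from\tto\tweight", con)
    if (nrow(el) > 0) {
      writeLines(sprintf("%s\t%s\t%.10g", el$from, el$to, el$weight), con)
    }
  }
  invisible(path)
}

write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", mode = "static",
                               defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "frequency",
                      type = "integer")
  nodes <- xml2::xml_add_child(graph, "nodes")
  vn <- igraph::V(g)$name
  vf <- igraph::V(g)$frequency
  for (i in seq_along(vn)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vn[i], label = vn[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = as.character(vf[i]))
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) {
      xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                          source = el$from[i], target = el$to[i],
                          weight = sprintf("%.10g", el$weight[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  vn <- xml2::xml_attr(node_els, "id")
  vf <- vapply(node_els, function(nd) {
    av <- xml2::xml_find_first(nd, ".//g:attvalue", ns)
    as.integer(xml2::xml_attr(av, "value"))
  }, integer(1))
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    weight = as.numeric(xml2::xml_attr(edge_els, "weight")),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = vn, frequency = vf,
                          stringsAsFactors = FALSE))
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("auto", "graphml", "gexf",
                                            "edgelist")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      graphml = "graphml", gexf = "gexf", tsv = , txt = "edgelist",
      stop("cannot infer network format from extension '.", ext, "'",
           call. = FALSE))
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    igraph::V(g)$frequency <- as.integer(igraph::V(g)$frequency)
    g
  } else if (format == "gexf") {
    read_gexf(path)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    node_lines <- lines[startsWith(lines, "#node\t")]
    parts <- strsplit(node_lines, "\t", fixed = TRUE)
    verts <- data.frame(
      name = vapply(parts, `[[`, character(1), 2L),
      frequency = as.integer(vapply(parts, `[[`, character(1), 3L)),
      stringsAsFactors = FALSE
    )
    body <- lines[!startsWith(lines, "#")]
    edges <- if (length(body) > 1L) {
      ep <- strsplit(body[-1], "\t", fixed = TRUE)
      data.frame(
        from = vapply(ep, `[[`, character(1), 1L),
        to = vapply(ep, `[[`, character(1), 2L),
        weight = as.numeric(vapply(ep, `[[`, character(1), 3L)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(from = character(0), to = character(0),
                 weight = numeric(0))
    }
    igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  }
}
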