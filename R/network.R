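#' Build the support-weighted multimorbidity network for a stratum
#'
#' Nodes are the 15 panel diseases with their stratum prevalence (node
#' size) and node strength (node colour); edges are unordered disease pairs
#' weighted by support (the proportion of the stratum carrying both
#' diseases). Node strength is the support row-sum over ALL 14 partner
#' diseases, \eqn{s_i = \sum_{j \ne i} w_{ij}}, computed before any display
#' threshold, so it is invariant to `edge_threshold`; the threshold only
#' controls which edges are exported for display.
#'
#' @param cohort A `morb_cohort`.
#' @param stratum A [stratum_spec()].
#' @param edge_threshold Minimum support for an edge to appear in the
#'   exported display graph (default 0: all positive-support edges).
#' @return A `morb_network`: list with `stratum`, `n`, `edge_threshold`,
#'   `nodes` (data.frame disease, prevalence, strength) and `edges`
#'   (data.frame from, to, support over all 105 pairs).
#' @export
build_network <- function(cohort, stratum = stratum_spec(),
                          edge_threshold = 0) {
  .assert(edge_threshold >= 0 && edge_threshold <= 1,
          "edge_threshold must be in [0, 1]")
  pc <- pair_counts(cohort, stratum)
  d <- disease_panel()
  support <- pc$joint / pc$n
  diag(support) <- 0
  nodes <- data.frame(disease = d,
                      prevalence = as.numeric(pc$marginal / pc$n),
                      strength = as.numeric(rowSums(support)),
                      row.names = NULL)
  idx <- .pair_index()
  edges <- data.frame(from = d[idx$i], to = d[idx$j],
                      support = support[cbind(idx$i, idx$j)],
                      row.names = NULL)
  structure(list(stratum = stratum, n = pc$n,
                 edge_threshold = edge_threshold,
                 nodes = nodes, edges = edges),
            class = "morb_network")
}

#' @export
print.morb_network <- function(x, ...) {
  cat(sprintf("<morb_network: stratum %s, n = %d, %d nodes, %d edges >= %.3g>\n",
              format(x$stratum), x$n, nrow(x$nodes),
              sum(x$edges$support >= max(x$edge_threshold,
                                         .Machine$double.xmin)),
              x$edge_threshold))
  top <- strength_ranking(x)
  cat("  strongest nodes:", paste(utils::head(top, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Diseases ranked by node strength
#'
#' @param network A `morb_network`.
#' @return Character vector of disease labels, by descending strength
#'   (ties broken alphabetically).
#' @export
strength_ranking <- function(network) {
  stopifnot(inherits(network, "morb_network"))
  nd <- network$nodes
  nd$disease[order(-nd$strength, nd$disease)]
}

# edges retained for display under the network's threshold
.display_edges <- function(network) {
  e <- network$edges
  e[e$support >= network$edge_threshold & e$support > 0, , drop = FALSE]
}

#' Export a multimorbidity network
#'
#' Serialises nodes (prevalence, strength) and the display edges (support
#' at or above the network's `edge_threshold`) in deterministic panel
#' order, so any plotting tool can reproduce the network figure.
#' `"graphml"` writes a single GraphML file (via igraph) with node
#' attributes `prevalence` and `strength` and edge attribute `support`;
#' `"edgelist"` writes a from/to/support CSV at `path` plus a node
#' attribute table (disease, prevalence, strength) at
#' `<path-sans-ext>_nodes.csv`.
#'
#' @param network A `morb_network`.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(network, "morb_network"))
  format <- match.arg(format)
  edges <- .display_edges(network)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.csv(edges, path, row.names = FALSE)
    utils::write.csv(network$nodes, .nodes_path(path), row.names = FALSE)
  }
  invisible(path)
}

.nodes_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_nodes.csv")
}

#' Re-import an exported network
#'
#' Inverse of [export_graph()] for round-trip checks and downstream
#' plotting: returns the node and display-edge tables.
#'
#' @param path Path given to [export_graph()].
#' @param format `"edgelist"` or `"graphml"`.
#' @return A list with `nodes` (disease, prevalence, strength) and `edges`
#'   (from, to, support).
#' @export
import_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(disease = igraph::V(g)$name,
                        prevalence = igraph::V(g)$prevalence,
                        strength = igraph::V(g)$strength,
                        row.names = NULL)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(from = el$from, to = el$to, support = el$support,
                        row.names = NULL)
  } else {
    edges <- utils::read.csv(path, stringsAsFactors = FALSE)
    nodes <- utils::read.csv(.nodes_path(path), stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}
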