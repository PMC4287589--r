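# Evidence-weighted TF-TF interaction network: assembly from a PPI edge
# list, paralog augmentation, summaries, and SIF/GraphML export.

#' Build the TF-TF interaction network
#'
#' Keeps edges whose both endpoints are in `tf_list`, sums duplicate
#' evidence rows per unordered pair into an integer `evidence` weight, and
#' takes the nodes from the retained edge endpoints (isolated TFs are not
#' added here; see [add_paralogs()]).
#'
#' @param tf_list TF ids admitted to the network.
#' @param ppi_edges data.frame `tf_a`, `tf_b` and optionally `evidence`
#'   (defaults to 1 per row).
#' @return a `TFNetwork`: list with `nodes` (tf, paralog_added) and
#'   `edges` (tf_a, tf_b, evidence).
#' @export
build_tf_network <- function(tf_list, ppi_edges) {
  e <- ppi_edges
  if (is.null(e$evidence)) e$evidence <- 1L
  keep <- e$tf_a %in% tf_list & e$tf_b %in% tf_list
  e <- e[keep, , drop = FALSE]
  if (nrow(e)) {
    a <- pmin(e$tf_a, e$tf_b); b <- pmax(e$tf_a, e$tf_b)
    agg <- stats::aggregate(list(evidence = e$evidence),
                            by = list(tf_a = a, tf_b = b), FUN = sum)
    edges <- agg[order(agg$tf_a, agg$tf_b), , drop = FALSE]
    rownames(edges) <- NULL
    edges$evidence <- as.integer(edges$evidence)
  } else {
    edges <- data.frame(tf_a = character(0), tf_b = character(0),
                        evidence = integer(0))
  }
  tf_nodes <- sort(unique(c(edges$tf_a, edges$tf_b)))
  nodes <- data.frame(tf = tf_nodes,
                      paralog_added = rep(FALSE, length(tf_nodes)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "TFNetwork")
}

#' @export
print.TFNetwork <- function(x, ...) {
  cat(sprintf("TFNetwork: %d nodes, %d edges (%d paralog-added)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$paralog_added)))
  invisible(x)
}

#' Add unconnected paralogs of connected nodes
#'
#' TFs from `tf_list` that are absent from the network but are paralogs of
#' a connected node are added as isolated, flagged nodes; no edges are
#' added.
#'
#' @param net a [build_tf_network()] object.
#' @param paralogy_table data.frame `tf_a`, `tf_b` of paralog pairs.
#' @param tf_list the admissible TF ids.
#' @return the augmented `TFNetwork`.
#' @export
add_paralogs <- function(net, paralogy_table, tf_list) {
  if (!nrow(paralogy_table)) return(net)
  connected <- net$nodes$tf
  candidates <- setdiff(tf_list, connected)
  qualifies <- vapply(candidates, function(tf) {
    partners <- c(paralogy_table$tf_b[paralogy_table$tf_a == tf],
                  paralogy_table$tf_a[paralogy_table$tf_b == tf])
    any(partners %in% connected)
  }, logical(1))
  add <- candidates[qualifies]
  if (length(add))
    net$nodes <- rbind(net$nodes,
                       data.frame(tf = add, paralog_added = TRUE,
                                  stringsAsFactors = FALSE))
  net
}

#' Summarize a TF network
#' @param net a `TFNetwork`.
#' @return list: `n_nodes`, `n_edges`, `n_paralog_nodes`, `total_evidence`,
#'   and a `degree` data.frame.
#' @export
summarize_network <- function(net) {
  deg <- table(factor(c(net$edges$tf_a, net$edges$tf_b),
                      levels = net$nodes$tf))
  list(n_nodes = nrow(net$nodes),
       n_edges = nrow(net$edges),
       n_paralog_nodes = sum(net$nodes$paralog_added),
       total_evidence = sum(net$edges$evidence),
       degree = data.frame(tf = names(deg), degree = as.integer(deg),
                           stringsAsFactors = FALSE))
}

#' Export a TF network as SIF
#' @param net a `TFNetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  lines <- sprintf("%s pp %s", net$edges$tf_a, net$edges$tf_b)
  iso <- setdiff(net$nodes$tf, c(net$edges$tf_a, net$edges$tf_b))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Export a TF network as GraphML
#'
#' Nodes carry the `paralog_added` flag, edges the `evidence` weight.
#'
#' @param net a `TFNetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges)) net$edges else
      data.frame(tf_a = character(0), tf_b = character(0)),
    directed = FALSE, vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
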