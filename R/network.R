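# Static pathway-hierarchy network export and top-pathway clustering.

#' Export model results onto the pathway hierarchy
#'
#' Builds a node/edge representation of the pathway parent-child DAG
#' annotated with model results: coverage, importance and adjusted p-value
#' where available, and each node's root pathway (the ancestor without a
#' parent, first in topological order on ties). Pathways in the results but
#' absent from the hierarchy are emitted as isolated nodes with a message.
#' When `path` is given, `<path>_nodes.tsv`, `<path>_edges.tsv` and
#' `<path>.graphml` are written.
#'
#' @param results A tibble with `pathway_id` and optionally `pathway_name`,
#'   `coverage`, `importance`, `p_adjusted` (e.g. [mb_vip()] joined with a
#'   [permutation_pvalues()] table and [filter_coverage()] counts).
#' @param hierarchy Edge tibble from [read_hierarchy()].
#' @param path Optional output path stem.
#' @return A list: `nodes` (tibble), `edges` (tibble), `graph` (igraph).
#' @export
export_network <- function(results, hierarchy, path = NULL) {
  stopifnot("pathway_id" %in% names(results))
  node_ids <- union(unique(c(hierarchy$parent, hierarchy$child)),
                    results$pathway_id)
  orphan <- setdiff(results$pathway_id,
                    c(hierarchy$parent, hierarchy$child))
  if (length(orphan) > 0) {
    rlang::inform(paste0(length(orphan),
                         " result pathway(s) absent from the hierarchy; ",
                         "emitted without parent."))
  }
  g <- igraph::graph_from_data_frame(hierarchy, directed = TRUE,
                                     vertices = node_ids)
  nodes <- tibble::tibble(pathway_id = node_ids)
  nodes$root_pathway <- dag_roots(g, node_ids)
  keep <- intersect(c("pathway_id", "pathway_name", "coverage",
                      "importance", "p_adjusted"), names(results))
  nodes <- dplyr::left_join(nodes, results[, keep, drop = FALSE],
                            by = "pathway_id")
  edges <- tibble::as_tibble(hierarchy)
  for (col in setdiff(names(nodes), "pathway_id")) {
    g <- igraph::set_vertex_attr(g, col, value = nodes[[col]])
  }
  if (!is.null(path)) {
    readr::write_tsv(nodes, paste0(path, "_nodes.tsv"))
    readr::write_tsv(edges, paste0(path, "_edges.tsv"))
    igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  }
  list(nodes = nodes, edges = edges, graph = g)
}

# Root (in-degree 0 ancestor) reachable from each node; ties broken by the
# first root in topological order. Isolated nodes are their own root.
dag_roots <- function(g, node_ids) {
  roots <- node_ids[igraph::degree(g, mode = "in") == 0]
  topo <- names(igraph::topo_sort(g, mode = "out"))
  roots <- roots[order(match(roots, topo))]
  res <- character(length(node_ids))
  reach <- lapply(roots, function(r) {
    names(igraph::subcomponent(g, r, mode = "out"))
  })
  for (i in seq_along(node_ids)) {
    hit <- which(vapply(reach, function(s) node_ids[i] %in% s, logical(1)))
    res[i] <- if (length(hit) > 0) roots[hit[1]] else NA_character_
  }
  res
}

#' Pathways within a given distance of a target
#'
#' Neighbourhood query on the hierarchy graph, ignoring edge direction.
#'
#' @param network Output of [export_network()] (or an igraph object).
#' @param target_id Pathway id at the centre.
#' @param d Maximum number of steps.
#' @return Character vector of pathway ids within distance `d` (including
#'   the target).
#' @export
network_neighborhood <- function(network, target_id, d) {
  g <- if (igraph::is_igraph(network)) network else network$graph
  nb <- igraph::ego(g, order = d, nodes = target_id, mode = "all")[[1]]
  names(nb)
}

#' Cluster samples and pathways on top pathway scores
#'
#' Hierarchical clustering (Euclidean distance, Ward linkage) of the
#' samples and of the pathways on the score matrix restricted to a set of
#' top-ranked pathways — the input for an annotated heatmap of model
#' results.
#'
#' @param scores A pathway score tibble (`sample_id` + score columns).
#' @param top_ids Pathway columns to keep.
#' @param linkage Linkage method (default `"ward"`, mapped to `ward.D2`).
#' @param metric Distance metric (default `"euclidean"`).
#' @return A list: `sample_hclust`, `pathway_hclust` (each `NULL` when the
#'   axis has fewer than 2 items), `sample_order`, `pathway_order`, and the
#'   restricted `matrix`.
#' @export
cluster_top_pathways <- function(scores, top_ids, linkage = "ward",
                                 metric = "euclidean") {
  m <- block_to_matrix(scores)
  missing <- setdiff(top_ids, colnames(m))
  if (length(missing) > 0) {
    rlang::abort(paste0("Score columns not found: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  m <- m[, top_ids, drop = FALSE]
  method <- if (linkage == "ward") "ward.D2" else linkage
  cl_axis <- function(x) {
    if (nrow(x) < 2) return(NULL)
    stats::hclust(stats::dist(x, method = metric), method = method)
  }
  sh <- cl_axis(m)
  ph <- cl_axis(t(m))
  list(sample_hclust = sh,
       pathway_hclust = ph,
       sample_order = if (is.null(sh)) rownames(m) else
         rownames(m)[sh$order],
       pathway_order = if (is.null(ph)) colnames(m) else
         colnames(m)[ph$order],
       matrix = m)
}
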