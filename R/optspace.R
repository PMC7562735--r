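# Optimization space: the disease-targets-components (DTC) network is
# the PPI induced on the union of predicted component targets and
# pathogenic genes; its hubs (degree strictly above the network average)
# form the optimization space of effective proteins, partitioned into
# essential-common, disease-specific and component-specific categories.

#' Build the disease-targets-components network
#'
#' Induces the PPI subgraph on the union of predicted target genes and
#' pathogenic (disease) genes; only genes present in the PPI node set can
#' appear. Each node carries logical flags `is_target` and `is_disease`
#' and a `category`: `essential_common` (target and disease gene),
#' `disease_specific` (disease gene only), `component_specific` (target
#' only). Components themselves are not graph nodes — the network is a
#' protein graph; component linkage lives in the component-target
#' network.
#'
#' @param ppi igraph PPI network ([load_ppi()]).
#' @param targets Character vector of predicted target genes.
#' @param disease Character vector of pathogenic genes.
#' @return An igraph graph with vertex attributes `is_target`,
#'   `is_disease`, `category`.
#' @export
build_dtc <- function(ppi, targets, disease) {
  stopifnot(igraph::is_igraph(ppi))
  if (!length(targets) || !length(disease))
    stop("targets and disease gene sets must be non-empty", call. = FALSE)
  keep <- intersect(union(targets, disease), igraph::V(ppi)$name)
  if (!length(keep)) stop("empty union: no target or disease gene maps to PPI",
                          call. = FALSE)
  g <- igraph::induced_subgraph(ppi, keep)
  nm <- igraph::V(g)$name
  igraph::V(g)$is_target <- nm %in% targets
  igraph::V(g)$is_disease <- nm %in% disease
  igraph::V(g)$category <- ifelse(
    igraph::V(g)$is_target & igraph::V(g)$is_disease, "essential_common",
    ifelse(igraph::V(g)$is_disease, "disease_specific", "component_specific"))
  message(sprintf("disease-targets-components network: %d nodes, %d edges",
                  igraph::vcount(g), igraph::ecount(g)))
  g
}

#' Average node degree
#'
#' @param net An igraph graph with at least one node.
#' @return `2|E| / |N|`.
#' @export
average_degree <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("empty graph", call. = FALSE)
  2 * igraph::ecount(net) / igraph::vcount(net)
}

#' Extract the optimization space of effective proteins
#'
#' Keeps the hub nodes of the disease-targets-components network — nodes
#' whose degree is strictly greater than the network's average degree —
#' and, under the default edge rule, the subgraph they induce. The
#' retained nodes are the effective proteins.
#'
#' @param dtc Graph from [build_dtc()].
#' @param edge_rule `"induced"` (default; both endpoints must be hubs) or
#'   `"incident"` (any edge touching a hub is kept in the edge table; the
#'   node set is still the hubs, so non-hub neighbours appear only as
#'   edge endpoints).
#' @return An object of class `opt_space`: list with `nodes` (data frame:
#'   gene, category, degree — degree measured in the DTC network),
#'   `edges` (data frame: geneA, geneB), `graph` (induced igraph, under
#'   the induced rule), `d_avg`, `k` (DTC node count) and `edge_rule`.
#' @export
extract_optspace <- function(dtc, edge_rule = c("induced", "incident")) {
  edge_rule <- match.arg(edge_rule)
  d_avg <- average_degree(dtc)
  deg <- igraph::degree(dtc)
  hubs <- names(deg)[deg > d_avg]
  if (!length(hubs))
    stop("no node exceeds the average degree; the graph appears degree-regular",
         call. = FALSE)
  nodes <- data.frame(
    gene = hubs,
    category = igraph::V(dtc)$category[match(hubs, igraph::V(dtc)$name)],
    degree = as.integer(deg[hubs]),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$degree, nodes$gene), ]
  rownames(nodes) <- NULL
  sub <- igraph::induced_subgraph(dtc, hubs)
  if (edge_rule == "induced") {
    ed <- igraph::as_data_frame(sub, what = "edges")[, c("from", "to")]
  } else {
    all_ed <- igraph::as_data_frame(dtc, what = "edges")[, c("from", "to")]
    ed <- all_ed[all_ed$from %in% hubs | all_ed$to %in% hubs, ]
  }
  names(ed) <- c("geneA", "geneB")
  ed <- ed[order(ed$geneA, ed$geneB), ]
  rownames(ed) <- NULL
  message(sprintf(
    "optimization space (%s rule): %d effective proteins, %d edges (D_avg = %.3f over %d nodes)",
    edge_rule, nrow(nodes), nrow(ed), d_avg, igraph::vcount(dtc)))
  structure(list(nodes = nodes, edges = ed, graph = sub, d_avg = d_avg,
                 k = igraph::vcount(dtc), edge_rule = edge_rule),
            class = "opt_space")
}

#' @export
print.opt_space <- function(x, ...) {
  cat(sprintf("<optimization space> %d effective proteins, %d edges (rule: %s)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_rule))
  print(table(x$nodes$category))
  invisible(x)
}

#' Per-category effective-protein lists
#'
#' @param space An `opt_space` from [extract_optspace()].
#' @return A named list of three disjoint, sorted gene vectors —
#'   `essential_common`, `disease_specific`, `component_specific` —
#'   whose union is the effective-protein set.
#' @export
category_tables <- function(space) {
  stopifnot(inherits(space, "opt_space"))
  cats <- c("essential_common", "disease_specific", "component_specific")
  out <- lapply(cats, function(cc) sort(space$nodes$gene[space$nodes$category == cc]))
  names(out) <- cats
  out
}
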