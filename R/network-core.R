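# Disease gene regulatory network construction: read a PPI edge list,
# read literature-weighted disease genes, and induce the weighted gene
# regulatory network of the disease on their intersection.

#' Load a protein-protein interaction network
#'
#' Reads a two-column edge list (TSV or SIF-like whitespace-delimited text,
#' one interaction per line, gene symbols). Self-loops and duplicate edges
#' (in either orientation) are removed so the result is an undirected
#' simple graph. Symbols are matched exactly after trimming whitespace; no
#' alias resolution is attempted.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::igraph] graph whose vertex names
#'   are gene symbols.
#' @export
load_ppi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PPI file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop("malformed PPI line ", bad[1], ": ", lines[bad[1]], call. = FALSE)
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  # drop a header line if present
  if (identical(tolower(a[1]), "genea") || identical(tolower(a[1]), "gene_a")) {
    a <- a[-1]; b <- b[-1]
  }
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  message(sprintf("PPI: %d nodes, %d edges after simplification",
                  igraph::vcount(g), igraph::ecount(g)))
  g
}

#' Load a weighted disease-gene table
#'
#' Reads a two-column table (gene, weight) where the weight is a
#' non-negative integer — typically the number of literature reports
#' linking the gene to the disease, as in a DisGeNET-style export.
#' Duplicated genes keep their maximum weight.
#'
#' @param path Path to the TSV file (header optional).
#' @return A data frame with columns `gene` and `weight`.
#' @export
load_disease_genes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("disease gene file needs two columns (gene, weight)", call. = FALSE)
  names(df)[1:2] <- c("gene", "weight")
  df$gene <- trimws(df$gene)
  df$weight <- as.integer(df$weight)
  if (any(is.na(df$weight)) || any(df$weight < 0))
    stop("disease gene weights must be non-negative integers", call. = FALSE)
  df <- df[order(df$gene, -df$weight), c("gene", "weight")]
  df <- df[!duplicated(df$gene), ]
  rownames(df) <- NULL
  df
}

#' Build the weighted gene regulatory network of the disease
#'
#' Induces the PPI subgraph on the disease genes that are present in the
#' PPI node set, attaching the literature-report count as a vertex
#' `weight` attribute. Disease genes absent from the PPI are dropped (and
#' counted in a message): a gene with no interaction evidence cannot
#' contribute network structure.
#'
#' @param ppi An igraph PPI network from [load_ppi()].
#' @param disease A data frame with columns `gene`, `weight`
#'   ([load_disease_genes()]).
#' @return An undirected igraph graph with a numeric vertex attribute
#'   `weight`.
#' @export
build_weighted_network <- function(ppi, disease) {
  stopifnot(igraph::is_igraph(ppi), is.data.frame(disease))
  keep <- intersect(disease$gene, igraph::V(ppi)$name)
  if (!length(keep)) stop("no disease genes map to PPI", call. = FALSE)
  dropped <- setdiff(disease$gene, keep)
  if (length(dropped))
    message(sprintf("%d of %d disease genes absent from the PPI were dropped",
                    length(dropped), nrow(disease)))
  g <- igraph::induced_subgraph(ppi, keep)
  w <- disease$weight[match(igraph::V(g)$name, disease$gene)]
  igraph::V(g)$weight <- as.numeric(w)
  message(sprintf("weighted gene regulatory network: %d nodes, %d edges",
                  igraph::vcount(g), igraph::ecount(g)))
  g
}

#' Per-node degree table and mean degree
#'
#' @param net An igraph graph with at least one node.
#' @return A list with `table` (data frame: gene, degree, sorted by degree
#'   descending then gene) and `mean_degree` (= 2|E|/|N|).
#' @export
degree_summary <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("empty graph", call. = FALSE)
  d <- igraph::degree(net)
  tab <- data.frame(gene = names(d), degree = as.integer(d), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, tab$gene), ]
  rownames(tab) <- NULL
  list(table = tab, mean_degree = 2 * igraph::ecount(net) / igraph::vcount(net))
}

#' Write a network as edge-list + node-attribute TSVs
#'
#' @param net An igraph graph (vertex attributes are written alongside).
#' @param edge_path,node_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_network_tsv <- function(net, edge_path, node_path) {
  ed <- igraph::as_data_frame(net, what = "edges")[, c("from", "to")]
  names(ed) <- c("geneA", "geneB")
  ed <- ed[order(ed$geneA, ed$geneB), ]
  write_tsv(ed, edge_path)
  nd <- igraph::as_data_frame(net, what = "vertices")
  names(nd)[names(nd) == "name"] <- "gene"
  nd <- nd[order(nd$gene), , drop = FALSE]
  write_tsv(nd, node_path)
  invisible(c(edge_path, node_path))
}
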