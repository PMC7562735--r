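# Hypergeometric over-representation analysis against GMT gene sets and
# the pathway-coverage statistic used to compare enrichment profiles.

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' The background universe defaults to the union of all pathway genes and
#' may be overridden.
#'
#' @param path Path to the .gmt file.
#' @param universe Optional character vector of background genes; must
#'   contain every pathway gene.
#' @return An object of class `pathway_collection`: list with `sets`
#'   (named list of gene vectors), `descriptions`, `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has no genes", call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicated pathway names in GMT", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  pathway_collection(sets,
                     descriptions = stats::setNames(vapply(fields, `[[`, "", 2L), nm),
                     universe = universe)
}

#' Construct a pathway collection
#'
#' @param sets Named list of non-empty gene-symbol vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @param universe Background gene universe; default is the union of all
#'   set members.
#' @return A `pathway_collection`.
#' @export
pathway_collection <- function(sets, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  if (any(lengths(sets) == 0L)) stop("empty pathway in collection", call. = FALSE)
  sets <- lapply(sets, unique)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(universe)
    outside <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(outside))
      stop("universe must contain every pathway gene; missing e.g. ",
           outside[1], call. = FALSE)
  }
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway collection> %d sets, universe of %d genes; sizes %d-%d\n",
              length(x$sets), length(x$universe),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, the upper-tail hypergeometric probability of seeing
#' at least the observed overlap between the query and the pathway, with
#' the collection's universe as the sampling population: `P(X >= k)` for
#' X hypergeometric(pathway size, universe size - pathway size, query
#' size), where the query is first intersected with the universe.
#' Significance follows the raw p-value cutoff by default;
#' Benjamini-Hochberg adjustment is reported and may drive the call.
#'
#' @param query Character vector of query genes.
#' @param pathways A `pathway_collection`.
#' @param alpha Significance cutoff (default 0.05).
#' @param adjust `"none"` (default; raw p drives the significance call)
#'   or `"BH"`.
#' @return Data frame (pathway, overlap, pathway_size, query_size,
#'   universe_size, p, p_adj, significant), ordered by p ascending.
#'   `p_adj` is always the BH value, whatever drives the call.
#' @export
ora <- function(query, pathways, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(pathways, "pathway_collection"))
  adjust <- match.arg(adjust)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  q <- intersect(unique(query), pathways$universe)
  if (!length(q))
    stop("query does not intersect the universe", call. = FALSE)
  N <- length(pathways$universe); n <- length(q)
  K <- lengths(pathways$sets)
  k <- vapply(pathways$sets, function(s) length(intersect(q, s)), 1L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    pathway = names(pathways$sets),
    overlap = as.integer(k),
    pathway_size = as.integer(K),
    query_size = n,
    universe_size = N,
    p = as.numeric(p),
    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- if (adjust == "BH") out$p_adj < alpha else out$p < alpha
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Significant pathway names from an ORA result
#'
#' @param result Data frame from [ora()].
#' @return Character vector of pathways called significant.
#' @export
significant_pathways <- function(result) {
  result$pathway[result$significant]
}

#' Pathway-coverage statistic between two enrichment profiles
#'
#' The fraction of reference pathways (`setB`) that are also found in
#' `setA`: `|A intersect B| / |B|` — the Venn-diagram consistency measure
#' used to validate one gene set's enrichment profile against another's.
#'
#' @param setA,setB Character vectors of significant pathway names; B is
#'   the reference profile and must be non-empty.
#' @return List with `coverage` (fraction), `coverage_pct` (2-decimal
#'   percent), `n_common`, `n_reference`, `common` (sorted intersection).
#' @export
pathway_coverage <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  if (!length(setB)) stop("reference pathway set B is empty", call. = FALSE)
  common <- sort(intersect(setA, setB))
  cov <- length(common) / length(setB)
  list(coverage = cov, coverage_pct = round(100 * cov, 2),
       n_common = length(common), n_reference = length(setB),
       common = common)
}
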