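# Component table handling: ADME screening of herbal components and
# construction of the bipartite component-target network from merged
# multi-tool target predictions.

#' Read a component property table
#'
#' Expects a TSV with columns `id`, `name`, `herbs` (comma-separated herb
#' codes), `formula`, `mw`, `ob`, `caco2`, `dl`, `whitelisted`
#' (TRUE/FALSE) — the layout of a TCMSP-style export. Missing numeric
#' properties may be empty or NA.
#'
#' @param path Path to components.tsv.
#' @return A data frame, one row per component, with attributes
#'   `n_rows` (raw row count) and `n_unique` (unique-id count); the two
#'   differ when a component is listed once per herb.
#' @export
read_components <- function(path) {
  df <- read_tsv(path)
  required <- c("id", "name", "ob", "caco2", "dl", "whitelisted")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("components table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_rows <- nrow(df)
  df$whitelisted <- as.logical(df$whitelisted)
  for (col in c("mw", "ob", "caco2", "dl"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  df <- df[!duplicated(df$id), ]
  rownames(df) <- NULL
  if (any(df$mw <= 0, na.rm = TRUE)) stop("mw must be positive", call. = FALSE)
  attr(df, "n_rows") <- n_rows
  attr(df, "n_unique") <- nrow(df)
  df
}

#' ADME screening of components
#'
#' A component passes the screen iff it satisfies all three ADME rules, or
#' is whitelisted (curated in despite failing the rules, e.g. for high
#' content and known bioactivity). Boundary semantics follow the screening
#' criteria as stated: oral bioavailability and drug-likeness are
#' inclusive (`ob >= ob_min`, `dl >= dl_min`), Caco-2 permeability is
#' strict (`caco2 > caco2_min`; a score at or below the cutoff means not
#' permeable).
#'
#' @param components Data frame from [read_components()].
#' @param ob_min Minimum oral bioavailability in percent (default 30).
#' @param caco2_min Exclusive lower bound on the Caco-2 permeability score
#'   (default -0.4).
#' @param dl_min Minimum drug-likeness index (default 0.18).
#' @param na_policy What to do with a non-whitelisted component missing a
#'   screened property: `"reject"` (default) or `"pass"` (treat the
#'   missing rule as satisfied).
#' @return The subset of rows that pass, with an attribute `rejections`
#'   giving per-rule rejection counts.
#' @export
filter_active <- function(components, ob_min = 30, caco2_min = -0.4,
                          dl_min = 0.18, na_policy = c("reject", "pass")) {
  na_policy <- match.arg(na_policy)
  # -Inf / Inf are legal (disable a rule entirely); NA is not
  for (th in list(ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min))
    if (!is.numeric(th) || length(th) != 1L || is.na(th))
      stop("thresholds must be single non-missing numbers", call. = FALSE)
  df <- components
  na_fill <- if (na_policy == "reject") FALSE else TRUE
  rule <- function(x) ifelse(is.na(x), na_fill, x)
  ob_ok <- rule(df$ob >= ob_min)
  caco2_ok <- rule(df$caco2 > caco2_min)
  dl_ok <- rule(df$dl >= dl_min)
  wl <- !is.na(df$whitelisted) & df$whitelisted
  pass <- (ob_ok & caco2_ok & dl_ok) | wl
  rej <- c(ob = sum(!ob_ok & !wl), caco2 = sum(!caco2_ok & !wl),
           dl = sum(!dl_ok & !wl), total_rejected = sum(!pass))
  message(sprintf(
    "ADME screen: %d/%d pass (%d whitelisted); failed ob=%d caco2=%d dl=%d",
    sum(pass), nrow(df), sum(wl & !(ob_ok & caco2_ok & dl_ok)),
    rej["ob"], rej["caco2"], rej["dl"]))
  out <- df[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rej
  out
}

#' Read component-target prediction rows
#'
#' @param path Path to targets.tsv with columns `component`, `gene`,
#'   `tool`.
#' @return A data frame of prediction rows (one per component-gene-tool).
#' @export
read_targets <- function(path) {
  df <- read_tsv(path)
  miss <- setdiff(c("component", "gene", "tool"), names(df))
  if (length(miss))
    stop("targets table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$component <- trimws(df$component); df$gene <- trimws(df$gene)
  df
}

#' Merge multi-tool target predictions into a component-target network
#'
#' Takes the union of predictions across tools, deduplicated by
#' (component, gene); the set of supporting tools per edge is retained as
#' provenance. `min_tools` restricts edges to those supported by at least
#' that many distinct tools (default 1, i.e. plain union — no voting
#' rule).
#'
#' @param predictions A data frame with columns `component`, `gene`,
#'   `tool`, or a list of such data frames (one per tool).
#' @param components Optional component table; if supplied, prediction
#'   rows referring to unknown component ids are an error.
#' @param min_tools Minimum number of distinct supporting tools per edge.
#' @return An object of class `ct_network`: a list with `edges` (data
#'   frame: component, gene, n_tools, tools), `components` and `targets`
#'   (character vectors of the two sides).
#' @export
merge_predictions <- function(predictions, components = NULL, min_tools = 1L) {
  if (is.data.frame(predictions)) predictions <- list(predictions)
  rows <- do.call(rbind, lapply(predictions, function(p) {
    stopifnot(all(c("component", "gene", "tool") %in% names(p)))
    p[, c("component", "gene", "tool")]
  }))
  if (!is.null(components)) {
    unknown <- setdiff(unique(rows$component), components$id)
    if (length(unknown))
      stop("unknown component id(s) in predictions: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- rows[!duplicated(rows), ]
  key <- paste(rows$component, rows$gene, sep = "\r")
  tools_by_edge <- split(rows$tool, key)
  edges <- rows[!duplicated(key), c("component", "gene")]
  ekey <- paste(edges$component, edges$gene, sep = "\r")
  edges$n_tools <- lengths(tools_by_edge)[ekey]
  edges$tools <- vapply(tools_by_edge[ekey],
                        function(t) paste(sort(unique(t)), collapse = ","), "")
  edges <- edges[edges$n_tools >= min_tools, , drop = FALSE]
  edges <- edges[order(edges$component, edges$gene), ]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         components = sort(unique(edges$component)),
         targets = sort(unique(edges$gene))),
    class = "ct_network")
}

#' @export
print.ct_network <- function(x, ...) {
  s <- ct_degree_stats(x)
  cat(sprintf(paste0(
    "<component-target network> %d components, %d targets, %d edges\n",
    "  mean targets/component: %.2f; mean components/target: %.2f\n"),
    s$n_components, s$n_targets, s$n_edges,
    s$mean_targets_per_component, s$mean_components_per_target))
  invisible(x)
}

#' Degree statistics of a component-target network
#'
#' @param ct A `ct_network` from [merge_predictions()].
#' @return A list with `n_components`, `n_targets`, `n_edges`,
#'   `mean_targets_per_component` (= edges / components) and
#'   `mean_components_per_target` (= edges / targets), at full precision.
#' @export
ct_degree_stats <- function(ct) {
  stopifnot(inherits(ct, "ct_network"))
  n_e <- nrow(ct$edges)
  if (n_e == 0L) stop("empty component-target network", call. = FALSE)
  list(
    n_components = length(ct$components),
    n_targets = length(ct$targets),
    n_edges = n_e,
    mean_targets_per_component = n_e / length(ct$components),
    mean_components_per_target = n_e / length(ct$targets)
  )
}

#' Per-component target sets of a component-target network
#'
#' @param ct A `ct_network`.
#' @return A named list mapping component id to its character vector of
#'   target genes.
#' @export
ct_target_sets <- function(ct) {
  stopifnot(inherits(ct, "ct_network"))
  split(ct$edges$gene, factor(ct$edges$component, levels = ct$components))
}
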