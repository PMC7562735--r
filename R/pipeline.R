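# End-to-end pipeline: disease network -> ADME screen -> C-T network ->
# disease-targets-components network -> optimization space -> CI/KGEC ->
# enrichment and pathway coverage. A run is a pure function of
# (input files, config): re-running the same config gives byte-identical
# outputs.

#' Assemble and validate a pipeline configuration
#'
#' @param ppi,disease_genes,components,targets,pathways Paths to the five
#'   input files (PPI edge list, weighted disease-gene table, component
#'   property table, component-target prediction rows, GMT pathway sets).
#' @param out_dir Output directory for stage outputs and the manifest.
#' @param ob_min,caco2_min,dl_min ADME screen thresholds
#'   ([filter_active()]).
#' @param min_tools Minimum supporting prediction tools per
#'   component-target edge ([merge_predictions()]).
#' @param edge_rule Optimization-space edge rule ([extract_optspace()]).
#' @param order Accumulation-curve ordering ([accumulation_curve()]).
#' @param coverage_threshold KGEC coverage cut in (0, 1]
#'   ([select_kgec()]).
#' @param alpha ORA significance cutoff ([ora()]).
#' @param adjust ORA adjustment, `"none"` or `"BH"`.
#' @param na_policy Missing-ADME-property policy ([filter_active()]).
#' @return A validated `run_config` list that round-trips through YAML
#'   via [write_run_config()] / [read_run_config()].
#' @export
run_config <- function(ppi, disease_genes, components, targets, pathways,
                       out_dir, ob_min = 30, caco2_min = -0.4, dl_min = 0.18,
                       min_tools = 1, edge_rule = c("induced", "incident"),
                       order = c("ci_desc", "greedy_marginal"),
                       coverage_threshold = 0.90, alpha = 0.05,
                       adjust = c("none", "BH"),
                       na_policy = c("reject", "pass")) {
  cfg <- list(
    ppi = ppi, disease_genes = disease_genes, components = components,
    targets = targets, pathways = pathways, out_dir = out_dir,
    ob_min = check_number(ob_min, "ob_min"),
    caco2_min = check_number(caco2_min, "caco2_min"),
    dl_min = check_number(dl_min, "dl_min"),
    min_tools = check_count(min_tools, "min_tools"),
    edge_rule = match.arg(edge_rule),
    order = match.arg(order),
    coverage_threshold = check_number(coverage_threshold,
                                      "coverage_threshold"),
    alpha = check_number(alpha, "alpha", lower = 0, upper = 1),
    adjust = match.arg(adjust),
    na_policy = match.arg(na_policy))
  if (cfg$coverage_threshold <= 0 || cfg$coverage_threshold > 1)
    stop("`coverage_threshold` must be in (0, 1]", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` the path, invisibly; `read_run_config` a
#'   validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full formula-optimization pipeline
#'
#' Executes the stages in order — weighted disease gene network, ADME
#' screen, component-target network, disease-targets-components network,
#' optimization space and effective-protein categories, contribution
#' index / knapsack / KGEC selection, pathway over-representation and
#' coverage — writing every stage output and a manifest of counts to
#' `config$out_dir`. Any stage failure aborts with the stage name after
#' writing a partial manifest.
#'
#' @param config A `run_config` (or path to its YAML file).
#' @return Invisibly, a list with the in-memory stage results (`network`,
#'   `active`, `ct`, `dtc`, `space`, `categories`, `ci`, `knapsack`,
#'   `curve`, `kgec`, `enrichment`, `coverage`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  stage("disease_network", {
    ppi <- load_ppi(config$ppi)
    disease <- load_disease_genes(config$disease_genes)
    res$network <- build_weighted_network(ppi, disease)
    manifest$n_ppi_nodes <- igraph::vcount(ppi)
    manifest$n_ppi_edges <- igraph::ecount(ppi)
    manifest$n_disease_genes <- nrow(disease)
    manifest$n_disease_network_nodes <- igraph::vcount(res$network)
    manifest$n_disease_network_edges <- igraph::ecount(res$network)
    write_network_tsv(res$network,
                      file.path(out, "weighted_network_edges.tsv"),
                      file.path(out, "weighted_network_nodes.tsv"))
    res$ppi <- ppi; res$disease <- disease
  })

  stage("adme_filter", {
    comps <- read_components(config$components)
    res$active <- filter_active(comps, config$ob_min, config$caco2_min,
                                 config$dl_min, config$na_policy)
    manifest$n_components_total <- attr(comps, "n_unique")
    manifest$n_component_rows <- attr(comps, "n_rows")
    manifest$n_active_components <- nrow(res$active)
    write_tsv(res$active, file.path(out, "active_components.tsv"))
    res$components <- comps
  })

  stage("ct_network", {
    preds <- read_targets(config$targets)
    preds <- preds[preds$component %in% res$active$id, , drop = FALSE]
    if (!nrow(preds)) stop("no predictions for active components")
    res$ct <- merge_predictions(preds, components = res$components,
                                 min_tools = config$min_tools)
    st <- ct_degree_stats(res$ct)
    manifest$n_ct_components <- st$n_components
    manifest$n_ct_targets <- st$n_targets
    manifest$n_ct_edges <- st$n_edges
    manifest$mean_targets_per_component <-
      round(st$mean_targets_per_component, 2)
    manifest$mean_components_per_target <-
      round(st$mean_components_per_target, 2)
    message(sprintf(
      "C-T network: %d components, %d targets, %d edges; mean targets/component %.2f, mean components/target %.2f",
      st$n_components, st$n_targets, st$n_edges,
      st$mean_targets_per_component, st$mean_components_per_target))
    write_tsv(res$ct$edges, file.path(out, "ct_edges.tsv"))
  })

  stage("optimization_space", {
    dis_in_ppi <- igraph::V(res$network)$name
    res$dtc <- build_dtc(res$ppi, res$ct$targets, dis_in_ppi)
    res$space <- extract_optspace(res$dtc, config$edge_rule)
    res$categories <- category_tables(res$space)
    manifest$n_dtc_nodes <- igraph::vcount(res$dtc)
    manifest$n_dtc_edges <- igraph::ecount(res$dtc)
    manifest$dtc_average_degree <- round(res$space$d_avg, 4)
    manifest$n_effective_proteins <- nrow(res$space$nodes)
    manifest$n_optspace_edges <- nrow(res$space$edges)
    manifest$n_essential_common <- length(res$categories$essential_common)
    manifest$n_disease_specific <- length(res$categories$disease_specific)
    manifest$n_component_specific <- length(res$categories$component_specific)
    write_tsv(res$space$nodes, file.path(out, "optspace_nodes.tsv"))
    write_tsv(res$space$edges, file.path(out, "optspace_edges.tsv"))
  })

  stage("ci_kgec", {
    inp <- ci_input(res$ct, res$space$nodes$gene)
    res$ci <- component_ci(inp)
    res$knapsack <- knapsack_select(inp)
    res$curve <- accumulation_curve(inp, config$order)
    res$kgec <- select_kgec(res$curve, config$coverage_threshold)
    manifest$n_ci_components <- inp$m
    manifest$knapsack_value <- res$knapsack$value
    manifest$kgec_size <- res$kgec$size
    manifest$kgec_coverage_pct <- res$kgec$coverage_pct
    manifest$kgec_order <- res$kgec$order
    message(sprintf("KGEC: %d components reach %.2f%% effective-protein coverage (%s order)",
                    res$kgec$size, res$kgec$coverage_pct, res$kgec$order))
    write_tsv(res$ci, file.path(out, "ci_table.tsv"))
    write_tsv(as.data.frame(res$curve), file.path(out, "curve.tsv"))
    writeLines(res$kgec$kgec, file.path(out, "kgec.txt"))
  })

  stage("enrichment", {
    gmt <- read_gmt(config$pathways)
    safe_ora <- function(q) {
      if (!length(intersect(q, gmt$universe))) return(NULL)
      ora(q, gmt, alpha = config$alpha, adjust = config$adjust)
    }
    kgec_targets <- sort(unique(
      res$ct$edges$gene[res$ct$edges$component %in% res$kgec$kgec]))
    queries <- list(
      disease = res$disease$gene,
      effective = res$space$nodes$gene,
      kgec_targets = kgec_targets,
      essential_common = res$categories$essential_common,
      disease_specific = res$categories$disease_specific,
      component_specific = res$categories$component_specific)
    enr <- lapply(queries, safe_ora)
    res$enrichment <- enr
    for (nm in c("disease", "effective", "kgec_targets"))
      if (!is.null(enr[[nm]]))
        write_tsv(enr[[nm]], file.path(out, paste0("enrichment_", nm, ".tsv")))
    ref <- if (is.null(enr$disease)) character() else
      significant_pathways(enr$disease)
    cov <- list()
    if (length(ref)) {
      for (nm in setdiff(names(enr), "disease")) {
        if (is.null(enr[[nm]])) next
        cc <- pathway_coverage(significant_pathways(enr[[nm]]), ref)
        cov[[nm]] <- list(coverage_pct = cc$coverage_pct,
                          n_common = cc$n_common,
                          n_reference = cc$n_reference)
        message(sprintf("pathway coverage of disease profile by %s: %.2f%% (%d/%d)",
                        nm, cc$coverage_pct, cc$n_common, cc$n_reference))
      }
    }
    res$coverage <- cov
    manifest$n_disease_enriched_pathways <- length(ref)
    manifest$n_effective_enriched_pathways <-
      if (is.null(enr$effective)) 0L else
        length(significant_pathways(enr$effective))
    manifest$n_kgec_enriched_pathways <-
      if (is.null(enr$kgec_targets)) 0L else
        length(significant_pathways(enr$kgec_targets))
    manifest$coverage <- cov
    yaml::write_yaml(cov, file.path(out, "coverage_report.yaml"))
  })

  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
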