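# Synthetic input generator. Emulates the five inputs of the workflow —
# a PPI edge list, a literature-weighted disease-gene table, a component
# property table, multi-tool component-target predictions and GMT
# pathway sets — with controlled statistical structure, so the whole
# pipeline runs and is testable without any database download. Gene
# symbols are synthetic ("G000001", ...) on purpose.

.HERB_CODES <- sprintf("H%02d", 1:16)
.TOOLS <- c("hitpick", "sea", "swisstarget")

#' Specify a synthetic fixture
#'
#' Collects and validates the parameters of [generate_fixture()].
#'
#' @param n_ppi_genes Number of genes in the PPI network.
#' @param ppi_mean_degree Approximate mean PPI degree; the graph is grown
#'   by preferential attachment with `round(ppi_mean_degree / 2)` edges
#'   per new node, then simplified.
#' @param n_disease_genes Number of disease genes (a subset of PPI
#'   genes); must not exceed `n_ppi_genes`.
#' @param weight_max Maximum literature-report weight (weights uniform on
#'   1..weight_max).
#' @param n_components Number of herbal components.
#' @param targets_mean,targets_dispersion Mean and dispersion (size) of
#'   the negative-binomial number of predicted targets per component.
#' @param frac_targets_in_disease Expected fraction of each component's
#'   targets drawn from the disease genes, in `[0, 1]`.
#' @param n_pathways Number of GMT gene sets.
#' @param pathway_size Length-2 integer range of pathway sizes.
#' @param seed Integer RNG seed; all sampling uses one stream seeded
#'   here, so a fixed seed gives byte-identical output files.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_ppi_genes = 500, ppi_mean_degree = 6,
                         n_disease_genes = 100, weight_max = 50,
                         n_components = 60, targets_mean = 30,
                         targets_dispersion = 5,
                         frac_targets_in_disease = 0.3,
                         n_pathways = 25, pathway_size = c(10, 40),
                         seed = 1) {
  spec <- list(
    n_ppi_genes = check_count(n_ppi_genes, "n_ppi_genes", lower = 3),
    ppi_mean_degree = check_number(ppi_mean_degree, "ppi_mean_degree", lower = 1),
    n_disease_genes = check_count(n_disease_genes, "n_disease_genes"),
    weight_max = check_count(weight_max, "weight_max"),
    n_components = check_count(n_components, "n_components"),
    targets_mean = check_number(targets_mean, "targets_mean", lower = 1),
    targets_dispersion = check_number(targets_dispersion, "targets_dispersion",
                                      lower = 1e-6),
    frac_targets_in_disease = check_number(frac_targets_in_disease,
                                           "frac_targets_in_disease", 0, 1),
    n_pathways = check_count(n_pathways, "n_pathways"),
    pathway_size = pathway_size,
    seed = check_count(seed, "seed", lower = 0))
  if (spec$n_disease_genes > spec$n_ppi_genes)
    stop("`n_disease_genes` must not exceed `n_ppi_genes`", call. = FALSE)
  if (length(pathway_size) != 2L || any(pathway_size < 1) ||
      pathway_size[1] > pathway_size[2])
    stop("`pathway_size` must be an increasing range of two positive counts",
         call. = FALSE)
  class(spec) <- "fixture_spec"
  spec
}

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
with_fixture_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Random plausible small-molecule formula strings (CxHyNzOw).
random_formulas <- function(n) {
  cC <- sample(6:30, n, replace = TRUE)
  cH <- sample(6:40, n, replace = TRUE)
  cN <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  cO <- sample(0:11, n, replace = TRUE)
  paste0("C", cC, "H", cH,
         ifelse(cN > 0, paste0("N", ifelse(cN == 1, "", cN)), ""),
         ifelse(cO > 0, paste0("O", ifelse(cO == 1, "", cO)), ""))
}

#' Generate a synthetic input bundle
#'
#' Writes the five input files plus a manifest into `dir`, drawing
#' everything from a single RNG stream seeded from the spec, in a fixed
#' documented order (PPI graph, disease genes, components, targets,
#' pathways). The PPI is a preferential-attachment graph with duplicate
#' edges collapsed and self-loops dropped; per-component target counts
#' are negative-binomial; the expected share `frac_targets_in_disease`
#' of each component's targets is drawn from the disease genes; pathway
#' membership is weighted 6:3:1 (disease gene : target : other) so that
#' disease-relevant enrichment structure exists downstream.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `manifest` (the counts also written to manifest.yaml).
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_fixture_rng(spec$seed, {
    genes <- sprintf("G%06d", seq_len(spec$n_ppi_genes))

    ## 1. PPI: preferential attachment, then simplify
    m_pa <- max(1L, as.integer(round(spec$ppi_mean_degree / 2)))
    g <- igraph::sample_pa(spec$n_ppi_genes, power = 1, m = m_pa,
                           directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- genes
    ppi_edges <- igraph::as_data_frame(g, what = "edges")[, c("from", "to")]
    names(ppi_edges) <- c("geneA", "geneB")
    ppi_edges <- ppi_edges[order(ppi_edges$geneA, ppi_edges$geneB), ]

    ## 2. disease genes with literature-report weights
    dis_genes <- sort(sample(genes, spec$n_disease_genes))
    disease <- data.frame(
      gene = dis_genes,
      weight = sample.int(spec$weight_max, spec$n_disease_genes, replace = TRUE))

    ## 3. component property table
    n_c <- spec$n_components
    comp_ids <- sprintf("CMP%04d", seq_len(n_c))
    formulas <- random_formulas(n_c)
    components <- data.frame(
      id = comp_ids,
      name = paste0("compound-", seq_len(n_c)),
      herbs = vapply(seq_len(n_c), function(i)
        paste(sort(sample(.HERB_CODES, sample(1:3, 1))), collapse = ","), ""),
      formula = formulas,
      mw = round(vapply(formulas, molecular_mass, 0), 2),
      ob = round(stats::runif(n_c, 0, 100), 2),
      caco2 = round(stats::runif(n_c, -1.5, 1.5), 3),
      dl = round(stats::runif(n_c, 0, 1), 3),
      whitelisted = stats::runif(n_c) < 0.05,
      stringsAsFactors = FALSE)

    ## 4. component-target predictions
    non_dis <- setdiff(genes, dis_genes)
    n_t <- stats::rnbinom(n_c, size = spec$targets_dispersion,
                          mu = spec$targets_mean)
    target_rows <- vector("list", n_c)
    for (i in seq_len(n_c)) {
      if (n_t[i] == 0L) next
      k_dis <- stats::rbinom(1L, n_t[i], spec$frac_targets_in_disease)
      k_dis <- min(k_dis, length(dis_genes))
      k_oth <- min(n_t[i] - k_dis, length(non_dis))
      tg <- c(if (k_dis > 0) sample(dis_genes, k_dis),
              if (k_oth > 0) sample(non_dis, k_oth))
      n_tools <- sample(1:3, length(tg), replace = TRUE,
                        prob = c(0.6, 0.3, 0.1))
      target_rows[[i]] <- do.call(rbind, lapply(seq_along(tg), function(j)
        data.frame(component = comp_ids[i], gene = tg[j],
                   tool = sample(.TOOLS, n_tools[j]),
                   stringsAsFactors = FALSE)))
    }
    targets <- do.call(rbind, target_rows)
    if (is.null(targets))
      targets <- data.frame(component = character(), gene = character(),
                            tool = character())

    ## 5. pathways, biased towards disease genes (strongly) and targets
    ## (moderately), so disease-relevant enrichment structure exists
    w <- ifelse(genes %in% dis_genes, 6,
                ifelse(genes %in% unique(targets$gene), 3, 1))
    sizes <- sample(spec$pathway_size[1]:spec$pathway_size[2],
                    spec$n_pathways, replace = TRUE)
    sizes <- pmin(sizes, length(genes))
    gmt_lines <- vapply(seq_len(spec$n_pathways), function(i) {
      members <- sort(sample(genes, sizes[i], prob = w))
      paste(c(sprintf("PW%03d", i), "synthetic pathway", members),
            collapse = "\t")
    }, "")

    paths <- c(
      ppi = file.path(dir, "ppi.tsv"),
      disease_genes = file.path(dir, "disease_genes.tsv"),
      components = file.path(dir, "components.tsv"),
      targets = file.path(dir, "targets.tsv"),
      pathways = file.path(dir, "pathways.gmt"),
      manifest = file.path(dir, "manifest.yaml"))
    write_tsv(ppi_edges, paths[["ppi"]])
    write_tsv(disease, paths[["disease_genes"]])
    write_tsv(components, paths[["components"]])
    write_tsv(targets, paths[["targets"]])
    writeLines(gmt_lines, paths[["pathways"]])

    manifest <- list(
      seed = spec$seed,
      n_ppi_nodes = igraph::vcount(g),
      n_ppi_edges = igraph::ecount(g),
      n_disease_genes = nrow(disease),
      n_components = nrow(components),
      n_prediction_rows = nrow(targets),
      n_ct_edges = nrow(unique(targets[, c("component", "gene")])),
      n_pathways = spec$n_pathways)
    yaml::write_yaml(manifest, paths[["manifest"]])
    invisible(list(paths = paths, manifest = manifest))
  })
}

#' Simulate an enrichment test case with one planted pathway
#'
#' Builds a pathway collection of random gene sets over a synthetic
#' universe, plants enrichment into the first pathway by constructing a
#' query that deliberately overlaps it, and leaves the remaining overlap
#' to chance. Used to check that over-representation analysis recovers a
#' known signal.
#'
#' @param seed RNG seed.
#' @param n_universe Universe size (default 500).
#' @param n_pathways Number of pathways (default 20).
#' @param pathway_size Genes per pathway (default 30).
#' @param query_size Query size (default 40).
#' @param planted_overlap Query genes drawn from the planted pathway
#'   (default 15; the rest are uniform over the remaining universe).
#' @return List with `pathways` (a `pathway_collection` whose universe is
#'   the full synthetic universe), `query`, and `planted` (the enriched
#'   pathway's name, always the first).
#' @export
simulate_enrichment_case <- function(seed, n_universe = 500, n_pathways = 20,
                                     pathway_size = 30, query_size = 40,
                                     planted_overlap = 15) {
  stopifnot(planted_overlap <= pathway_size, planted_overlap <= query_size,
            pathway_size <= n_universe)
  with_fixture_rng(seed, {
    universe <- sprintf("G%06d", seq_len(n_universe))
    sets <- lapply(seq_len(n_pathways), function(i)
      sort(sample(universe, pathway_size)))
    names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
    planted <- names(sets)[1]
    query <- c(sample(sets[[planted]], planted_overlap),
               sample(setdiff(universe, sets[[planted]]),
                      query_size - planted_overlap))
    list(pathways = pathway_collection(sets, universe = universe),
         query = sort(query), planted = planted)
  })
}
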