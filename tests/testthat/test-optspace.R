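# Disease-targets-components network and optimization-space extraction.

toy_ppi <- function(edges) suppressMessages(load_ppi(write_ppi_file(edges)))

test_that("DTC induction handles identical and disjoint gene sets", {
  ppi <- toy_ppi(rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E")))
  same <- suppressMessages(build_dtc(ppi, targets = c("A", "B", "C"),
                                     disease = c("A", "B", "C")))
  expect_true(all(igraph::V(same)$category == "essential_common"))
  expect_equal(igraph::ecount(same), 2)  # A-B, B-C

  disj <- suppressMessages(build_dtc(ppi, targets = c("A", "B"),
                                     disease = c("D", "E")))
  expect_equal(igraph::ecount(disj), 2)  # A-B and D-E only, no bridge (B-C-D broken)
  expect_setequal(igraph::V(disj)$category[igraph::V(disj)$is_disease],
                  "disease_specific")
  expect_error(suppressMessages(build_dtc(ppi, "Z1", "Z2")), "empty union")
})

test_that("fixture DTC equals the two-step set-algebra oracle", {
  fx <- local_fixture(seed = 6)
  ppi <- suppressMessages(load_ppi(fx$paths[["ppi"]]))
  dis <- load_disease_genes(fx$paths[["disease_genes"]])
  preds <- read_targets(fx$paths[["targets"]])
  targets <- unique(preds$gene)
  dtc <- suppressMessages(build_dtc(ppi, targets, dis$gene))

  # oracle: union the sets, keep raw edges with both endpoints inside
  keep <- intersect(union(targets, dis$gene), igraph::V(ppi)$name)
  raw <- read.delim(fx$paths[["ppi"]])
  inside <- raw$geneA %in% keep & raw$geneB %in% keep
  expect_setequal(igraph::V(dtc)$name, keep)
  expect_equal(igraph::ecount(dtc), sum(inside))
})

test_that("average degree is 2E/N", {
  path3 <- toy_ppi(rbind(c("A", "B"), c("B", "C")))
  expect_equal(average_degree(path3), 4 / 3)
  ring <- toy_ppi(cbind(LETTERS[1:6], LETTERS[c(2:6, 1)]))
  expect_equal(average_degree(ring), 2)
  fx <- local_fixture(seed = 6)
  raw <- read.delim(fx$paths[["ppi"]])
  g <- suppressMessages(load_ppi(fx$paths[["ppi"]]))
  expect_equal(average_degree(g), mean(table(c(raw$geneA, raw$geneB))))
})

test_that("hub extraction keeps strictly-above-average nodes only", {
  star <- toy_ppi(cbind("HUB", paste0("L", 1:9)))
  igraph::V(star)$category <- "component_specific"
  sp <- suppressMessages(extract_optspace(star))
  expect_identical(sp$nodes$gene, "HUB")
  expect_equal(nrow(sp$edges), 0)
  expect_equal(sp$d_avg, 1.8)

  ring <- toy_ppi(cbind(LETTERS[1:6], LETTERS[c(2:6, 1)]))
  igraph::V(ring)$category <- "component_specific"
  expect_error(suppressMessages(extract_optspace(ring)), "degree-regular")
})

test_that("fixture optimization space equals a brute-force degree scan", {
  fx <- local_fixture(seed = 6)
  ppi <- suppressMessages(load_ppi(fx$paths[["ppi"]]))
  dis <- load_disease_genes(fx$paths[["disease_genes"]])
  targets <- unique(read_targets(fx$paths[["targets"]])$gene)
  dtc <- suppressMessages(build_dtc(ppi, targets, dis$gene))
  sp <- suppressMessages(extract_optspace(dtc))

  deg <- igraph::degree(dtc)
  expect_setequal(sp$nodes$gene, names(deg)[deg > mean(deg)])
  # strictly fewer nodes than the DTC whenever degrees vary
  expect_lt(nrow(sp$nodes), igraph::vcount(dtc))
  # induced rule: every edge endpoint is a retained hub
  expect_true(all(c(sp$edges$geneA, sp$edges$geneB) %in% sp$nodes$gene))

  # incident rule keeps a superset of edges, each touching a hub
  inc <- suppressMessages(extract_optspace(dtc, edge_rule = "incident"))
  expect_gte(nrow(inc$edges), nrow(sp$edges))
  expect_true(all(inc$edges$geneA %in% sp$nodes$gene |
                    inc$edges$geneB %in% sp$nodes$gene))
})

test_that("categories partition the effective proteins", {
  fx <- local_fixture(seed = 10)
  ppi <- suppressMessages(load_ppi(fx$paths[["ppi"]]))
  dis <- load_disease_genes(fx$paths[["disease_genes"]])
  targets <- unique(read_targets(fx$paths[["targets"]])$gene)
  sp <- suppressMessages(extract_optspace(build_dtc(ppi, targets, dis$gene)))
  cats <- category_tables(sp)
  expect_equal(sum(lengths(cats)), nrow(sp$nodes))
  expect_length(intersect(cats$essential_common, cats$disease_specific), 0)
  expect_length(intersect(cats$essential_common, cats$component_specific), 0)
  expect_setequal(unlist(cats, use.names = FALSE), sp$nodes$gene)
  # membership semantics
  expect_true(all(cats$essential_common %in% intersect(targets, dis$gene)))
  expect_true(all(cats$disease_specific %in% setdiff(dis$gene, targets)))
  expect_true(all(cats$component_specific %in% setdiff(targets, dis$gene)))
})
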