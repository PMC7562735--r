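# ADME screening and component-target network assembly.

make_components <- function(ob, caco2, dl, whitelisted = FALSE) {
  n <- max(lengths(list(ob, caco2, dl, whitelisted)))
  data.frame(id = sprintf("CMP%04d", seq_len(n)),
             name = paste0("c", seq_len(n)),
             ob = ob, caco2 = caco2, dl = dl,
             whitelisted = whitelisted, stringsAsFactors = FALSE)
}

test_that("ADME boundaries: ob and dl inclusive, caco2 strict", {
  df <- make_components(ob = c(30, 30, 29.99), caco2 = c(-0.4, -0.39, 1),
                        dl = c(0.18, 0.18, 0.5))
  out <- suppressMessages(filter_active(df))
  # exactly the caco2 = -0.4 row fails (not strictly greater)
  expect_identical(out$id, "CMP0002")
})

test_that("whitelisted components pass regardless of ADME values", {
  df <- make_components(ob = 12, caco2 = -1, dl = 0.01, whitelisted = TRUE)
  expect_equal(nrow(suppressMessages(filter_active(df))), 1)
})

test_that("missing properties follow the configured policy", {
  df <- make_components(ob = c(NA, NA), caco2 = c(0, 0), dl = c(0.5, 0.5),
                        whitelisted = c(FALSE, TRUE))
  rej <- suppressMessages(filter_active(df))
  expect_identical(rej$id, "CMP0002")  # whitelist overrides missing data
  pas <- suppressMessages(filter_active(df, na_policy = "pass"))
  expect_equal(nrow(pas), 2)
})

test_that("screen equals a brute-force row scan on random components", {
  set.seed(31)
  df <- make_components(ob = runif(1000, 0, 100),
                        caco2 = runif(1000, -1.5, 1.5),
                        dl = runif(1000, 0, 1),
                        whitelisted = runif(1000) < 0.05)
  out <- suppressMessages(filter_active(df))
  expected <- character(0)
  for (i in seq_len(nrow(df))) {  # deliberate scalar re-derivation
    if ((df$ob[i] >= 30 && df$caco2[i] > -0.4 && df$dl[i] >= 0.18) ||
        df$whitelisted[i])
      expected <- c(expected, df$id[i])
  }
  expect_identical(out$id, expected)
  # with all thresholds at -Inf every component passes
  all_in <- suppressMessages(filter_active(df, -Inf, -Inf, -Inf))
  expect_equal(nrow(all_in), nrow(df))
})

test_that("prediction merge unions tools with provenance", {
  t1 <- data.frame(component = "CMP0001", gene = "G1", tool = "sea")
  t2 <- data.frame(component = "CMP0001", gene = "G1", tool = "hitpick")
  ct <- merge_predictions(list(t1, t2))
  expect_equal(nrow(ct$edges), 1)
  expect_equal(ct$edges$n_tools, 2)
  expect_equal(ct$edges$tools, "hitpick,sea")
  # a voting rule stricter than any edge's support empties the network
  ct3 <- merge_predictions(list(t1), min_tools = 3)
  expect_equal(nrow(ct3$edges), 0)
})

test_that("merge equals the set-union oracle on random tool tables", {
  set.seed(8)
  tabs <- lapply(c("sea", "hitpick", "swisstarget"), function(tool)
    data.frame(component = sample(sprintf("CMP%04d", 1:10), 200, TRUE),
               gene = sample(sprintf("G%03d", 1:50), 200, TRUE),
               tool = tool, stringsAsFactors = FALSE))
  ct <- merge_predictions(tabs)
  all_rows <- do.call(rbind, tabs)
  oracle <- unique(paste(all_rows$component, all_rows$gene))
  expect_setequal(paste(ct$edges$component, ct$edges$gene), oracle)
  expect_lte(nrow(ct$edges), nrow(all_rows))
})

test_that("unknown component ids in predictions are an error", {
  comps <- make_components(ob = 50, caco2 = 0, dl = 0.5)
  preds <- data.frame(component = "NOPE", gene = "G1", tool = "sea")
  expect_error(merge_predictions(preds, components = comps), "NOPE")
})

test_that("degree statistics reproduce the printed C-T table arithmetic", {
  one <- merge_predictions(
    data.frame(component = "CMP0001", gene = "G1", tool = "sea"))
  s1 <- ct_degree_stats(one)
  expect_equal(s1$mean_targets_per_component, 1)
  expect_equal(s1$mean_components_per_target, 1)

  # 193 components, 1220 targets, 6399 unique associations
  ct <- counted_ct_network(193, 1220, 6399)
  s <- ct_degree_stats(ct)
  expect_equal(s$n_components, 193)
  expect_equal(s$n_targets, 1220)
  expect_equal(s$n_edges, 6399)
  expect_equal(round(s$mean_targets_per_component, 2), 33.16)
  expect_equal(round(s$mean_components_per_target, 2), 5.25)
})
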