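# Contribution index, 0-1 knapsack, accumulation curve and KGEC cut.

test_that("contribution index is nu/W with id-ascending tie-break", {
  inp <- ci_input_from_sets(
    list(b = sprintf("E%03d", 1:9), a = sprintf("E%03d", 1:9),
         c = character(0)),
    omega = c(12, 10, 0) + c(0, 0, 1),  # c has 1 target, none effective
    W = 10)
  expect_error(ci_input_from_sets(list(a = "E1"), omega = 0),
               "exceed omega")
  tab <- component_ci(inp)
  expect_equal(tab$ci[tab$component == "a"], 0.9)
  expect_equal(tab$ci_pct[1], 90)
  expect_identical(tab$component, c("a", "b", "c"))  # tie a before b
  expect_equal(tab$ci[tab$component == "c"], 0)
})

test_that("knapsack DP solves the classic instance and base cases", {
  # values 60/100/120, weights 10/20/30, capacity 50: optimum is {2, 3}
  ks <- knapsack_dp(c(60, 100, 120), c(10, 20, 30), 50)
  expect_equal(ks$value, 220)
  expect_equal(ks$selected, c(2L, 3L))
  expect_equal(brute_knapsack(c(60, 100, 120), c(10, 20, 30), 50), 220)

  zero <- knapsack_dp(c(60, 100, 120), c(10, 20, 30), 0)
  expect_equal(zero$value, 0)
  expect_length(zero$selected, 0)
  expect_error(knapsack_dp(c(-1, 2), c(1, 1), 5), "negative")

  # through the ci_input wrapper, named components come back
  inp <- ci_input_from_sets(list(a = c("E1", "E2"), b = c("E2", "E3")),
                            omega = c(2, 3), W = 3)
  expect_setequal(knapsack_select(inp, capacity = 5)$selected, c("a", "b"))
})

test_that("knapsack DP equals exhaustive enumeration on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    m <- sample(4:15, 1)
    W <- sample(10:40, 1)
    inp <- rand_ci_input(m, W)
    cap <- sample(0:sum(inp$omega), 1)
    ks <- knapsack_select(inp, capacity = cap)
    expect_equal(ks$value,
                 brute_knapsack(as.numeric(inp$nu), as.numeric(inp$omega), cap))
    # the reconstructed subset realizes the value within the capacity
    expect_equal(sum(inp$nu[ks$selected]), ks$value)
    expect_lte(sum(inp$omega[ks$selected]), cap)
  }
})

test_that("with capacity for everything the knapsack takes everything", {
  set.seed(55)
  inp <- rand_ci_input(8, 25)
  ks <- knapsack_select(inp, capacity = sum(inp$omega))
  expect_equal(ks$value, sum(inp$nu))
})

test_that("accumulation curve unions coverage without double counting", {
  eff <- sprintf("E%02d", 1:10)
  # two identical components: the second adds nothing
  twin <- ci_input_from_sets(list(a = eff[1:6], b = eff[1:6]), W = 10)
  cv <- accumulation_curve(twin)
  expect_equal(cv$marginal_gain, c(6, 0))
  expect_equal(cv$cumulative_coverage, c(0.6, 0.6))

  # disjoint sets accumulate as a running sum of nu/W
  disj <- ci_input_from_sets(list(a = eff[1:4], b = eff[5:7], c = eff[8:9]),
                             W = 10)
  cv <- accumulation_curve(disj)
  expect_equal(cv$cumulative_coverage, cumsum(c(4, 3, 2)) / 10)
})

test_that("curve is monotone, bounded and ends at the union coverage", {
  set.seed(77)
  for (rep in 1:20) {
    inp <- rand_ci_input(sample(3:12, 1), sample(10:30, 1))
    for (ord in c("ci_desc", "greedy_marginal")) {
      cv <- accumulation_curve(inp, order = ord)
      expect_true(all(diff(cv$cumulative_coverage) >= 0))
      expect_lte(max(cv$cumulative_coverage), 1)
      expect_equal(cv$cumulative_covered[nrow(cv)],
                   length(unique(unlist(inp$lambda))))
    }
  }
})

test_that("greedy order dominates ci-descending order at every prefix", {
  set.seed(88)
  for (rep in 1:20) {
    inp <- rand_ci_input(sample(4:12, 1), sample(10:30, 1))
    ci_cv <- accumulation_curve(inp, "ci_desc")
    gr_cv <- accumulation_curve(inp, "greedy_marginal")
    expect_true(all(gr_cv$cumulative_coverage >=
                      ci_cv$cumulative_coverage - 1e-12))
  }
})

test_that("KGEC cut takes the shortest prefix reaching the threshold", {
  eff <- sprintf("E%03d", 1:100)
  inp <- ci_input_from_sets(
    list(a = eff[1:50], b = eff[51:80], c = eff[81:92], d = eff[93:95]),
    W = 100)
  cv <- accumulation_curve(inp)   # curve: 0.50, 0.80, 0.92, 0.95
  sel <- select_kgec(cv, threshold = 0.90)
  expect_equal(sel$size, 3)
  expect_identical(sel$kgec, c("a", "b", "c"))
  expect_equal(sel$coverage, 0.92)

  # threshold 1.0 when full coverage exists
  full <- ci_input_from_sets(list(a = eff[1:60], b = eff[41:100]), W = 100)
  expect_equal(select_kgec(accumulation_curve(full), 1.0)$coverage, 1)

  # unreachable threshold returns everything with a warning
  expect_warning(all4 <- select_kgec(cv, threshold = 0.99), "unreachable")
  expect_equal(all4$size, 4)
  expect_error(select_kgec(cv, threshold = 0), "in \\(0, 1\\]")

  # prefix length is non-decreasing in the threshold
  sizes <- sapply(c(0.4, 0.6, 0.8, 0.95), function(th)
    select_kgec(cv, threshold = th)$size)
  expect_true(all(diff(sizes) >= 0))
})

test_that("ci_input extracts effective-target sets from a C-T network", {
  preds <- data.frame(
    component = c("c1", "c1", "c1", "c2", "c2", "c3"),
    gene = c("Ga", "Gb", "Gc", "Gb", "Gd", "Gd"),
    tool = "sea", stringsAsFactors = FALSE)
  ct <- merge_predictions(preds)
  inp <- ci_input(ct, effective = c("Ga", "Gb", "Gx"))
  # c3 targets no effective protein and is dropped
  expect_setequal(names(inp$lambda), c("c1", "c2"))
  expect_equal(inp$W, 3)
  expect_equal(as.integer(inp$nu[c("c1", "c2")]), c(2L, 1L))
  expect_equal(as.integer(inp$omega[c("c1", "c2")]), c(3L, 2L))
})
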