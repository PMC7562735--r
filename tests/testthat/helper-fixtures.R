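# Shared helpers: in-code fixtures and independent brute-force oracles.

# Generate a fixture bundle under a session-temporary directory.
local_fixture <- function(seed = 1, ..., env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  generate_fixture(fixture_spec(seed = seed, ...), dir)
}

# Exhaustive 0-1 knapsack oracle: enumerate every subset.
brute_knapsack <- function(values, weights, capacity) {
  m <- length(values)
  best <- 0
  for (mask in 0:(2^m - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    if (sum(weights[sel]) <= capacity) best <- max(best, sum(values[sel]))
  }
  best
}

# Random ci_input over a synthetic effective-protein universe.
rand_ci_input <- function(m, W, max_omega = 2 * W) {
  eff <- sprintf("E%03d", seq_len(W))
  lambda <- lapply(seq_len(m), function(i)
    sort(sample(eff, sample.int(W, 1))))
  names(lambda) <- sprintf("c%02d", seq_len(m))
  omega <- lengths(lambda) + sample(0:max(1, max_omega - W), m, replace = TRUE)
  ci_input_from_sets(lambda, omega = omega, W = W)
}

# Bipartite component-target network with exactly the printed counts of
# a C-T table: n_c components, n_t targets, n_e unique edges. Pair j is
# (j mod n_c, j mod n_t); pairs are unique whenever lcm(n_c, n_t) > n_e.
counted_ct_network <- function(n_c, n_t, n_e) {
  j <- seq_len(n_e) - 1L
  df <- data.frame(
    component = sprintf("C%04d", (j %% n_c) + 1L),
    gene = sprintf("T%04d", (j %% n_t) + 1L),
    tool = "tab", stringsAsFactors = FALSE)
  merge_predictions(df)
}

# Write a tiny PPI edge-list file from a two-column matrix of symbols.
write_ppi_file <- function(edges, path = withr::local_tempfile(
                             fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(paste(edges[, 1], edges[, 2], sep = "\t"), path)
  path
}
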