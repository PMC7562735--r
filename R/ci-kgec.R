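# Contribution-index model and KGEC selection. Each active component i
# has a target count omega_i, an effective-target set lambda_i (its
# targets among the W effective proteins) and a coverage count
# nu_i = |lambda_i|. The contribution index is CI_i = nu_i / W. A
# dynamic 0-1 knapsack (values nu, weights omega, capacity W) gives the
# optimal scalar-value subset; the KGEC itself is cut from the
# cumulative union-coverage curve at a coverage threshold.

#' Assemble contribution-index input
#'
#' For each component of a component-target network, records its full
#' target count (omega), its set of effective targets (lambda = targets
#' intersected with the effective proteins) and the coverage count
#' (nu = |lambda|). Components with no effective target are dropped —
#' only components associated with effective proteins enter the model.
#'
#' @param ct A `ct_network` ([merge_predictions()]).
#' @param effective Character vector of effective proteins (e.g.
#'   `extract_optspace(...)$nodes$gene`).
#' @return An object of class `ci_input`: list with `lambda` (named list
#'   of effective-target sets), `omega`, `nu` (named integer vectors),
#'   `m` (number of components) and `W` (number of effective proteins).
#' @export
ci_input <- function(ct, effective) {
  stopifnot(inherits(ct, "ct_network"))
  effective <- unique(effective)
  if (!length(effective)) stop("empty effective-protein set", call. = FALSE)
  sets <- ct_target_sets(ct)
  lambda <- lapply(sets, function(s) sort(intersect(s, effective)))
  keep <- lengths(lambda) > 0L
  lambda <- lambda[keep]
  if (!any(keep)) stop("no component targets any effective protein", call. = FALSE)
  omega <- lengths(sets)[keep]
  structure(
    list(lambda = lambda,
         omega = stats::setNames(as.integer(omega), names(lambda)),
         nu = stats::setNames(as.integer(lengths(lambda)), names(lambda)),
         m = length(lambda), W = length(effective)),
    class = "ci_input")
}

# Construct a ci_input from raw pieces; used by tests and small examples.
#' Build contribution-index input from explicit sets
#'
#' Low-level constructor taking the per-component effective-target sets
#' and total target counts directly.
#'
#' @param lambda Named list of effective-target sets (character vectors).
#' @param omega Named integer vector of total target counts, aligned with
#'   `lambda`; defaults to `lengths(lambda)`.
#' @param W Number of effective proteins; defaults to the size of the
#'   union of `lambda`.
#' @return A `ci_input` object.
#' @export
ci_input_from_sets <- function(lambda, omega = lengths(lambda),
                               W = length(unique(unlist(lambda)))) {
  stopifnot(is.list(lambda), length(lambda) >= 1L, !is.null(names(lambda)))
  nu <- lengths(lambda)
  if (any(nu > omega)) stop("nu_i cannot exceed omega_i", call. = FALSE)
  W <- check_count(W, "W")
  if (any(nu > W)) stop("nu_i cannot exceed W", call. = FALSE)
  structure(
    list(lambda = lambda,
         omega = stats::setNames(as.integer(omega), names(lambda)),
         nu = stats::setNames(as.integer(nu), names(lambda)),
         m = length(lambda), W = W),
    class = "ci_input")
}

#' Per-component contribution index
#'
#' `CI_i = nu_i / W`: the fraction of the effective proteins that
#' component i targets.
#'
#' @param input A `ci_input`.
#' @return A data frame (component, omega, nu, ci, ci_pct, rank) ordered
#'   by ci descending with ties broken by component id ascending.
#' @export
component_ci <- function(input) {
  stopifnot(inherits(input, "ci_input"))
  if (input$W < 1L) stop("W must be at least 1", call. = FALSE)
  df <- data.frame(
    component = names(input$nu),
    omega = as.integer(input$omega),
    nu = as.integer(input$nu),
    ci = input$nu / input$W,
    stringsAsFactors = FALSE)
  df$ci_pct <- round(100 * df$ci, 2)
  df <- df[order(-df$ci, df$component), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Dynamic 0-1 knapsack over component coverage counts
#'
#' Maximizes the summed coverage counts `nu_i` of the chosen components
#' subject to their summed target counts `omega_i` not exceeding the
#' capacity (default W, the number of effective proteins). The DP is the
#' textbook recurrence `c[i, w] = max(c[i-1, w], nu_i + c[i-1, w -
#' omega_i])` with `c[0, .] = c[., 0] = 0` and a strictly-greater update,
#' so on ties the earlier-indexed solution is preferred; the subset is
#' recovered by backtracking.
#'
#' @param input A `ci_input`.
#' @param capacity Knapsack capacity (non-negative integer; default
#'   `input$W`).
#' @return List with `value` (= c[m, capacity]), `selected` (component
#'   ids, in input order), `total_weight` (their summed omega) and
#'   `capacity`.
#' @export
knapsack_select <- function(input, capacity = input$W) {
  stopifnot(inherits(input, "ci_input"))
  out <- knapsack_dp(as.numeric(input$nu), as.integer(input$omega), capacity)
  list(value = out$value,
       selected = names(input$nu)[out$selected],
       total_weight = sum(input$omega[out$selected]),
       capacity = out$capacity)
}

#' Dynamic 0-1 knapsack on raw value and weight vectors
#'
#' The DP behind [knapsack_select()], usable on any non-negative integer
#' weights and non-negative values.
#'
#' @param values,weights Equal-length non-negative vectors (weights
#'   integer).
#' @param capacity Non-negative integer capacity.
#' @return List with `value` (the DP optimum `c[m, capacity]`),
#'   `selected` (indices of one optimal subset, earliest-index preferred
#'   on ties) and `capacity`.
#' @export
knapsack_dp <- function(values, weights, capacity) {
  capacity <- check_count(capacity, "capacity", lower = 0)
  v <- as.numeric(values); w <- as.integer(weights); m <- length(v)
  stopifnot(length(w) == m)
  if (any(v < 0) || any(w < 0)) stop("negative weight or value", call. = FALSE)
  # c has m+1 rows (item prefix) and capacity+1 columns (weight 0..capacity)
  tab <- matrix(0, nrow = m + 1L, ncol = capacity + 1L)
  for (i in seq_len(m)) {
    prev <- tab[i, ]
    cur <- prev
    if (w[i] <= capacity) {
      idx <- (w[i]:capacity) + 1L
      cand <- v[i] + prev[idx - w[i]]
      better <- cand > prev[idx]
      cur[idx[better]] <- cand[better]
    }
    tab[i + 1L, ] <- cur
  }
  # backtrack: item i taken iff the value changed at row i
  sel <- logical(m); wr <- capacity + 1L
  for (i in m:1) {
    if (tab[i + 1L, wr] != tab[i, wr]) {
      sel[i] <- TRUE
      wr <- wr - w[i]
    }
  }
  list(value = tab[m + 1L, capacity + 1L],
       selected = which(sel),
       capacity = capacity)
}

#' Cumulative coverage accumulation curve
#'
#' Orders the components and accumulates the union of their
#' effective-target sets: the value at step j is
#' `|lambda_(1) U ... U lambda_(j)| / W`. Two orderings are offered:
#' `ci_desc` ranks by contribution index descending (ties by component id
#' ascending); `greedy_marginal` is the classic greedy maximum-coverage
#' order, picking at each step the component with the largest marginal
#' gain (ties by id ascending).
#'
#' @param input A `ci_input`.
#' @param order `"ci_desc"` (default) or `"greedy_marginal"`.
#' @return An object of class `ci_curve`: data frame with columns `rank`,
#'   `component`, `omega`, `nu`, `ci`, `marginal_gain` (newly covered
#'   effective proteins at this step), `cumulative_covered`,
#'   `cumulative_coverage` (fraction of W); attributes `order` and `W`.
#' @export
accumulation_curve <- function(input, order = c("ci_desc", "greedy_marginal")) {
  stopifnot(inherits(input, "ci_input"))
  order <- match.arg(order)
  ids <- names(input$lambda)
  if (order == "ci_desc") {
    ord <- ids[order(-input$nu, ids)]
  } else {
    remaining <- ids
    covered <- character(0)
    ord <- character(0)
    while (length(remaining)) {
      gains <- vapply(remaining,
                      function(id) length(setdiff(input$lambda[[id]], covered)), 1L)
      pick <- remaining[order(-gains, remaining)][1L]
      ord <- c(ord, pick)
      covered <- union(covered, input$lambda[[pick]])
      remaining <- setdiff(remaining, pick)
    }
  }
  covered <- character(0)
  marg <- integer(length(ord)); cum <- integer(length(ord))
  for (j in seq_along(ord)) {
    new <- setdiff(input$lambda[[ord[j]]], covered)
    covered <- c(covered, new)
    marg[j] <- length(new)
    cum[j] <- length(covered)
  }
  out <- data.frame(
    rank = seq_along(ord),
    component = ord,
    omega = as.integer(input$omega[ord]),
    nu = as.integer(input$nu[ord]),
    ci = input$nu[ord] / input$W,
    marginal_gain = marg,
    cumulative_covered = cum,
    cumulative_coverage = cum / input$W,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, order = order, W = input$W, class = c("ci_curve", "data.frame"))
}

#' Select the key group of effective components (KGEC)
#'
#' Cuts the accumulation curve at the shortest prefix whose cumulative
#' coverage of the effective proteins reaches the threshold. If the
#' threshold is unreachable, all components are returned with a warning
#' reporting the achieved maximum.
#'
#' @param curve A `ci_curve` from [accumulation_curve()].
#' @param threshold Coverage fraction in (0, 1] (default 0.90).
#' @return List with `kgec` (component ids, curve order), `size`,
#'   `coverage` (achieved fraction), `coverage_pct`, `threshold`,
#'   `order`.
#' @export
select_kgec <- function(curve, threshold = 0.90) {
  stopifnot(inherits(curve, "ci_curve"))
  check_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  hit <- which(curve$cumulative_coverage >= threshold)
  if (length(hit)) {
    n <- hit[1L]
  } else {
    n <- nrow(curve)
    warning(sprintf(
      "coverage threshold %.2f unreachable; maximum achievable is %.4f — returning all %d components",
      threshold, curve$cumulative_coverage[n], n), call. = FALSE)
  }
  cov <- curve$cumulative_coverage[n]
  list(kgec = curve$component[seq_len(n)], size = n,
       coverage = cov, coverage_pct = round(100 * cov, 2),
       threshold = threshold, order = attr(curve, "order"))
}
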