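# Synthetic benchmark generator ------------------------------------------
#
# Emulates a benchmark generator for network-inference tools: a known
# topology, hidden binary regulatory states propagated through it, and
# observed expression emitted from a two-component (bimodal) Gaussian per
# state.  The gold standard is the topology's adjacency, exactly.

#' Graded-parents benchmark topology
#'
#' Gene `i` (1-based) has exactly `i - 1` parents, namely genes `1..i-1`;
#' with one layer per gene this is a deliberately heterogeneous static
#' topology (the last gene is a hub child).  Total edge count is
#' `n (n - 1) / 2`.
#'
#' @param n gene count (>= 1).
#' @param mode `"static"` or `"dynamic"`.
#' @return object of class `bnx_topology` with fields `n`, `variables`,
#'   `adjacency` (parent rows x child columns, logical), `layering`, `mode`.
#' @export
make_graded_topology <- function(n, mode = "static") {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("gene count must be at least 1", call. = FALSE)
  vars <- paste0("G", seq_len(n))
  adj <- upper.tri(matrix(FALSE, n, n))
  dimnames(adj) <- list(vars, vars)
  structure(list(n = n, variables = vars, adjacency = adj,
                 layering = as.list(vars),
                 mode = match.arg(mode, c("static", "dynamic"))),
            class = "bnx_topology")
}

#' User-specified topology
#'
#' Wraps an arbitrary parent-by-child adjacency matrix as a benchmark
#' topology.  Static topologies must be acyclic; the layering used for the
#' exported regulator preamble is derived from the longest-path depth of
#' each gene.
#'
#' @param adjacency square logical/0-1 matrix, parents in rows.
#' @param mode `"static"` or `"dynamic"`.
#' @return a `bnx_topology`.
#' @export
bnx_topology <- function(adjacency, mode = c("static", "dynamic")) {
  mode <- match.arg(mode)
  adjacency <- adjacency != 0
  n <- nrow(adjacency)
  if (n != ncol(adjacency))
    stop("adjacency must be square", call. = FALSE)
  vars <- rownames(adjacency)
  if (is.null(vars)) vars <- paste0("G", seq_len(n))
  dimnames(adjacency) <- list(vars, vars)
  depth <- rep(0L, n)
  if (mode == "static") {
    # longest-path layering; also detects cycles
    for (pass in seq_len(n + 1L)) {
      nd <- depth
      for (i in seq_len(n)) {
        pa <- which(adjacency[, i])
        if (length(pa)) nd[i] <- max(depth[pa]) + 1L
      }
      if (identical(nd, depth)) break
      if (pass > n) stop("static topology must be acyclic", call. = FALSE)
      depth <- nd
    }
  }
  layering <- lapply(sort(unique(depth)), function(d) vars[depth == d])
  structure(list(n = n, variables = vars, adjacency = adjacency,
                 layering = layering, mode = mode),
            class = "bnx_topology")
}

#' Preferential-attachment (scale-free-like) topology
#'
#' Convenience extension beyond the graded benchmark: gene `i > 1` picks
#' `m` parents among genes `1..i-1` with probability proportional to
#' 1 + current out-degree, giving hub regulators.  Static, one layer per
#' gene.
#'
#' @param n gene count.
#' @param m parents drawn per gene (capped at `i - 1`).
#' @param seed RNG seed.
#' @return a `bnx_topology`.
#' @export
make_scalefree_topology <- function(n, m = 1L, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("gene count must be at least 1", call. = FALSE)
  vars <- paste0("G", seq_len(n))
  adj <- matrix(FALSE, n, n, dimnames = list(vars, vars))
  with_seed(seed, {
    for (i in seq_len(n)[-1L]) {
      w <- 1 + rowSums(adj)[seq_len(i - 1L)]
      k <- min(m, i - 1L)
      pa <- sample(seq_len(i - 1L), k, prob = w)
      adj[pa, i] <- TRUE
    }
  })
  structure(list(n = n, variables = vars, adjacency = adj,
                 layering = as.list(vars), mode = "static"),
            class = "bnx_topology")
}

#' Emission model for the generator
#'
#' Hidden binary states are emitted as draws from `N(mu_low, sigma)` (state
#' 0) or `N(mu_high, sigma)` (state 1), so each gene's marginal expression
#' distribution is a bimodal Gaussian mixture.  A child's hidden state is
#' the sign-weighted majority vote of its parents' states, flipped with
#' probability `flip_prob` (regulatory noise); vote ties are resolved by a
#' fair coin.
#'
#' @param mu_low,mu_high state means, expression units (`mu_low < mu_high`).
#' @param sigma state standard deviation (> 0).
#' @param flip_prob regulatory noise in \[0, 1).
#' @return an `bnx_emission` object.
#' @export
emission_model <- function(mu_low = 0, mu_high = 5, sigma = 1,
                           flip_prob = 0.05) {
  if (!(mu_low < mu_high)) stop("mu_low must be below mu_high", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (flip_prob < 0 || flip_prob >= 1)
    stop("flip_prob must lie in [0, 1)", call. = FALSE)
  structure(list(mu_low = mu_low, mu_high = mu_high, sigma = sigma,
                 flip_prob = flip_prob), class = "bnx_emission")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  eval.parent(substitute(expr))
}

vote_states <- function(parent_states, signs, flip_prob, nobs) {
  votes <- colSums(signs * (2 * parent_states - 1))
  s <- as.integer(votes > 0)
  tie <- votes == 0
  if (any(tie)) s[tie] <- stats::rbinom(sum(tie), 1L, 0.5)
  flip <- stats::rbinom(nobs, 1L, flip_prob)
  as.integer(xor(s, flip))
}

#' Simulate observations from a benchmark topology
#'
#' Static topologies: each observation column is independent; root genes
#' draw their hidden state from Bernoulli(0.5), children vote over their
#' parents (see [emission_model()]).  Dynamic topologies: hidden states
#' evolve across time steps within replicate series — parents at time `t`
#' determine a child's state at `t + 1`, parent-free genes resample — and
#' the replicate boundaries are recorded as series breaks.  The same seed
#' always reproduces the identical dataset.
#'
#' @param topology a `bnx_topology`.
#' @param n_obs number of observation columns (>= 1).
#' @param seed RNG seed.
#' @param emission an [emission_model()].
#' @param mixed_signs randomize edge signs to +/- (default all activating).
#' @param series_length time points per replicate (dynamic mode only).
#' @return list of class `bnx_simulation` with `dataset` ([bnx_dataset()]),
#'   `gold` ([bnx_gold()]), `topology`, `states`.
#' @export
simulate_observations <- function(topology, n_obs, seed = 1L,
                                  emission = emission_model(),
                                  mixed_signs = FALSE, series_length = 20L) {
  stopifnot(inherits(topology, "bnx_topology"),
            inherits(emission, "bnx_emission"))
  n_obs <- as.integer(n_obs)
  if (is.na(n_obs) || n_obs < 1L)
    stop("n_obs must be at least 1", call. = FALSE)
  n <- topology$n
  adj <- topology$adjacency
  with_seed(seed, {
    signs <- matrix(1, n, n, dimnames = dimnames(adj))
    if (mixed_signs)
      signs[adj] <- sample(c(-1, 1), sum(adj), replace = TRUE)
    states <- matrix(0L, n, n_obs,
                     dimnames = list(topology$variables, NULL))
    breaks <- 0L
    if (topology$mode == "static") {
      topo_order <- match(unlist(topology$layering), topology$variables)
      for (i in topo_order) {           # layer order is topological
        pa <- which(adj[, i])
        states[i, ] <- if (!length(pa))
          stats::rbinom(n_obs, 1L, 0.5)
        else
          vote_states(states[pa, , drop = FALSE], signs[pa, i],
                      emission$flip_prob, n_obs)
      }
      conditions <- paste0("OBS", seq_len(n_obs))
    } else {
      series_length <- max(2L, as.integer(series_length))
      t_in_series <- (seq_len(n_obs) - 1L) %% series_length
      breaks <- sort(unique(c(0L, which(t_in_series == 0L) - 1L)))
      for (t in seq_len(n_obs)) {
        if (t_in_series[t] == 0L) {
          states[, t] <- stats::rbinom(n, 1L, 0.5)
        } else {
          for (i in seq_len(n)) {
            pa <- which(adj[, i])
            states[i, t] <- if (!length(pa)) stats::rbinom(1L, 1L, 0.5)
            else vote_states(states[pa, t - 1L, drop = FALSE],
                             signs[pa, i], emission$flip_prob, 1L)
          }
        }
      }
      conditions <- paste0("S", cumsum(t_in_series == 0L), "T",
                           t_in_series + 1L)
    }
    mu <- emission$mu_low + states * (emission$mu_high - emission$mu_low)
    values <- mu + matrix(stats::rnorm(n * n_obs, 0, emission$sigma),
                          n, n_obs)
  })
  dimnames(values) <- list(topology$variables, conditions)
  layers <- if (topology$mode == "static") topology$layering else list()
  dataset <- bnx_dataset(values, variables = topology$variables,
                         conditions = conditions,
                         regulator_layers = layers,
                         series_breaks = breaks)
  gold <- bnx_gold(1 * adj, topology$variables, directed = TRUE)
  structure(list(dataset = dataset, gold = gold, topology = topology,
                 states = states, signs = signs, emission = emission,
                 seed = seed),
            class = "bnx_simulation")
}

#' Export a simulated benchmark to files
#'
#' Writes `expression.txt` (the learning-data text format) and `gold.tsv`
#' (a parent/child/weight edge list).  `layout = "layered"` emits one
#' `#regulators` line per layer (top-down); `layout = "single"` one line
#' naming every gene with at least one target.  Dynamic simulations carry
#' no regulator preamble (only `#series`), since regulator lists are what
#' make a dataset static.
#'
#' @param sim a [simulate_observations()] result.
#' @param dir output directory (created if needed).
#' @param layout `"layered"` or `"single"`.
#' @return named character vector of the file paths.
#' @export
export_benchmark <- function(sim, dir, layout = c("layered", "single")) {
  layout <- match.arg(layout)
  stopifnot(inherits(sim, "bnx_simulation"))
  dataset <- sim$dataset
  if (sim$topology$mode == "dynamic") {
    if (layout == "layered")
      stop("layered regulator layout requires a static topology",
           call. = FALSE)
  } else if (layout == "single") {
    regulators <- sim$topology$variables[rowSums(sim$topology$adjacency) > 0]
    dataset$regulator_layers <- list(regulators)
  } else {
    dataset$regulator_layers <- sim$topology$layering
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.txt")
  gold_path <- file.path(dir, "gold.tsv")
  format_expression_file(dataset, expr_path)
  e <- which(sim$topology$adjacency, arr.ind = TRUE)
  writeLines(sprintf("%s\t%s\t1", sim$topology$variables[e[, 1L]],
                     sim$topology$variables[e[, 2L]]), gold_path)
  c(expression = expr_path, gold = gold_path)
}
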