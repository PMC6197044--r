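# Shared fixtures and independent oracles.

four_gene_text <- function() {
  c("#regulators G1 G2",
    "conditions\tEXP0\tEXP1\tEXP2\tEXP3\tEXP4\tEXP5",
    "G1\t0.2\t3.4\t1.3\t7.4\t2.2\t0.4",
    "G2\t4.5\t7.8\t0.3\t5.6\t3.3\t1.1",
    "G3\t1.0\t2.9\t0.8\t5.5\t1.6\t2.8",
    "G4\t3.2\t6.5\t0.5\t3.1\t8.2\t5.0")
}

four_gene_dataset <- function() parse_expression_file(four_gene_text())

# Random continuous dataset; static variants get 1-3 regulator layers.
random_dataset <- function(n_var, n_obs, mode = c("dynamic", "static"),
                           seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  vars <- paste0("V", seq_len(n_var))
  vals <- matrix(round(rnorm(n_var * n_obs), 3), n_var, n_obs)
  layers <- list()
  if (mode == "static") {
    nl <- sample(1:min(3, n_var - 1), 1)
    cut <- sort(sample(seq_len(n_var - 1), nl))
    idx <- split(vars, findInterval(seq_len(n_var), cut + 1L))
    layers <- unname(idx)
  }
  bnx_dataset(vals, variables = vars,
              conditions = paste0("C", seq_len(n_obs)),
              regulator_layers = layers)
}

# Independent exhaustive search: enumerate every nonempty subset of the pool
# up to `limit` (the empty set only for an empty pool), score with the
# exported scorers, and rank with an independently coded comparator.
brute_force_parents <- function(child, ddata, pool, dataset, score = "mdl",
                                limit = 2, k_subopt = 0, ess = 1,
                                mit_alpha = 0.999, priors = NULL) {
  score_fun <- switch(score,
    mdl = function(ch, pa) score_mdl(ch, pa, ddata, priors),
    bde = function(ch, pa) score_bde(ch, pa, ddata, priors, ess = ess),
    mit = function(ch, pa) score_mit(ch, pa, ddata, alpha = mit_alpha))
  if (length(pool) == 0) {
    s <- score_fun(child, character(0))
    return(data.frame(rank = 1L, parents = "", g = s$g, d = s$d,
                      total = s$total, stringsAsFactors = FALSE))
  }
  amat <- if (dataset$mode == "dynamic") {
    pr <- bnexact:::series_pairs(dataset)
    a <- suppressWarnings(cor(t(dataset$values[, pr$pred, drop = FALSE]),
                              t(dataset$values[, pr$succ, drop = FALSE])))
    a[!is.finite(a)] <- 0; abs(a)
  } else {
    a <- suppressWarnings(cor(t(dataset$values)))
    a[!is.finite(a)] <- 0; abs(a)
  }
  kmax <- if (limit <= 0) length(pool) else min(limit, length(pool))
  rows <- list()
  for (card in seq_len(kmax)) {
    cmb <- combn(seq_along(pool), card)
    for (j in seq_len(ncol(cmb))) {
      pa <- pool[cmb[, j]]
      pa <- pa[order(match(pa, dataset$variables))]
      s <- score_fun(child, pa)
      rows[[length(rows) + 1L]] <- data.frame(
        parents = paste(pa, collapse = ","), g = s$g, d = s$d,
        total = s$total, cardinality = card,
        assoc = mean(amat[pa, child]), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(round(df$total, 9), df$cardinality, -df$assoc, df$parents,
                 method = "radix"), ]
  df <- head(df, k_subopt + 1)
  data.frame(rank = seq_len(nrow(df)), parents = df$parents, g = df$g,
             d = df$d, total = df$total, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Entropy (bits) of a discrete vector / conditional on a configuration.
entropy_bits <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

cond_entropy_bits <- function(y, cfg) {
  h <- 0
  for (c in unique(cfg)) {
    sel <- cfg == c
    h <- h + sum(sel) / length(y) * entropy_bits(y[sel])
  }
  h
}

mutual_info_bits <- function(x, y) entropy_bits(y) - cond_entropy_bits(y, x)

# Exhaustive concordant-pair AUROC with half credit for ties.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Direct product-of-Gamma evaluation of the BDe marginal likelihood.
bde_oracle_bits <- function(y, X, kc, kp, ess) {
  if (is.null(X)) { cfg <- rep(0, length(y)); q <- 1 }
  else {
    cfg <- 0; m <- 1
    for (i in seq_len(nrow(X))) { cfg <- cfg + X[i, ] * m; m <- m * kp[i] }
    q <- m
  }
  a_cell <- ess / (q * kc); a_cfg <- ess / q
  logml <- 0
  for (c in unique(cfg)) {
    sel <- cfg == c
    logml <- logml + lgamma(a_cfg) - lgamma(a_cfg + sum(sel))
    for (k in unique(y[sel]))
      logml <- logml + lgamma(a_cell + sum(y[sel] == k)) - lgamma(a_cell)
  }
  -logml / log(2)
}

# Manually assembled network fixture (for evaluation tests).
manual_network <- function(variables, sets, mode = "static",
                           fingerprint = "test") {
  bnexact:::new_bnx_network(variables, mode, fingerprint, sets)
}

graded_benchmark <- function(n, n_obs, seed, layout = "layered", ...) {
  sim <- simulate_observations(make_graded_topology(n), n_obs, seed = seed,
                               ...)
  dir <- file.path(tempfile("bench"), "d")
  files <- export_benchmark(sim, dir, layout = layout)
  list(sim = sim, files = files, dataset = parse_expression_file(files[["expression"]]))
}
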