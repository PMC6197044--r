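test_that("candidate pools respect mode, layers and self-loop settings", {
  # cascade of regulator layers: plcg on top, then PIP3
  cascade <- bnx_dataset(matrix(seq_len(4 * 6), 4, 6,
                              dimnames = list(c("plcg", "PIP3", "PIP2",
                                                "pakts473"), NULL)),
                       regulator_layers = list("plcg", "PIP3"))
  expect_equal(candidate_parent_pool("PIP2", cascade), c("plcg", "PIP3"))
  expect_equal(candidate_parent_pool("PIP3", cascade), "plcg")
  expect_equal(candidate_parent_pool("plcg", cascade), character(0))

  dyn <- random_dataset(20, 5, "dynamic", seed = 3)
  expect_length(candidate_parent_pool("V7", dyn), 19)
  dyn$self_loops <- TRUE
  expect_length(candidate_parent_pool("V7", dyn), 20)
  expect_true("V7" %in% candidate_parent_pool("V7", dyn))
})

test_that("the pruned search matches exhaustive enumeration exactly", {
  cases <- expand.grid(seed = 1:6, score = c("mdl", "bde", "mit"),
                       mode = c("dynamic", "static"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    set.seed(cs$seed * 100)
    n_var <- sample(3:6, 1); n_obs <- sample(8:30, 1)
    limit <- sample(1:3, 1); k_subopt <- sample(0:5, 1)
    ds <- random_dataset(n_var, n_obs, cs$mode, seed = cs$seed)
    dd <- discretize(ds)
    for (child in ds$variables) {
      pool <- candidate_parent_pool(child, ds)
      got <- find_optimal_parents(child, dd, pool, score = cs$score,
                                  limit = limit, k_subopt = k_subopt,
                                  dataset = ds)
      want <- brute_force_parents(child, dd, pool, ds, score = cs$score,
                                  limit = limit, k_subopt = k_subopt)
      expect_equal(got, want, tolerance = 0,
                   info = sprintf("seed %d score %s mode %s child %s",
                                  cs$seed, cs$score, cs$mode, child))
    }
  }
})

test_that("early stopping only skips work, never changes the result", {
  for (seed in 1:5) {
    ds <- random_dataset(5, 20, "dynamic", seed = seed)
    dd <- discretize(ds)
    for (score in c("mdl", "bde", "mit")) {
      a <- find_optimal_parents("V1", dd, candidate_parent_pool("V1", ds),
                                score = score, limit = 3, k_subopt = 2,
                                dataset = ds, use_stop = TRUE)
      b <- find_optimal_parents("V1", dd, candidate_parent_pool("V1", ds),
                                score = score, limit = 3, k_subopt = 2,
                                dataset = ds, use_stop = FALSE)
      expect_equal(a, b, tolerance = 0)
    }
  }
})

test_that("suboptimal-set lists grow as prefixes of one another", {
  ds <- random_dataset(6, 25, "dynamic", seed = 11)
  dd <- discretize(ds)
  pool <- candidate_parent_pool("V2", ds)
  prev <- NULL
  for (s in c(0, 2, 5)) {
    cur <- find_optimal_parents("V2", dd, pool, limit = 2, k_subopt = s,
                                dataset = ds)
    if (!is.null(prev))
      expect_equal(cur[seq_len(nrow(prev)), ], prev, tolerance = 0)
    prev <- cur
  }
})

test_that("a child with an empty pool receives the empty parent set", {
  ds <- four_gene_dataset()
  dd <- discretize(ds)
  res <- find_optimal_parents("G1", dd, candidate_parent_pool("G1", ds),
                              dataset = ds)
  expect_equal(nrow(res), 1)
  expect_equal(res$parents, "")
  one <- bnx_dataset(rbind(A = c(1, 2, 3, 2)))
  net1 <- learn_network(one)    # dynamic, self-loops off
  expect_equal(net1$sets$A$parents, "")
})

test_that("the worked four-gene example is learned exactly", {
  ds <- four_gene_dataset()
  dd <- discretize(ds)
  g3 <- find_optimal_parents("G3", dd, candidate_parent_pool("G3", ds),
                             dataset = ds)
  expect_equal(g3$parents[1], "G1")
  net <- learn_network(ds)
  expect_identical(sort(write_sif(net, ds)), c("G1 + G3", "G2 + G4"))
})

test_that("learning is deterministic and static results are acyclic", {
  ds <- graded_benchmark(6, 80, seed = 5)$dataset
  n1 <- learn_network(ds, k_subopt = 2)
  n2 <- learn_network(ds, k_subopt = 2)
  expect_identical(serialize_network(n1), serialize_network(n2))
  e <- bnexact:::rank1_edges(n1)
  # layer pools only ever point down the hierarchy
  idx <- match(e$parent, ds$variables) < match(e$child, ds$variables)
  expect_true(all(idx))
})

test_that("static learning without regulators is a configuration error", {
  dyn <- random_dataset(3, 10, "dynamic", seed = 1)
  expect_error(learn_network(dyn, mode = "static"), "no regulators")
})
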