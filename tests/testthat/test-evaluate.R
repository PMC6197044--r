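test_that("confidences are exp2-weighted over kept parent sets", {
  vars <- c("A", "B", "C", "X")
  # one kept set: full confidence
  net <- manual_network(vars, list(
    X = data.frame(rank = 1L, parents = "A", g = 1, d = 1, total = 2)))
  expect_equal(confidence_matrix(net)$values["A", "X"], 1)

  # two equal-scoring sets share it
  net <- manual_network(vars, list(
    X = data.frame(rank = 1:2, parents = c("A", "B"), g = 0, d = 3,
                   total = c(3, 3))))
  cm <- confidence_matrix(net)
  expect_equal(cm$values["A", "X"], 0.5)
  expect_equal(cm$values["B", "X"], 0.5)

  # totals one bit apart: weights 4/7, 2/7, 1/7
  net <- manual_network(vars, list(
    X = data.frame(rank = 1:3, parents = c("A", "B", "C"), g = 0, d = 0,
                   total = c(5, 6, 7))))
  cm <- confidence_matrix(net)
  expect_equal(unname(cm$values[c("A", "B", "C"), "X"]), c(4, 2, 1) / 7)
  expect_equal(cm$values["A", "B"], 0)
})

test_that("symmetrization keeps the higher edge probability and is idempotent", {
  vars <- paste0("V", 1:3)
  cm <- structure(list(variables = vars,
                       values = matrix(0, 3, 3, dimnames = list(vars, vars)),
                       directed = TRUE), class = "bnx_confidence")
  cm$values[1, 3] <- 0.8; cm$values[3, 1] <- 0.2
  s <- symmetrize(cm)
  expect_equal(s$values[1, 3], 0.8)
  expect_equal(s$values[3, 1], 0.8)
  expect_false(s$directed)
  expect_equal(symmetrize(s)$values, s$values)
  zero <- symmetrize(structure(list(variables = vars,
                                    values = matrix(0, 3, 3),
                                    directed = TRUE),
                               class = "bnx_confidence"))
  expect_true(all(zero$values == 0))
})

test_that("perfect and inverted rankings bracket the metrics", {
  vars <- paste0("V", 1:5)
  adj <- matrix(0, 5, 5, dimnames = list(vars, vars))
  adj[1, 2] <- adj[2, 3] <- adj[1, 4] <- 1
  gold <- bnx_gold(adj, vars)
  perfect <- structure(list(variables = vars, values = adj, directed = TRUE),
                       class = "bnx_confidence")
  r <- evaluate_network(perfect, gold)
  expect_equal(r$auroc, 1)
  expect_equal(r$aupr, 1)

  inv <- perfect
  inv$values <- 1 - adj; diag(inv$values) <- 0
  expect_equal(evaluate_network(inv, gold)$auroc, 0)

  none <- bnx_gold(matrix(0, 5, 5), vars)
  expect_error(evaluate_network(perfect, none), "no positive")
})

test_that("AUROC equals the exhaustive concordant-pair oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    vars <- paste0("V", seq_len(n))
    adj <- matrix(rbinom(n * n, 1, 0.2), n, n,
                  dimnames = list(vars, vars)); diag(adj) <- 0
    if (sum(adj) == 0) adj[1, 2] <- 1
    conf <- matrix(round(runif(n * n), 2), n, n,
                   dimnames = list(vars, vars)); diag(conf) <- 0
    gold <- bnx_gold(adj, vars)
    cm <- structure(list(variables = vars, values = conf, directed = TRUE),
                    class = "bnx_confidence")
    r <- evaluate_network(cm, gold)
    off <- row(adj) != col(adj)
    expect_equal(r$auroc, auroc_oracle(conf[off], adj[off] == 1),
                 tolerance = 1e-12)
  }
})

test_that("top-fraction evaluation treats unretrieved positives as missed", {
  vars <- paste0("V", 1:10)
  adj <- matrix(0, 10, 10, dimnames = list(vars, vars))
  set.seed(5)
  adj[sample(which(row(adj) != col(adj)), 5)] <- 1
  gold <- bnx_gold(adj, vars)
  perfect <- structure(list(variables = vars, values = adj, directed = TRUE),
                       class = "bnx_confidence")
  # 5 positives fit inside the top 20% of 90 pairs
  r <- evaluate_network(perfect, gold, fraction = 0.2)
  expect_equal(r$aupr, 1)
  expect_equal(r$n_evaluated, 18)

  # push one positive below every negative: it can never be retrieved
  worst <- perfect
  pos <- which(adj == 1)
  worst$values[pos[1]] <- 0
  worst$values[adj == 0 & row(adj) != col(adj)] <- 0.1
  r2 <- evaluate_network(worst, gold, fraction = 0.05)
  expect_lt(r2$aupr, 1)
  # undirected evaluation needs both sides symmetric
  expect_error(evaluate_network(perfect, bnx_gold(adj, vars, directed = FALSE)),
               "symmetrize")
  und <- evaluate_network(symmetrize(perfect),
                          bnx_gold(adj, vars, directed = FALSE))
  expect_equal(und$auroc, 1)
})

test_that("the evaluation pipeline scores a learned benchmark sensibly", {
  sim <- simulate_observations(make_graded_topology(6), 800, seed = 31)
  net <- learn_network(sim$dataset, limit = 0, k_subopt = 3)
  res <- evaluate_network(confidence_matrix(net), sim$gold)
  expect_gt(res$auroc, 0.9)
  expect_equal(res$n_candidates, 30)
  expect_equal(res$n_positives, 15)
})
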