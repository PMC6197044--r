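test_that("binarization policies and evidence masking behave as documented", {
  ds <- four_gene_dataset()
  dd_med <- discretize(ds, "median")
  # median of G1 is 1.75; strictly-above goes to state 1
  expect_equal(unname(dd_med$states["G1", ]), c(0L, 1L, 0L, 1L, 1L, 0L))
  dd_mean <- discretize(ds, "mean")
  expect_equal(unname(dd_mean$states["G1", ]), c(0L, 1L, 0L, 1L, 0L, 0L))

  # dynamic: 6 conditions with a replicate break after 3 -> 4 lagged pairs
  dyn <- parse_expression_file(c("#series C4",
                                 "conditions C1 C2 C3 C4 C5 C6",
                                 "A 1 2 3 4 5 6", "B 6 5 4 3 2 1"))
  dd <- discretize(dyn)
  expect_length(dd$pairs$pred, 4)
  expect_equal(dd$pairs$pred, c(1L, 2L, 4L, 5L))
  expect_equal(dd$pairs$succ, c(2L, 3L, 5L, 6L))

  # perturbation masks the child's evidence only
  pert <- parse_expression_file(c("#regulators G1",
                                  "#perturbed G2 EXP0",
                                  "conditions EXP0 EXP1 EXP2 EXP3",
                                  "G1 1 2 3 4", "G2 4 3 2 1"))
  dd <- discretize(pert)
  expect_equal(dd$obs$G2, 2:4)
  expect_equal(dd$obs$G1, 1:4)

  expect_error(discretize(bnx_dataset(rbind(A = rep(1, 5), B = 1:5)),
                          "quantile:3"),
               "'A' is single-state")
})

test_that("MDL score matches its closed forms", {
  # binary child, N = 8, 4 ones / 4 zeros, empty parent set
  ds <- bnx_dataset(rbind(X = c(0, 0, 0, 0, 1, 1, 1, 1) * 10),
                    regulator_layers = list("X"))
  s <- score_mdl("X", character(0), discretize(ds))
  expect_equal(s$g, 1.5)
  expect_equal(s$d, 8)

  # child identical to a parent: zero conditional entropy
  ds2 <- bnx_dataset(rbind(P = c(1, 5, 1, 5, 5, 1), C = c(1, 5, 1, 5, 5, 1)),
                     regulator_layers = list("P"))
  s2 <- score_mdl("C", "P", discretize(ds2))
  expect_equal(s2$d, 0)

  # 3 binary parents, N = 16: g = (log2 16)/2 * 1 * 8 = 16; d checked against
  # an independent contingency-table entropy oracle
  set.seed(42)
  vals <- matrix(rnorm(4 * 16), 4, 16,
                 dimnames = list(c("A", "B", "C", "Y"), NULL))
  ds3 <- bnx_dataset(vals, regulator_layers = list(c("A", "B", "C")))
  dd3 <- discretize(ds3)
  s3 <- score_mdl("Y", c("A", "B", "C"), dd3)
  expect_equal(s3$g, 16)
  cfg <- paste(dd3$states["A", ], dd3$states["B", ], dd3$states["C", ])
  expect_equal(s3$d, 16 * cond_entropy_bits(dd3$states["Y", ], cfg))

  # empty-parent d is exactly N * H(child)
  for (seed in 1:5) {
    set.seed(seed)
    ds4 <- bnx_dataset(matrix(rnorm(3 * 11), 3,
                              dimnames = list(c("A", "B", "Y"), NULL)),
                       regulator_layers = list(c("A", "B")))
    dd4 <- discretize(ds4)
    s4 <- score_mdl("Y", character(0), dd4)
    expect_equal(s4$d, 11 * entropy_bits(dd4$states["Y", ]))
  }
})

test_that("BDe score equals the direct product-of-Gamma evaluation", {
  # N = 1, empty parents, binary child: marginal likelihood 1/2 at ess = 1
  ds <- bnx_dataset(rbind(X = 3), conditions = "C1",
                    regulator_layers = list("X"))
  s <- score_bde("X", character(0), discretize(ds))
  expect_equal(s$d, 1)
  expect_equal(s$g, 0)

  # neutral priors cost one bit per edge
  ds2 <- four_gene_dataset()
  dd2 <- discretize(ds2)
  expect_equal(score_bde("G3", c("G1", "G2"), dd2)$g, 2)
  expect_equal(score_bde("G4", "G1", dd2)$g, 1)

  # an 8-observation two-parent table against the Gamma oracle
  dd <- discretize(bnx_dataset(rbind(A = c(1, 1, 9, 9, 1, 9, 1, 9),
                                     B = c(1, 9, 1, 9, 9, 1, 9, 1),
                                     Y = c(9, 9, 1, 1, 9, 1, 1, 9)),
                               regulator_layers = list(c("A", "B"))))
  s <- score_bde("Y", c("A", "B"), dd, ess = 1)
  expect_equal(s$d,
               bde_oracle_bits(dd$states["Y", ],
                               dd$states[c("A", "B"), ], 2, c(2, 2), 1),
               tolerance = 1e-12)

  # random small instances, several ess values
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(4:12, 1)
    vals <- matrix(rnorm(4 * N), 4, dimnames = list(LETTERS[1:4], NULL))
    dd <- discretize(bnx_dataset(vals,
                                 regulator_layers = list(c("A", "B", "C"))))
    pa <- sample(c("A", "B", "C"), sample(0:3, 1))
    ess <- sample(c(0.5, 1, 4), 1)
    s <- score_bde("D", pa, dd, ess = ess)
    oracle <- bde_oracle_bits(dd$states["D", ],
                              if (length(pa)) dd$states[pa, , drop = FALSE]
                              else NULL, 2, rep(2, length(pa)), ess)
    expect_equal(s$d, oracle, tolerance = 1e-9)
    expect_gte(s$d, 0)
  }
})

test_that("MIT score uses chi-square penalties and scaled conditional entropy", {
  ds <- bnx_dataset(rbind(P = rep(c(1, 9), 10),
                          Y = c(rep(1, 10), rep(9, 10))),
                    regulator_layers = list("P"))
  dd <- discretize(ds)
  # empty parent set carries no quantile penalty
  expect_equal(score_mit("Y", character(0), dd)$g, 0)
  # P carries no information on Y here: d = 2 * 20 * ln2 * H(Y)
  s <- score_mit("Y", "P", dd)
  expect_equal(s$d, 2 * 20 * log(2) * 1)
  expect_equal(s$g, qchisq(0.999, 1) / (2 * log(2)))
  # quantile-table oracle at alpha = 0.95
  expect_equal(score_mit("Y", "P", dd, alpha = 0.95)$g,
               3.841459 / (2 * log(2)), tolerance = 1e-6)
})

test_that("every scorer keeps g monotone under inclusion and d nonnegative", {
  set.seed(7)
  ds <- bnx_dataset(matrix(rnorm(5 * 24), 5,
                           dimnames = list(LETTERS[1:5], NULL)),
                    regulator_layers = list(c("A", "B", "C", "D")))
  dd <- discretize(ds)
  scorers <- list(
    mdl = function(ch, pa) score_mdl(ch, pa, dd),
    bde = function(ch, pa) score_bde(ch, pa, dd),
    mit = function(ch, pa) score_mit(ch, pa, dd))
  pool <- c("A", "B", "C", "D")
  for (nm in names(scorers)) {
    f <- scorers[[nm]]
    for (rep in 1:10) {
      pa <- sample(pool, sample(0:3, 1))
      extra <- sample(setdiff(pool, pa), 1)
      s_small <- f("E", pa)
      s_big <- f("E", c(pa, extra))
      expect_lte(s_small$g, s_big$g)
      expect_gte(s_small$d, 0)
      expect_gte(s_big$d, 0)
      if (nm == "mdl")   # conditioning never increases empirical entropy
        expect_gte(s_small$d + 1e-9, s_big$d)
    }
  }
})

test_that("edge priors reorder penalties without breaking monotonicity", {
  ds <- four_gene_dataset()
  dd <- discretize(ds)
  pr <- data.frame(parent = "G1", child = "G3", prob = 0.1)
  s_neutral <- score_mdl("G3", "G1", dd)
  s_prior <- score_mdl("G3", "G1", dd, priors = pr)
  expect_equal(s_prior$g - s_neutral$g, log2(0.5 / 0.1))
  # priors above 0.5 are clipped, never negative
  pr2 <- data.frame(parent = "G1", child = "G3", prob = 0.9)
  expect_equal(score_mdl("G3", "G1", dd, priors = pr2)$g, s_neutral$g)
  # BDe: g = log2(1/p) per edge
  expect_equal(score_bde("G3", "G1", dd, priors = pr)$g, log2(10),
               tolerance = 1e-12)
})

test_that("interaction signs follow the raw-scale correlation", {
  ds <- four_gene_dataset()
  expect_equal(edge_sign("G1", "G3", ds), "+")
  expect_equal(edge_sign("G2", "G4", ds), "+")
  anti <- bnx_dataset(rbind(P = c(1, 2, 3, 4), C = c(4, 3, 2, 1)))
  expect_equal(edge_sign("P", "C", anti), "-")
  expect_equal(edge_sign("P", "P", anti), "+")
})
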