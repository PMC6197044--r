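# Decomposable two-component scores --------------------------------------
#
# Every scorer returns, for one child and one candidate parent set, a pair
# (g, d) in bits with total = g + d, smaller is better:
#   g  complexity penalty; depends on the parent set (and edge priors), not
#      on how well it fits, and is nondecreasing under set inclusion.  This
#      monotonicity is what makes the search's early stopping sound.
#   d  nonnegative data-fit term.
#
# MDL: g = log2(N)/2 * (k_c - 1) * prod(k_p)  +  sum_p max(0, log2(0.5 / prior))
#      d = N * H(child | parents)                      (empirical, in bits)
# BDe: g = sum_p log2(1 / prior)
#      d = -log2 of the Dirichlet-multinomial marginal likelihood of the
#          child given the parent configuration, uniform pseudocounts
#          ess / (k_c * prod(k_p)) per cell
# MIT: g = sum over parents, taken in dataset order, of the chi-square
#          quantile at `alpha` with df = (k_c - 1)(k_p - 1) * prod(earlier
#          k_p), divided by 2 ln 2
#      d = 2 N ln 2 * (H(child) - I(child; parents)), clipped at 0

# Counts for child states (rows) x parent configurations (columns); the
# parent configuration index is built least-significant-parent-first in the
# order the parents are supplied.
count_table <- function(ev, parents, kc, kp) {
  if (length(parents) == 0L) {
    cfg <- rep(0L, ev$N); q <- 1
  } else {
    cfg <- 0; m <- 1
    for (j in seq_along(parents)) {
      cfg <- cfg + as.numeric(ev$E[parents[j], ]) * m
      m <- m * kp[j]
    }
    q <- m
  }
  code <- cfg * kc + ev$y
  counts <- tabulate(code + 1L, nbins = as.integer(q * kc))
  matrix(counts, nrow = kc)
}

d_entropy_bits <- function(M) {
  # sum_jk N_jk * log2(N_j / N_jk) = N * H(child | parents)
  nj <- colSums(M)
  pos <- M > 0
  sum(nj[nj > 0] * log2(nj[nj > 0])) - sum(M[pos] * log2(M[pos]))
}

d_bde_bits <- function(M, ess) {
  q <- ncol(M); kc <- nrow(M)
  a_cell <- ess / (q * kc)
  a_cfg <- ess / q
  nj <- colSums(M)
  obs_cfg <- nj > 0
  pos <- M > 0
  logml <- sum(lgamma(a_cfg) - lgamma(a_cfg + nj[obs_cfg])) +
    sum(lgamma(a_cell + M[pos]) - lgamma(a_cell))
  -logml / log(2)
}

qchisq_cache <- new.env(parent = emptyenv())
qchisq_bits <- function(alpha, df) {
  key <- sprintf("%.10g|%.10g", alpha, df)
  v <- qchisq_cache[[key]]
  if (is.null(v)) {
    v <- stats::qchisq(alpha, df) / (2 * log(2))
    qchisq_cache[[key]] <- v
  }
  v
}

make_scorer <- function(ddata, score = c("mdl", "bde", "mit"),
                        priors = NULL, ess = 1, alpha = 0.999) {
  score <- match.arg(score)
  nvar <- length(ddata$variables)
  if (is.null(priors))
    priors <- matrix(0.5, nvar, nvar,
                     dimnames = list(ddata$variables, ddata$variables))
  if (score == "bde" && ess <= 0) stop("ess must be positive", call. = FALSE)
  if (score == "mit" && (alpha <= 0 || alpha >= 1))
    stop("mit alpha must lie in (0, 1)", call. = FALSE)
  ev_cache <- vector("list", nvar)
  evidence <- function(child) {
    ev <- ev_cache[[child]]
    if (is.null(ev)) {
      ev <- child_evidence(ddata, child)
      if (ev$N == 0L)
        stop(sprintf("no effective observations for variable '%s'",
                     ddata$variables[child]), call. = FALSE)
      ev_cache[[child]] <<- ev
    }
    ev
  }
  ns <- ddata$nstates

  g_fun <- function(child, parents, N) {
    kc <- ns[child]
    switch(score,
      mdl = 0.5 * log2(N) * (kc - 1) * prod(ns[parents]) +
        sum(pmax(0, log2(0.5 / priors[cbind(parents, rep(child, length(parents)))]))),
      bde = sum(log2(1 / priors[cbind(parents, rep(child, length(parents)))])),
      mit = {
        p_ord <- sort(parents)  # dataset order
        g <- 0; m <- 1
        for (p in p_ord) {
          g <- g + qchisq_bits(alpha, (kc - 1) * (ns[p] - 1) * m)
          m <- m * ns[p]
        }
        g
      })
  }

  d_fun <- function(child, parents, ev) {
    M <- count_table(ev, parents, ns[child], ns[parents])
    base <- d_entropy_bits(M)
    switch(score,
      mdl = base,
      bde = d_bde_bits(M, ess),
      mit = max(0, 2 * log(2) * base))
  }

  score_set <- function(child, parents) {
    ev <- evidence(child)
    g <- g_fun(child, parents, ev$N)
    d <- d_fun(child, parents, ev)
    c(g = g, d = d)
  }

  # Sound lower bound on g over all parent sets of a given cardinality drawn
  # from `pool`: combine the `card` smallest parent state counts with the
  # `card` cheapest prior penalties.  Nondecreasing in `card`, so a single
  # comparison justifies skipping every remaining cardinality layer.
  lb_g <- function(child, card, pool) {
    if (card == 0L) return(0)
    kc <- ns[child]
    N <- evidence(child)$N
    ks <- sort(ns[pool])[seq_len(card)]
    switch(score,
      mdl = {
        pen <- sort(pmax(0, log2(0.5 / priors[pool, child])))[seq_len(card)]
        0.5 * log2(N) * (kc - 1) * prod(ks) + sum(pen)
      },
      bde = sum(sort(log2(1 / priors[pool, child]))[seq_len(card)]),
      mit = {
        g <- 0; m <- 1
        for (j in seq_len(card)) {
          g <- g + qchisq_bits(alpha, (kc - 1) * (ks[1L] - 1) * m)
          m <- m * ks[j]
        }
        g
      })
  }

  list(score = score, score_set = score_set, lb_g = lb_g,
       evidence = evidence, nstates = ns)
}

score_one <- function(score, child, parents, data, priors, ess, alpha) {
  stopifnot(inherits(data, "bnx_discrete"))
  ci <- match(child, data$variables)
  pi <- match(parents, data$variables)
  if (is.na(ci) || anyNA(pi)) stop("unknown variable name", call. = FALSE)
  if (anyDuplicated(pi) || (ci %in% pi && data$mode != "dynamic"))
    stop("parents must be distinct and exclude the child", call. = FALSE)
  pm <- NULL
  if (!is.null(priors)) {
    if (is.matrix(priors)) pm <- priors
    else {
      pm <- matrix(0.5, length(data$variables), length(data$variables),
                   dimnames = list(data$variables, data$variables))
      pm[cbind(match(priors$parent, data$variables),
               match(priors$child, data$variables))] <- priors$prob
    }
  }
  sc <- make_scorer(data, score, priors = pm, ess = ess, alpha = alpha)
  v <- sc$score_set(ci, pi)
  list(g = unname(v["g"]), d = unname(v["d"]), total = unname(v["g"] + v["d"]))
}

#' Decomposable parent-set scores
#'
#' Score one candidate parent set for one child on discretized evidence.
#' All three scores are reported in bits as a complexity penalty `g`, a
#' nonnegative data-fit term `d`, and their sum `total`; smaller is better.
#' `score_mdl` is the minimal-description-length score, `score_bde` the
#' Bayesian-Dirichlet-equivalence score (negative log marginal likelihood
#' with uniform pseudocounts of total weight `ess`), and `score_mit` a
#' mutual-information-test score whose penalty accumulates chi-square
#' quantiles at level `alpha`.
#'
#' Edge priors enter `g` additively per edge: `log2(0.5/p)` (clipped at 0)
#' for MDL and `log2(1/p)` for BDe, so a prior above the neutral 0.5 makes a
#' parent cheaper to include, and `g` remains nondecreasing under set
#' inclusion — the property the search's pruning relies on.
#'
#' @param child child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @param data a [discretize()]d dataset.
#' @param priors `NULL`, a `parent`/`child`/`prob` data frame, or a full
#'   parent-by-child matrix of prior probabilities.
#' @param ess equivalent sample size for BDe (> 0).
#' @param alpha chi-square level in (0, 1) for MIT.
#' @return list with `g`, `d`, `total` (bits).
#' @export
score_mdl <- function(child, parents, data, priors = NULL)
  score_one("mdl", child, parents, data, priors, 1, 0.999)

#' @rdname score_mdl
#' @export
score_bde <- function(child, parents, data, priors = NULL, ess = 1)
  score_one("bde", child, parents, data, priors, ess, 0.999)

#' @rdname score_mdl
#' @export
score_mit <- function(child, parents, data, alpha = 0.999)
  score_one("mit", child, parents, data, NULL, 1, alpha)
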