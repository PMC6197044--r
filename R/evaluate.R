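# Network evaluation: confidences, AUROC, AUPR ---------------------------

#' Edge-confidence matrix of a learned network
#'
#' Per child, each kept parent set is weighted by `2^(-total bits)`,
#' normalized over the kept sets; the confidence of an edge `p -> c` is the
#' summed weight of `c`'s sets containing `p`.  With a single kept set per
#' child every optimal edge gets confidence 1; suboptimal sets spread
#' graded confidences over their union of edges.  Pairs never seen in a
#' kept set score 0.
#'
#' @param network a `bnx_network`.
#' @return object of class `bnx_confidence` (fields `variables`, `values`
#'   parent-by-child matrix, `directed`).
#' @export
confidence_matrix <- function(network) {
  vars <- network$variables
  v <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (child in names(network$sets)) {
    df <- network$sets[[child]]
    w <- 2^(-(df$total - min(df$total)))
    w <- w / sum(w)
    for (r in seq_len(nrow(df))) {
      if (!nzchar(df$parents[r])) next
      for (parent in strsplit(df$parents[r], ",", fixed = TRUE)[[1L]])
        v[parent, child] <- v[parent, child] + w[r]
    }
  }
  structure(list(variables = vars, values = v, directed = TRUE),
            class = "bnx_confidence")
}

#' Symmetrize a confidence matrix
#'
#' For undirected evaluation: `out[i, j] = out[j, i] = max(in[i, j],
#' in[j, i])` — the higher edge probability is preserved.  Idempotent.
#'
#' @param conf a [confidence_matrix()].
#' @return the undirected `bnx_confidence`.
#' @export
symmetrize <- function(conf) {
  stopifnot(inherits(conf, "bnx_confidence"))
  conf$values <- pmax(conf$values, t(conf$values))
  conf$directed <- FALSE
  conf
}

#' @export
print.bnx_confidence <- function(x, ...) {
  cat(sprintf("<bnx_confidence> %d variables, %s, %d nonzero entries\n",
              length(x$variables), if (x$directed) "directed" else "undirected",
              sum(x$values > 0)))
  invisible(x)
}

#' Score a confidence matrix against a gold standard
#'
#' Candidate pairs are all non-diagonal ordered pairs (directed) or
#' unordered pairs (undirected; the gold standard must then be symmetric —
#' [symmetrize()] the confidences first).  Pairs are ranked by confidence,
#' tied confidences share their average rank, and with `fraction < 1` only
#' the top `ceiling(fraction * candidates)` pairs are retained — positives
#' outside that prefix count as never retrieved (the recall denominator
#' stays at all positives).  AUROC is the Mann-Whitney rank statistic;
#' AUPR integrates the precision-recall curve over the retained prefix.
#'
#' @param conf a `bnx_confidence`.
#' @param gold a [bnx_gold()] with the same variables and directedness.
#' @param fraction fraction of all possible pairs to evaluate, in (0, 1\].
#' @return object of class `bnx_eval` with fields `auroc`, `aupr`,
#'   `fraction_evaluated`, `n_positives`, `n_candidates`.
#' @export
evaluate_network <- function(conf, gold, fraction = 1) {
  stopifnot(inherits(conf, "bnx_confidence"), inherits(gold, "bnx_gold"))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (!setequal(conf$variables, gold$variables))
    stop("confidence matrix and gold standard cover different variables",
         call. = FALSE)
  if (conf$directed != gold$directed)
    stop("directedness of predictions and gold standard must agree ",
         "(symmetrize() the confidences for an undirected gold standard)",
         call. = FALSE)
  adj <- gold$adjacency[conf$variables, conf$variables]
  n <- length(conf$variables)
  if (conf$directed) {
    idx <- which(row(adj) != col(adj))
  } else {
    idx <- which(upper.tri(adj))
  }
  s <- conf$values[idx]
  y <- adj[idx] >= 0.5
  P <- sum(y); NN <- sum(!y)
  if (P == 0L) stop("gold standard contains no positive edges", call. = FALSE)
  if (NN == 0L) stop("gold standard contains no negative pairs", call. = FALSE)
  m <- ceiling(fraction * length(s))
  ord <- order(-s, seq_along(s))          # stable truncation
  retained <- ord[seq_len(m)]
  s_trunc <- rep(-Inf, length(s))
  s_trunc[retained] <- s[retained]
  r <- rank(s_trunc, ties.method = "average")
  auroc <- (sum(r[y]) - P * (P + 1) / 2) / (P * NN)
  # PR over the retained prefix, grouped by tied confidence
  sr <- s[retained]
  yr <- y[retained]
  o <- order(-sr)
  sr <- sr[o]; yr <- yr[o]
  grp <- cumsum(!duplicated(sr))
  tp <- cumsum(yr); fp <- cumsum(!yr)
  last <- !duplicated(grp, fromLast = TRUE)
  TP <- tp[last]; FP <- fp[last]
  rec <- TP / P
  prec <- TP / (TP + FP)
  rec <- c(0, rec); prec <- c(prec[1L], prec)
  aupr <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  structure(list(auroc = auroc, aupr = aupr,
                 fraction_evaluated = fraction, n_positives = P,
                 n_candidates = length(s), n_evaluated = m),
            class = "bnx_eval")
}

#' @export
print.bnx_eval <- function(x, ...) {
  cat(sprintf("<bnx_eval> AUROC %.4f  AUPR %.4f  (%d positives / %d pairs, top %.0f%% evaluated)\n",
              x$auroc, x$aupr, x$n_positives, x$n_candidates,
              100 * x$fraction_evaluated))
  invisible(x)
}
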