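# Exact parent-set search -------------------------------------------------

#' Candidate parent pool of one child
#'
#' Dynamic mode: every variable (excluding the child itself unless
#' self-loops are allowed).  Static mode: the union of regulator layers
#' strictly above the child's layer; a child that is not itself a regulator
#' may be regulated by every regulator.  Same-layer regulation is never
#' allowed — this is what guarantees the learned static network is acyclic.
#' A static child with an empty pool (e.g. in the top layer) simply receives
#' the empty parent set; it is not an error.
#'
#' @param child child variable name.
#' @param dataset a [bnx_dataset()].
#' @param self_loops allow `child` itself in the pool (dynamic mode only).
#' @return character vector of candidate parents, in dataset order.
#' @export
candidate_parent_pool <- function(child, dataset,
                                  self_loops = dataset$self_loops) {
  stopifnot(child %in% dataset$variables)
  if (dataset$mode == "dynamic") {
    pool <- dataset$variables
    if (!isTRUE(self_loops)) pool <- setdiff(pool, child)
    return(pool)
  }
  layer_of <- NA_integer_
  for (l in seq_along(dataset$regulator_layers))
    if (child %in% dataset$regulator_layers[[l]]) { layer_of <- l; break }
  upto <- if (is.na(layer_of)) length(dataset$regulator_layers) else layer_of - 1L
  pool <- unlist(dataset$regulator_layers[seq_len(upto)], use.names = FALSE)
  dataset$variables[dataset$variables %in% pool]  # dataset order
}

# Deterministic total order on scored parent sets: rounded total score, then
# cardinality, then stronger raw-scale association with the child, then the
# comma-joined parent names (byte order).  The rounding absorbs
# last-ulp differences between algebraically identical totals.
order_sets <- function(df) {
  order(round(df$total, 9), df$cardinality, -df$assoc, df$parents,
        method = "radix")
}

set_key <- function(vars, idx) paste(vars[sort(idx)], collapse = ",")

serial_evaluator <- function(scorer) {
  function(child, subsets) {
    t(vapply(subsets, function(s) scorer$score_set(child, s), numeric(2)))
  }
}

# Core search for one child.  Enumerates nonempty subsets of the pool in
# cardinality layers (the empty set only when the pool itself is empty),
# keeps the k_subopt + 1 best, and stops before a layer whose penalty lower
# bound already exceeds the worst kept total.
find_parents_core <- function(child, pool, scorer, limit, k_subopt,
                              evaluator, assoc, vars, use_stop = TRUE) {
  k_keep <- k_subopt + 1L
  if (length(pool) == 0L) {
    v <- scorer$score_set(child, integer(0))
    return(data.frame(rank = 1L, parents = "", g = v[["g"]], d = v[["d"]],
                      total = v[["g"]] + v[["d"]],
                      stringsAsFactors = FALSE))
  }
  np <- length(pool)
  kmax <- if (limit <= 0L) np else min(limit, np)
  kept <- NULL
  for (card in seq_len(kmax)) {
    if (use_stop && !is.null(kept) && nrow(kept) >= k_keep &&
        scorer$lb_g(child, card, pool) >= max(kept$total))
      break
    combos <- utils::combn(seq_len(np), card)
    subsets <- lapply(seq_len(ncol(combos)), function(j) pool[combos[, j]])
    sc <- evaluator(child, subsets)
    if (any(sc[, 2L] < -1e-9))
      stop("internal consistency error: negative data-fit score", call. = FALSE)
    layer <- data.frame(
      parents = vapply(subsets, function(s) set_key(vars, s), ""),
      g = sc[, 1L], d = sc[, 2L], total = sc[, 1L] + sc[, 2L],
      cardinality = card,
      assoc = vapply(subsets, function(s) mean(assoc[s, child]), 0),
      stringsAsFactors = FALSE)
    kept <- rbind(kept, layer)
    kept <- kept[order_sets(kept), , drop = FALSE]
    if (nrow(kept) > k_keep) kept <- kept[seq_len(k_keep), , drop = FALSE]
  }
  data.frame(rank = seq_len(nrow(kept)), parents = kept$parents,
             g = kept$g, d = kept$d, total = kept$total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Optimal and suboptimal parent sets of one child
#'
#' Exact top-(`k_subopt` + 1) search over all parent sets of size at most
#' `limit` drawn from `pool`, by nondecreasing-penalty enumeration with
#' sound early stopping: candidate sets are scored in cardinality layers and
#' the search stops once the smallest possible penalty of the next layer
#' cannot beat the worst kept total.  Early stopping never changes the
#' result, only skips work.
#'
#' @param child child variable name.
#' @param data a [discretize()]d dataset.
#' @param pool candidate parent names (see [candidate_parent_pool()]).
#' @param score `"mdl"`, `"bde"` or `"mit"`.
#' @param limit maximum parent-set size; 0 means no explicit limit.
#' @param k_subopt number of suboptimal sets to keep beside the optimum.
#' @param priors,ess,mit_alpha scoring options, see [score_mdl()].
#' @param assoc optional precomputed association matrix used only to break
#'   exact score ties (by default derived from `dataset` when given).
#' @param dataset the originating [bnx_dataset()]; needed for tie-breaking
#'   associations, otherwise ties fall back to name order.
#' @param use_stop disable to force full enumeration (testing aid).
#' @return data frame with columns `rank`, `parents` (comma-joined names),
#'   `g`, `d`, `total`.
#' @export
find_optimal_parents <- function(child, data, pool, score = "mdl",
                                 limit = 2L, k_subopt = 0L, priors = NULL,
                                 ess = 1, mit_alpha = 0.999,
                                 dataset = NULL, assoc = NULL,
                                 use_stop = TRUE) {
  stopifnot(inherits(data, "bnx_discrete"))
  ci <- match(child, data$variables)
  pidx <- match(pool, data$variables)
  if (is.na(ci) || anyNA(pidx)) stop("unknown variable name", call. = FALSE)
  pm <- if (is.matrix(priors)) priors else if (is.data.frame(priors)) {
    m <- matrix(0.5, length(data$variables), length(data$variables),
                dimnames = list(data$variables, data$variables))
    m[cbind(match(priors$parent, data$variables),
            match(priors$child, data$variables))] <- priors$prob
    m
  } else NULL
  scorer <- make_scorer(data, score, priors = pm, ess = ess, alpha = mit_alpha)
  if (is.null(assoc))
    assoc <- if (!is.null(dataset)) association_matrix(dataset) else
      matrix(0, length(data$variables), length(data$variables))
  find_parents_core(ci, pidx, scorer, as.integer(limit),
                    as.integer(k_subopt), serial_evaluator(scorer),
                    assoc, data$variables, use_stop = use_stop)
}

# Network container -------------------------------------------------------

config_fingerprint <- function(score, limit, k_subopt, discretization,
                               ess, mit_alpha, mode, self_loops) {
  sprintf("score=%s;limit=%d;subopt=%d;disc=%s;ess=%.10g;alpha=%.10g;mode=%s;self_loops=%s",
          score, as.integer(limit), as.integer(k_subopt), discretization,
          ess, mit_alpha, mode, if (isTRUE(self_loops)) "yes" else "no")
}

new_bnx_network <- function(variables, mode, fingerprint, sets) {
  structure(list(variables = variables, mode = mode,
                 fingerprint = fingerprint, sets = sets),
            class = "bnx_network")
}

#' @export
print.bnx_network <- function(x, ...) {
  ne <- nrow(rank1_edges(x))
  cat(sprintf("<bnx_network> %d/%d variables, %d optimal-set edges\n",
              length(x$sets), length(x$variables), ne))
  cat("  ", x$fingerprint, "\n")
  invisible(x)
}

# Edges of the rank-1 (optimal) parent sets: data.frame(parent, child).
rank1_edges <- function(network) {
  out <- list()
  for (child in names(network$sets)) {
    p <- network$sets[[child]]$parents[1L]
    if (nzchar(p))
      out[[child]] <- data.frame(parent = strsplit(p, ",", fixed = TRUE)[[1L]],
                                 child = child, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(parent = character(0), child = character(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Kahn's algorithm over the rank-1 edges; static results must be acyclic.
assert_acyclic <- function(network) {
  e <- rank1_edges(network)
  vars <- network$variables
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(e$child)
  indeg[names(tab)] <- as.integer(tab)
  adj <- split(e$child, e$parent)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen != length(vars))
    stop("internal error: learned static network contains a cycle",
         call. = FALSE)
  invisible(TRUE)
}

#' Learn an optimal Bayesian network
#'
#' Discretizes the dataset once, then finds the exact optimal (and, with
#' `k_subopt > 0`, suboptimal) parent sets of every variable independently.
#' In static mode the per-layer candidate pools guarantee the rank-1
#' network is a DAG, which is re-verified before returning.  The result is
#' independent of the order in which children are processed and of the
#' scheduler used.
#'
#' @inheritParams find_optimal_parents
#' @param dataset a [bnx_dataset()].
#' @param discretization policy for [discretize()].
#' @param mode `"auto"` (take the dataset's mode), `"static"` or `"dynamic"`.
#' @param self_loops allow self-regulation in dynamic mode.
#' @param scheduler `"serial"`, `"variable"`, `"set"` or `"hybrid"`; all
#'   produce identical networks (see [run_scheduler()]).
#' @param workers worker processes for the parallel schedulers.
#' @param subset optionally learn only these children (see [split_run()]).
#' @return an object of class `bnx_network`.
#' @export
learn_network <- function(dataset, score = "mdl", limit = 2L, k_subopt = 0L,
                          discretization = "mean", ess = 1,
                          mit_alpha = 0.999, mode = "auto",
                          self_loops = FALSE,
                          scheduler = c("serial", "variable", "set", "hybrid"),
                          workers = 1L, subset = NULL, use_stop = TRUE) {
  scheduler <- match.arg(scheduler)
  stopifnot(inherits(dataset, "bnx_dataset"))
  mode <- match.arg(mode, c("auto", "static", "dynamic"))
  if (mode == "static" && length(dataset$regulator_layers) == 0L)
    stop("static mode requested but the dataset defines no regulators",
         call. = FALSE)
  if (mode == "dynamic" && dataset$mode == "static") {
    dataset$regulator_layers <- list()
    dataset$mode <- "dynamic"
  }
  dataset$self_loops <- isTRUE(self_loops)
  children <- if (is.null(subset)) dataset$variables else {
    bad <- setdiff(subset, dataset$variables)
    if (length(bad))
      stop("unknown variable in subset: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (length(subset) == 0L) stop("empty variable subset", call. = FALSE)
    dataset$variables[dataset$variables %in% subset]
  }
  ddata <- discretize(dataset, discretization)
  scorer <- make_scorer(ddata, score, priors = prior_matrix(dataset),
                        ess = ess, alpha = mit_alpha)
  assoc <- association_matrix(dataset)
  limit <- as.integer(limit); k_subopt <- as.integer(k_subopt)
  workers <- max(1L, as.integer(workers))

  child_task <- function(child, evaluator) {
    ci <- match(child, dataset$variables)
    pool <- match(candidate_parent_pool(child, dataset), dataset$variables)
    find_parents_core(ci, pool, scorer, limit, k_subopt, evaluator,
                      assoc, dataset$variables, use_stop = use_stop)
  }

  sets <- dispatch_scheduler(children, child_task, scorer, scheduler, workers)
  sched_info <- attr(sets, "scheduler")
  attr(sets, "scheduler") <- NULL
  names(sets) <- children
  net <- new_bnx_network(dataset$variables, dataset$mode,
                         config_fingerprint(score, limit, k_subopt,
                                            discretization, ess, mit_alpha,
                                            dataset$mode, self_loops),
                         sets)
  if (dataset$mode == "static" && is.null(subset)) assert_acyclic(net)
  attr(net, "scheduler") <- sched_info
  net
}
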