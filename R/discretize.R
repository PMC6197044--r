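# Discretization ---------------------------------------------------------

parse_policy <- function(policy) {
  if (startsWith(policy, "quantile")) {
    k <- sub("^quantile:?", "", policy)
    k <- if (nzchar(k)) as.integer(k) else 3L
    if (is.na(k) || k < 2L) stop("quantile policy needs k >= 2", call. = FALSE)
    list(name = "quantile", k = k)
  } else if (policy %in% c("mean", "median", "none")) {
    list(name = policy, k = 2L)
  } else stop("unknown discretization policy: ", policy, call. = FALSE)
}

#' Discretize an expression dataset
#'
#' Turns continuous values into the discrete evidence the scorers consume.
#' Policies:
#' \describe{
#'   \item{`"mean"` (default)}{per-variable binarization: values strictly
#'     above that variable's mean become state 1, everything else state 0.}
#'   \item{`"median"`}{same rule with the median as threshold; ties at the
#'     threshold go to state 0.}
#'   \item{`"quantile:k"`}{k states cut at the empirical k-quantiles.}
#'   \item{`"none"`}{values are already non-negative integer states.}
#' }
#' In dynamic mode the evidence consists of lagged (predecessor, successor)
#' column pairs that never span a series break; in static mode each child's
#' evidence excludes the conditions in which that child was perturbed (in
#' dynamic mode the pair is dropped when the *successor* observation of the
#' child was perturbed).  Perturbed variables still provide evidence as
#' parents: an intervention breaks incoming, not outgoing, influence.
#'
#' @param dataset a [bnx_dataset()].
#' @param policy policy string, see above.
#' @return an object of class `bnx_discrete`.
#' @export
discretize <- function(dataset, policy = "mean") {
  pol <- parse_policy(policy)
  n <- length(dataset$variables)
  nc <- length(dataset$conditions)
  states <- matrix(0L, n, nc, dimnames = dimnames(dataset$values))
  nstates <- integer(n)
  for (i in seq_len(n)) {
    v <- dataset$values[i, ]
    if (pol$name %in% c("mean", "median")) {
      thr <- if (pol$name == "mean") mean(v) else stats::median(v)
      states[i, ] <- as.integer(v > thr)
      nstates[i] <- 2L
    } else if (pol$name == "quantile") {
      if (length(unique(v)) < 2L)
        stop(sprintf("variable '%s' is single-state under the quantile policy",
                     dataset$variables[i]), call. = FALSE)
      br <- unique(stats::quantile(v, probs = seq_len(pol$k - 1L) / pol$k,
                                   names = FALSE))
      s <- findInterval(v, br, left.open = TRUE)
      if (length(unique(s)) < 2L)
        stop(sprintf("variable '%s' is single-state under the quantile policy",
                     dataset$variables[i]), call. = FALSE)
      states[i, ] <- as.integer(match(s, sort(unique(s))) - 1L)
      nstates[i] <- length(unique(s))
    } else {  # none
      if (any(v < 0) || any(v != round(v)))
        stop(sprintf("variable '%s' is not pre-discretized (need integers >= 0)",
                     dataset$variables[i]), call. = FALSE)
      states[i, ] <- as.integer(v)
      nstates[i] <- max(2L, max(states[i, ]) + 1L)
    }
  }
  pairs <- NULL
  obs <- vector("list", n)
  names(obs) <- dataset$variables
  if (dataset$mode == "dynamic") {
    pairs <- series_pairs(dataset)
    for (i in seq_len(n)) {
      pert <- dataset$perturbations[[dataset$variables[i]]]
      keep <- if (is.null(pert)) seq_along(pairs$succ) else
        which(!(dataset$conditions[pairs$succ] %in% pert))
      obs[[i]] <- keep
    }
  } else {
    for (i in seq_len(n)) {
      pert <- dataset$perturbations[[dataset$variables[i]]]
      obs[[i]] <- if (is.null(pert)) seq_len(nc) else
        which(!(dataset$conditions %in% pert))
    }
  }
  structure(list(variables = dataset$variables, nstates = nstates,
                 states = states, mode = dataset$mode, pairs = pairs,
                 obs = obs, policy = policy),
            class = "bnx_discrete")
}

#' @export
print.bnx_discrete <- function(x, ...) {
  cat(sprintf("<bnx_discrete> %d variables, %s mode, policy '%s', %d effective observations (max)\n",
              length(x$variables), x$mode, x$policy,
              max(lengths(x$obs)))); invisible(x)
}

# Per-child evidence: child states y, parent-state matrix rows aligned with
# all variables, and the effective observation count N.
child_evidence <- function(ddata, child_idx) {
  keep <- ddata$obs[[child_idx]]
  if (ddata$mode == "dynamic") {
    y <- ddata$states[child_idx, ddata$pairs$succ[keep]]
    E <- ddata$states[, ddata$pairs$pred[keep], drop = FALSE]
  } else {
    y <- ddata$states[child_idx, keep]
    E <- ddata$states[, keep, drop = FALSE]
  }
  list(y = y, E = E, N = length(y))
}
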