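# Parallel schedulers -----------------------------------------------------
#
# Three strategies over the same exact search; all are required to return a
# network byte-identical to the serial run after serialization:
#   variable  one child per worker, children queued when workers run out
#   set       children processed one at a time; within each cardinality
#             layer the candidate subsets are chunked across all workers
#             and merged deterministically before the stop-rule check
#   hybrid    workers are partitioned uniformly across children
#             (allocate_cores) and each child runs set-wise in its share
# The contract is worker-count accounting, not OS pinning: wall-clock
# behaviour is outside the correctness contract.

#' Uniform core allocation for the hybrid scheduler
#'
#' Distributes `k` workers over the variables as evenly as possible: each
#' variable receives `floor(k/n)` workers and the first `k mod n` variables
#' (in dataset order) one extra.  With fewer workers than variables the
#' first `k` variables get one worker each and the rest wait for a freed
#' worker; freed workers are never re-allocated across variables.
#'
#' @param k total worker count (>= 1).
#' @param variables character vector of variable names.
#' @return object of class `bnx_allocation` with a named `per_variable`
#'   vector of worker counts.
#' @export
#' @examples
#' allocate_cores(7, c("A", "B", "C"))$per_variable  # 3 2 2
allocate_cores <- function(k, variables) {
  k <- as.integer(k)
  n <- length(variables)
  if (is.na(k) || k < 1L) stop("worker count must be at least 1", call. = FALSE)
  if (n < 1L) stop("no variables to allocate workers to", call. = FALSE)
  if (k < n) {
    counts <- c(rep(1L, k), rep(0L, n - k))
  } else {
    counts <- rep(k %/% n, n)
    extra <- k %% n
    if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  }
  structure(list(k = k, n = n,
                 per_variable = stats::setNames(counts, variables)),
            class = "bnx_allocation")
}

#' @export
print.bnx_allocation <- function(x, ...) {
  cat(sprintf("<bnx_allocation> %d workers over %d variables: %s\n",
              x$k, x$n, paste(x$per_variable, collapse = " ")))
  invisible(x)
}

apply_parallel <- function(xs, fn, cores) {
  if (cores <= 1L || length(xs) <= 1L || .Platform$OS.type == "windows")
    return(lapply(xs, fn))
  parallel::mclapply(xs, fn, mc.cores = cores, mc.preschedule = TRUE)
}

# Set-wise evaluator: chunk the subsets of one cardinality layer across
# `workers` processes, chunk size ceil(layer / workers); concatenating the
# chunk results in order reproduces the serial evaluation exactly.
parallel_evaluator <- function(scorer, workers) {
  force(scorer); force(workers)
  function(child, subsets) {
    n <- length(subsets)
    if (workers <= 1L || n <= 1L) {
      return(t(vapply(subsets, function(s) scorer$score_set(child, s),
                      numeric(2))))
    }
    csize <- ceiling(n / workers)
    idx <- split(seq_len(n), ceiling(seq_len(n) / csize))
    res <- apply_parallel(idx, function(ii) {
      tryCatch(
        t(vapply(subsets[ii], function(s) scorer$score_set(child, s),
                 numeric(2))),
        error = function(e) structure(list(msg = conditionMessage(e)),
                                      class = "bnx_worker_error"))
    }, workers)
    bad <- vapply(res, inherits, TRUE, "bnx_worker_error")
    if (any(bad))
      stop("parallel worker failed: ", res[[which(bad)[1L]]]$msg,
           call. = FALSE)
    do.call(rbind, res)
  }
}

dispatch_scheduler <- function(children, child_task, scorer, scheduler,
                               workers) {
  n <- length(children)
  info <- list(mode = scheduler, workers = workers)
  if (scheduler == "serial" || workers <= 1L) {
    sets <- lapply(children, child_task, evaluator = serial_evaluator(scorer))
    info$concurrent <- 1L
  } else if (scheduler == "variable") {
    res <- apply_parallel(children, function(ch)
      tryCatch(child_task(ch, serial_evaluator(scorer)),
               error = function(e) structure(list(msg = conditionMessage(e)),
                                             class = "bnx_worker_error")),
      min(workers, n))
    bad <- vapply(res, inherits, TRUE, "bnx_worker_error")
    if (any(bad))
      stop("scheduler worker failed; unfinished variables: ",
           paste(children[bad], collapse = ", "), call. = FALSE)
    sets <- res
    info$concurrent <- min(workers, n)
    info$per_variable <- stats::setNames(rep(1L, n), children)
  } else if (scheduler == "set") {
    sets <- lapply(children, child_task,
                   evaluator = parallel_evaluator(scorer, workers))
    info$concurrent <- workers
    info$per_variable <- stats::setNames(rep(workers, n), children)
  } else {  # hybrid
    alloc <- allocate_cores(workers, children)
    if (workers < n) {
      res <- apply_parallel(children, function(ch)
        tryCatch(child_task(ch, serial_evaluator(scorer)),
                 error = function(e) structure(list(msg = conditionMessage(e)),
                                               class = "bnx_worker_error")),
        workers)
      bad <- vapply(res, inherits, TRUE, "bnx_worker_error")
      if (any(bad))
        stop("scheduler worker failed; unfinished variables: ",
             paste(children[bad], collapse = ", "), call. = FALSE)
      sets <- res
    } else {
      sets <- lapply(seq_along(children), function(i)
        child_task(children[i],
                   parallel_evaluator(scorer, alloc$per_variable[i])))
    }
    info$concurrent <- min(workers, n)
    info$per_variable <- alloc$per_variable
  }
  attr(sets, "scheduler") <- info
  sets
}

#' Run the learner under an explicit scheduling strategy
#'
#' Thin wrapper over [learn_network()] that makes the scheduling contract
#' explicit: whatever `scheduler` and `workers` are chosen, the returned
#' network is byte-identical to the serial run once serialized.
#'
#' @inheritParams learn_network
#' @param scheduler `"variable"`, `"set"` or `"hybrid"`.
#' @param workers number of worker processes (>= 1).
#' @param ... further arguments passed to [learn_network()].
#' @return a `bnx_network`.
#' @export
run_scheduler <- function(dataset, scheduler = c("set", "variable", "hybrid"),
                          workers = 1L, ...) {
  scheduler <- match.arg(scheduler)
  learn_network(dataset, scheduler = scheduler, workers = workers, ...)
}

# Distributed split/aggregate ---------------------------------------------

#' Distributed runs: compute a fragment, then aggregate fragments
#'
#' `split_run()` learns parent sets only for `subset` and serializes them,
#' with the full configuration fingerprint, via [write_partial_result()].
#' `aggregate_runs()` reads every partial-result file in a directory,
#' verifies that the fingerprints match the requested configuration, that no
#' variable is missing and that duplicated fragments agree, and reassembles
#' the network — identically to a monolithic run with the same
#' configuration.
#'
#' @inheritParams learn_network
#' @param subset character vector of child variables (or a file with one
#'   name per line).
#' @param path file to write the fragment to.
#' @param ... configuration arguments passed to [learn_network()].
#' @return `split_run()` the fragment network (invisibly); `aggregate_runs()`
#'   the full `bnx_network`.
#' @export
split_run <- function(dataset, subset, path, ...) {
  if (length(subset) == 1L && file.exists(subset) &&
      !subset %in% dataset$variables)
    subset <- as_input_lines(subset)
  if (length(subset) == 0L)
    stop("empty variable subset", call. = FALSE)
  net <- learn_network(dataset, subset = subset, ...)
  write_partial_result(net, path)
  invisible(net)
}

#' @rdname split_run
#' @param dir directory containing partial-result files.
#' @export
aggregate_runs <- function(dir, dataset, score = "mdl", limit = 2L,
                           k_subopt = 0L, discretization = "mean", ess = 1,
                           mit_alpha = 0.999, self_loops = FALSE, ...) {
  files <- sort(list.files(dir, full.names = TRUE))
  if (!length(files))
    stop("no partial-result files in ", dir, call. = FALSE)
  fp <- config_fingerprint(score, limit, k_subopt, discretization, ess,
                           mit_alpha, dataset$mode, self_loops)
  sets <- list()
  for (f in files) {
    frag <- read_partial_result(f, fingerprint = fp)
    for (child in names(frag$sets)) {
      if (!is.null(sets[[child]])) {
        if (!identical(serialize_sets(sets[[child]]),
                       serialize_sets(frag$sets[[child]])))
          stop("conflicting results for variable '", child,
               "' across fragments", call. = FALSE)
      } else sets[[child]] <- frag$sets[[child]]
    }
  }
  missing <- setdiff(dataset$variables, names(sets))
  if (length(missing))
    stop("aggregation is missing variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sets <- sets[dataset$variables]
  net <- new_bnx_network(dataset$variables, dataset$mode, fp, sets)
  if (dataset$mode == "static") assert_acyclic(net)
  net
}
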