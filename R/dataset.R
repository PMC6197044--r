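#' @keywords internal
"_PACKAGE"

# Expression dataset container -------------------------------------------

#' Construct an expression dataset
#'
#' The central input container: a variables x conditions matrix of (typically
#' continuous) expression values plus the side information that constrains
#' structure learning.  A dataset is *static* when at least one regulator
#' layer is present (candidate parents are then drawn from strictly earlier
#' layers, which guarantees acyclicity) and *dynamic* otherwise (parents at
#' one time point predict children at the next; the unrolled graph is acyclic
#' by construction).
#'
#' @param values numeric matrix, variables in rows, conditions in columns.
#'   Row and column names are taken as variable and condition names unless
#'   `variables`/`conditions` are given.
#' @param variables,conditions character vectors of names.
#' @param regulator_layers list of character vectors, top layer first.  A
#'   non-empty list switches the dataset to static mode.
#' @param perturbations named list mapping a variable to the condition names
#'   in which it was externally perturbed.  A perturbed measurement reflects
#'   the intervention rather than regulation, so those conditions are dropped
#'   from that variable's evidence when it is scored as a child (it still
#'   serves as a parent everywhere).
#' @param edge_priors `NULL` or a data frame with columns `parent`, `child`,
#'   `prob` giving prior edge probabilities in (0, 1]; absent pairs default
#'   to the neutral 0.5.
#' @param series_breaks integer vector of 0-based condition indices at which
#'   a new time-series replicate starts; must begin with 0.  Only meaningful
#'   in dynamic mode, where lagged observation pairs never span a break.
#' @param self_loops logical; allow a variable to be its own parent
#'   (dynamic mode only).
#'
#' @return an object of class `bnx_dataset`.
#' @export
bnx_dataset <- function(values, variables = rownames(values),
                        conditions = colnames(values),
                        regulator_layers = list(),
                        perturbations = list(),
                        edge_priors = NULL,
                        series_breaks = 0L,
                        self_loops = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(variables))
    variables <- paste0("V", seq_len(nrow(values)))
  if (is.null(conditions))
    conditions <- paste0("C", seq_len(ncol(values)))
  dimnames(values) <- list(variables, conditions)
  x <- structure(list(
    variables = as.character(variables),
    conditions = as.character(conditions),
    values = values,
    mode = if (length(regulator_layers) > 0L) "static" else "dynamic",
    regulator_layers = regulator_layers,
    perturbations = perturbations,
    edge_priors = edge_priors,
    series_breaks = as.integer(series_breaks),
    self_loops = isTRUE(self_loops)
  ), class = "bnx_dataset")
  validate_bnx_dataset(x)
  x
}

validate_bnx_dataset <- function(x) {
  v <- x$variables
  if (nrow(x$values) != length(v))
    stop("row count does not match variable count", call. = FALSE)
  if (ncol(x$values) != length(x$conditions))
    stop("column count does not match condition count", call. = FALSE)
  if (anyDuplicated(v))
    stop("duplicate variable name: ",
         paste(unique(v[duplicated(v)]), collapse = ", "), call. = FALSE)
  if (anyNA(x$values))
    stop("non-numeric or missing expression value", call. = FALSE)
  layer_vars <- unlist(x$regulator_layers, use.names = FALSE)
  bad <- setdiff(layer_vars, v)
  if (length(bad))
    stop("regulator not among variables: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(layer_vars))
    stop("variable assigned to more than one regulator layer: ",
         paste(unique(layer_vars[duplicated(layer_vars)]), collapse = ", "),
         call. = FALSE)
  for (nm in names(x$perturbations)) {
    if (!nm %in% v)
      stop("perturbed variable not in dataset: ", nm, call. = FALSE)
    bad <- setdiff(x$perturbations[[nm]], x$conditions)
    if (length(bad))
      stop("perturbation names unknown condition: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(x$edge_priors)) {
    ep <- x$edge_priors
    stopifnot(is.data.frame(ep),
              all(c("parent", "child", "prob") %in% names(ep)))
    bad <- setdiff(c(ep$parent, ep$child), v)
    if (length(bad))
      stop("edge prior names unknown variable: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(ep$prob <= 0 | ep$prob > 1))
      stop("edge prior probabilities must lie in (0, 1]", call. = FALSE)
  }
  sb <- x$series_breaks
  if (length(sb) == 0L || sb[1L] != 0L || is.unsorted(sb, strictly = TRUE))
    stop("series breaks must be strictly increasing and start at 0",
         call. = FALSE)
  if (any(sb >= length(x$conditions)))
    stop("series break beyond last condition", call. = FALSE)
  invisible(x)
}

#' @export
print.bnx_dataset <- function(x, ...) {
  cat(sprintf("<bnx_dataset> %d variables x %d conditions, %s mode\n",
              length(x$variables), length(x$conditions), x$mode))
  if (x$mode == "static")
    cat(sprintf("  regulator layers: %s\n",
                paste(vapply(x$regulator_layers, paste, "", collapse = ","),
                      collapse = " | ")))
  if (length(x$series_breaks) > 1L)
    cat(sprintf("  %d time-series replicates\n", length(x$series_breaks)))
  if (length(x$perturbations))
    cat(sprintf("  perturbations for: %s\n",
                paste(names(x$perturbations), collapse = ", ")))
  invisible(x)
}

# Prior lookup matrix (parent x child), neutral 0.5 where unspecified.
prior_matrix <- function(dataset) {
  n <- length(dataset$variables)
  pm <- matrix(0.5, n, n, dimnames = list(dataset$variables, dataset$variables))
  ep <- dataset$edge_priors
  if (!is.null(ep))
    pm[cbind(match(ep$parent, dataset$variables),
             match(ep$child, dataset$variables))] <- ep$prob
  pm
}

# Lagged observation pairs for dynamic mode: predecessor/successor column
# indices within each replicate segment.
series_pairs <- function(dataset) {
  nc <- length(dataset$conditions)
  starts <- dataset$series_breaks + 1L
  ends <- c(dataset$series_breaks[-1L], nc)
  pred <- integer(0); succ <- integer(0)
  for (s in seq_along(starts)) {
    if (ends[s] > starts[s]) {
      pred <- c(pred, starts[s]:(ends[s] - 1L))
      succ <- c(succ, (starts[s] + 1L):ends[s])
    }
  }
  list(pred = pred, succ = succ)
}

# Pairwise association strengths on the raw scale (|Pearson r|), lagged in
# dynamic mode; used only to order equal-scoring parent sets deterministically.
association_matrix <- function(dataset) {
  if (dataset$mode == "dynamic") {
    pr <- series_pairs(dataset)
    a <- suppressWarnings(stats::cor(t(dataset$values[, pr$pred, drop = FALSE]),
                                     t(dataset$values[, pr$succ, drop = FALSE])))
  } else {
    a <- suppressWarnings(stats::cor(t(dataset$values)))
  }
  a[!is.finite(a)] <- 0
  abs(a)
}

#' Sign of a putative interaction
#'
#' Sign of the Pearson correlation between parent and child on the raw
#' (continuous) values; in dynamic mode the parent is lagged one step behind
#' the child.  Zero or undefined correlation is reported as `"+"`.
#'
#' @param parent,child variable names.
#' @param dataset a [bnx_dataset()].
#' @return `"+"` or `"-"`.
#' @export
edge_sign <- function(parent, child, dataset) {
  stopifnot(parent %in% dataset$variables, child %in% dataset$variables)
  if (dataset$mode == "dynamic") {
    pr <- series_pairs(dataset)
    r <- suppressWarnings(stats::cor(dataset$values[parent, pr$pred],
                                     dataset$values[child, pr$succ]))
  } else {
    r <- suppressWarnings(stats::cor(dataset$values[parent, ],
                                     dataset$values[child, ]))
  }
  if (!is.finite(r) || r >= 0) "+" else "-"
}
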