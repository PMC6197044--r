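# Expression-table text dialect ------------------------------------------
#
# Preamble lines start with '#':
#   #regulators g1 g2 ...     one regulator layer per occurrence, top first;
#                             at least one occurrence => static mode
#   #perturbed var cond ...   conditions where var was externally perturbed
#   #prioredge child p g1 ..  prior probability p in (0,1] for each g -> child
#   #series cond ...          condition names at which a new time-series
#                             replicate begins (first replicate is implicit)
# The first non-preamble line is the conditions header (its leading token is
# an arbitrary label); every remaining line is one variable row.  Fields are
# separated by any run of spaces or tabs.

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1L]]

as_input_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  else if (length(x) == 1L)
    x <- strsplit(x, "\n", fixed = TRUE)[[1L]]
  x[nzchar(trimws(x))]
}

#' Parse an expression table
#'
#' Reads the learning-data text format: an optional preamble (`#regulators`,
#' `#perturbed`, `#prioredge`, `#series` directives), a conditions header
#' line, and one row of numeric values per variable.  One or more
#' `#regulators` lines make the dataset static (each line contributes one
#' regulator layer, top layer first); without them the dataset is dynamic and
#' column order is taken as temporal order.
#'
#' @param x a file path or the table text itself (single string or character
#'   vector of lines).
#' @return a [bnx_dataset()].
#' @export
#' @examples
#' txt <- c("#regulators G1",
#'          "conditions E1 E2 E3 E4",
#'          "G1 0.1 2.0 0.2 1.9",
#'          "G2 0.3 2.2 0.1 2.4")
#' parse_expression_file(txt)
parse_expression_file <- function(x) {
  lines <- as_input_lines(x)
  if (length(lines) < 2L)
    stop("expression table needs a header and at least one data row",
         call. = FALSE)
  layers <- list(); pert <- list(); priors <- NULL; series_names <- character(0)
  i <- 1L
  while (i <= length(lines) && startsWith(lines[[i]], "#")) {
    f <- split_fields(lines[[i]])
    switch(f[1L],
      "#regulators" = {
        if (length(f) < 2L) stop("#regulators line names no variables",
                                 call. = FALSE)
        layers[[length(layers) + 1L]] <- f[-1L]
      },
      "#perturbed" = {
        if (length(f) < 3L)
          stop("#perturbed needs a variable and at least one condition",
               call. = FALSE)
        pert[[f[2L]]] <- unique(c(pert[[f[2L]]], f[-(1:2)]))
      },
      "#prioredge" = {
        if (length(f) < 4L)
          stop("#prioredge needs a child, a probability and parents",
               call. = FALSE)
        p <- suppressWarnings(as.numeric(f[3L]))
        if (!is.finite(p)) stop("#prioredge probability is not numeric",
                                call. = FALSE)
        priors <- rbind(priors, data.frame(parent = f[-(1:3)], child = f[2L],
                                           prob = p))
      },
      "#series" = {
        series_names <- c(series_names, f[-1L])
      },
      stop("unknown preamble directive: ", f[1L], call. = FALSE)
    )
    i <- i + 1L
  }
  if (i + 1L > length(lines))
    stop("no data rows after the conditions header", call. = FALSE)
  header <- split_fields(lines[[i]])
  conditions <- header[-1L]
  rows <- lines[(i + 1L):length(lines)]
  vars <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), length(conditions))
  for (r in seq_along(rows)) {
    f <- split_fields(rows[[r]])
    vars[r] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (length(v) != length(conditions) || anyNA(v))
      stop(sprintf("row '%s' does not have %d numeric values",
                   f[1L], length(conditions)), call. = FALSE)
    vals[r, ] <- v
  }
  if (anyDuplicated(vars))
    stop("duplicate variable name: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "), call. = FALSE)
  breaks <- 0L
  if (length(series_names)) {
    idx <- match(series_names, conditions)
    if (anyNA(idx))
      stop("#series names unknown condition: ",
           paste(series_names[is.na(idx)], collapse = ", "), call. = FALSE)
    breaks <- sort(unique(c(0L, idx - 1L)))
  }
  bnx_dataset(vals, variables = vars, conditions = conditions,
              regulator_layers = layers, perturbations = pert,
              edge_priors = priors, series_breaks = breaks)
}

#' Render a dataset back to the expression-table text format
#'
#' Inverse of [parse_expression_file()]; values are written at full
#' precision so that a parse/write round trip is exact.
#'
#' @param dataset a [bnx_dataset()].
#' @param path optional file to write to.
#' @return the lines, invisibly when `path` is given.
#' @export
format_expression_file <- function(dataset, path = NULL) {
  out <- character(0)
  for (layer in dataset$regulator_layers)
    out <- c(out, paste("#regulators", paste(layer, collapse = " ")))
  for (nm in names(dataset$perturbations))
    out <- c(out, paste("#perturbed", nm,
                        paste(dataset$perturbations[[nm]], collapse = " ")))
  ep <- dataset$edge_priors
  if (!is.null(ep))
    for (r in seq_len(nrow(ep)))
      out <- c(out, sprintf("#prioredge %s %.17g %s",
                            ep$child[r], ep$prob[r], ep$parent[r]))
  if (length(dataset$series_breaks) > 1L)
    out <- c(out, paste("#series",
                        paste(dataset$conditions[dataset$series_breaks[-1L] + 1L],
                              collapse = " ")))
  out <- c(out, paste("conditions", paste(dataset$conditions, collapse = "\t")))
  for (r in seq_along(dataset$variables))
    out <- c(out, paste(dataset$variables[r],
                        paste(sprintf("%.17g", dataset$values[r, ]),
                              collapse = "\t")))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# Gold standards ----------------------------------------------------------

#' Construct / read a gold-standard network
#'
#' `bnx_gold()` wraps a reference adjacency matrix (parent rows, child
#' columns, confidences in \[0, 1\], 1 = true edge).  `read_gold_standard()`
#' reads either a 3-column edge list (`parent child weight`) or a labeled
#' square matrix; with `directed = FALSE` the adjacency is symmetrized by
#' taking the elementwise maximum.
#'
#' @param adjacency square numeric matrix.
#' @param variables variable names.
#' @param directed logical flag.
#' @return an object of class `bnx_gold`.
#' @export
bnx_gold <- function(adjacency, variables = rownames(adjacency),
                     directed = TRUE) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("gold-standard adjacency must be square", call. = FALSE)
  if (any(adjacency < 0 | adjacency > 1))
    stop("gold-standard weights must lie in [0, 1]", call. = FALSE)
  if (is.null(variables))
    variables <- paste0("V", seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(variables, variables)
  if (!directed)
    adjacency <- pmax(adjacency, t(adjacency))
  structure(list(variables = as.character(variables), adjacency = adjacency,
                 directed = isTRUE(directed)),
            class = "bnx_gold")
}

#' @rdname bnx_gold
#' @param x file path or text of the gold standard.
#' @param variables for the edge-list form, the full variable set (defaults
#'   to the names seen in the list).
#' @export
read_gold_standard <- function(x, directed = TRUE, variables = NULL) {
  lines <- as_input_lines(x)
  fields <- lapply(lines, split_fields)
  third_num <- length(fields[[1L]]) == 3L &&
    !is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))
  if (all(lengths(fields) == 3L) && third_num) {
    parent <- vapply(fields, `[`, "", 1L)
    child <- vapply(fields, `[`, "", 2L)
    w <- as.numeric(vapply(fields, `[`, "", 3L))
    if (anyNA(w) || any(w < 0 | w > 1))
      stop("gold-standard weights must lie in [0, 1]", call. = FALSE)
    if (is.null(variables)) variables <- unique(c(parent, child))
    bad <- setdiff(c(parent, child), variables)
    if (length(bad))
      stop("gold-standard names unknown variable: ",
           paste(bad, collapse = ", "), call. = FALSE)
    adj <- matrix(0, length(variables), length(variables),
                  dimnames = list(variables, variables))
    adj[cbind(match(parent, variables), match(child, variables))] <- w
    bnx_gold(adj, variables, directed = directed)
  } else {
    vars <- fields[[1L]]
    body <- fields[-1L]
    if (length(body) != length(vars) ||
        any(lengths(body) != length(vars) + 1L))
      stop("labeled gold-standard matrix is not square", call. = FALSE)
    adj <- t(vapply(body, function(f) as.numeric(f[-1L]),
                    numeric(length(vars))))
    if (anyNA(adj) || any(adj < 0 | adj > 1))
      stop("gold-standard weights must lie in [0, 1]", call. = FALSE)
    dimnames(adj) <- list(vapply(body, `[`, "", 1L), vars)
    adj <- adj[vars, , drop = FALSE]
    bnx_gold(adj, vars, directed = directed)
  }
}

#' @export
print.bnx_gold <- function(x, ...) {
  cat(sprintf("<bnx_gold> %d variables, %d positive edges, %s\n",
              length(x$variables), sum(x$adjacency >= 0.5),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}
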