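# Network serialization ---------------------------------------------------
#
# Self-describing text form used both for full networks and for distributed
# partial results.  Scores are printed with 17 significant digits, which
# round-trips IEEE doubles exactly, so write/read preserves every score
# bit-for-bit and serial/parallel/distributed runs can be compared for byte
# identity.

serialize_sets <- function(df) {
  sprintf("%d\t%s\t%.17g\t%.17g\t%.17g", df$rank,
          ifelse(nzchar(df$parents), df$parents, "-"),
          df$g, df$d, df$total)
}

#' Serialize a network to text lines
#'
#' @param network a `bnx_network`.
#' @return character vector of lines.
#' @export
serialize_network <- function(network) {
  out <- c("#bnexact-network 1",
           paste0("#fingerprint ", network$fingerprint),
           paste0("#mode ", network$mode),
           paste0("#variables ", paste(network$variables, collapse = " ")),
           paste0("#children ", paste(names(network$sets), collapse = " ")))
  for (child in names(network$sets))
    out <- c(out, paste0(child, "\t", serialize_sets(network$sets[[child]])))
  out
}

#' Write / read a (partial) result file
#'
#' A partial result holds the ranked parent sets of a subset of variables
#' plus the configuration fingerprint (score type, limit, number of
#' suboptimal sets, discretization policy, ...).  Reading verifies the
#' fingerprint when one is expected, so fragments computed under different
#' configurations can never be aggregated together.  The round trip is
#' lossless: scores are restored bit-for-bit and set order is preserved.
#'
#' @param network a `bnx_network` (possibly covering a variable subset).
#' @param path file path.
#' @param fingerprint expected configuration fingerprint, or `NULL` to skip
#'   the check.
#' @return `read_partial_result()` returns the `bnx_network` fragment.
#' @export
write_partial_result <- function(network, path) {
  writeLines(serialize_network(network), path)
  invisible(path)
}

#' @rdname write_partial_result
#' @export
read_partial_result <- function(path, fingerprint = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1L] != "#bnexact-network 1")
    stop("not a bnexact network file: ", path, call. = FALSE)
  hdr <- function(tag) {
    l <- lines[startsWith(lines, paste0("#", tag, " "))][1L]
    sub(paste0("^#", tag, " "), "", l)
  }
  fp <- hdr("fingerprint")
  if (!is.null(fingerprint) && !identical(fp, fingerprint))
    stop("configuration fingerprint mismatch in ", path,
         "\n  expected: ", fingerprint, "\n  found:    ", fp, call. = FALSE)
  variables <- split_fields(hdr("variables"))
  children <- split_fields(hdr("children"))
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  df <- data.frame(child = vapply(f, `[`, "", 1L),
                   rank = as.integer(vapply(f, `[`, "", 2L)),
                   parents = vapply(f, `[`, "", 3L),
                   g = as.numeric(vapply(f, `[`, "", 4L)),
                   d = as.numeric(vapply(f, `[`, "", 5L)),
                   total = as.numeric(vapply(f, `[`, "", 6L)),
                   stringsAsFactors = FALSE)
  df$parents[df$parents == "-"] <- ""
  sets <- lapply(children, function(ch) {
    s <- df[df$child == ch, c("rank", "parents", "g", "d", "total")]
    row.names(s) <- NULL
    s
  })
  names(sets) <- children
  new_bnx_network(variables, hdr("mode"), fp, sets)
}

# SIF and scored edge lists ----------------------------------------------

#' Write a network in SIF (simple interaction format)
#'
#' One line per optimal-set edge, `"<parent> <sign> <child>"`, with the sign
#' taken from [edge_sign()] (Pearson correlation on the raw values).  Lines
#' are ordered by child then parent in dataset order, so serial and parallel
#' runs emit byte-identical files.
#'
#' @param network a `bnx_network`.
#' @param dataset the dataset the network was learned from.
#' @param path optional output file.
#' @return the SIF lines (invisibly when `path` is given).
#' @export
write_sif <- function(network, dataset, path = NULL) {
  stopifnot(all(names(network$sets) %in% dataset$variables))
  out <- character(0)
  ord <- function(v) v[order(match(v, dataset$variables))]
  for (child in ord(names(network$sets))) {
    p <- network$sets[[child]]$parents[1L]
    if (!nzchar(p)) next
    for (parent in ord(strsplit(p, ",", fixed = TRUE)[[1L]]))
      out <- c(out, paste(parent, edge_sign(parent, child, dataset), child))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Write a scored edge list
#'
#' TSV with one row per (child, parent) pair occurring in any kept parent
#' set: the interaction sign, the edge confidence (see
#' [confidence_matrix()]) and the best rank of a parent set containing the
#' parent.
#'
#' @inheritParams write_sif
#' @return a data frame (written to `path` as TSV when given).
#' @export
write_edge_list <- function(network, dataset, path = NULL) {
  conf <- confidence_matrix(network)
  rows <- list()
  ord <- function(v) v[order(match(v, dataset$variables))]
  for (child in ord(names(network$sets))) {
    df <- network$sets[[child]]
    best_rank <- list()
    for (r in seq_len(nrow(df))) {
      if (!nzchar(df$parents[r])) next
      for (parent in strsplit(df$parents[r], ",", fixed = TRUE)[[1L]])
        if (is.null(best_rank[[parent]])) best_rank[[parent]] <- df$rank[r]
    }
    for (parent in ord(names(best_rank)))
      rows[[length(rows) + 1L]] <- data.frame(
        child = child, parent = parent,
        sign = edge_sign(parent, child, dataset),
        confidence = conf$values[parent, child],
        rank = best_rank[[parent]], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(child = character(0), parent = character(0),
               sign = character(0), confidence = numeric(0),
               rank = integer(0))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
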