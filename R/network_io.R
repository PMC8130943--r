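#' Read a reference interaction network
#'
#' Reads an edge list into an igraph graph, the prior interaction scaffold
#' used to filter and orient sample-specific co-expression edges. Two
#' formats are accepted: plain 2+-column TSV (source, target, extra columns
#' ignored) and SIF (source, interaction type, target). Lines starting with
#' `#` are ignored. Duplicate edges are collapsed with a warning carrying
#' the count; the node set is the union of edge endpoints.
#'
#' @param path edge-list file.
#' @param directed logical; interpret edges as directed.
#' @param format `"auto"` (by extension: `.sif` = SIF), `"tsv"`, or `"sif"`.
#' @return an `igraph` graph.
#' @export
read_network <- function(path, directed = TRUE,
                         format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no edges in '", path, "'")
  parts <- strsplit(lines, "[\t ]+")
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 2)) {
    bad <- which(ncols < 2)[1]
    stop("parse error in '", path, "' line ", bad,
         ": fewer than 2 columns")
  }
  if (format == "sif") {
    if (any(ncols < 3))
      stop("parse error in '", path, "': SIF needs 3 columns ",
           "(source interaction target)")
    edges <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 3L))
  } else {
    edges <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  }
  key <- if (directed) paste(edges[, 1], edges[, 2], sep = "\r")
         else paste(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2]), sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    warning("collapsed ", ndup, " duplicate edge(s) in '", path, "'")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = directed)
  g
}

#' Write a network as a 2-column tab-delimited edge list
#' @param g an `igraph` graph with named vertices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Sample-specific network
#'
#' One sample's inferred state-transition edge set with per-edge statistic
#' and p-value. Edges are stored as a data frame with columns `source`,
#' `target`, `statistic`, `p_value`.
#'
#' @param sample_id sample identifier.
#' @param edges data.frame with columns `source`, `target`, `statistic`,
#'   `p_value` (`p_value` may be `NA` for score-thresholded methods).
#' @param method construction method tag (`"CSN"`, `"SSN"`, `"pairedSSN"`,
#'   `"SPCC"`, `"LIONESS"`).
#' @param directed logical; whether edges carry reference orientation.
#' @param reference_tag optional name of the reference network applied.
#' @return an object of class `sample_network`.
#' @export
sample_network <- function(sample_id, edges, method, directed = FALSE,
                           reference_tag = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "target", "statistic", "p_value")
  for (col in setdiff(need, names(edges))) edges[[col]] <- NA_real_
  edges <- edges[need]
  pv <- edges$p_value[!is.na(edges$p_value)]
  if (length(pv) && (any(pv < 0) || any(pv > 1)))
    stop("p_value outside [0,1]")
  structure(list(sample_id = sample_id, edges = edges, method = method,
                 directed = directed, reference_tag = reference_tag),
            class = "sample_network")
}

#' @export
print.sample_network <- function(x, ...) {
  cat("Sample-specific network [", x$method, "] sample '", x$sample_id,
      "': ", nrow(x$edges), if (x$directed) " directed" else " undirected",
      " edges\n", sep = "")
  invisible(x)
}

#' Convert a sample-specific network to an igraph graph
#' @param net a `sample_network`.
#' @param nodes optional node universe to include as (possibly isolated)
#'   vertices.
#' @return an `igraph` graph, directed if the network is directed.
#' @export
as_igraph <- function(net, nodes = NULL) {
  el <- as.matrix(net$edges[c("source", "target")])
  vn <- union(nodes, unique(c(el)))
  g <- igraph::graph_from_edgelist(el, directed = net$directed)
  extra <- setdiff(vn, igraph::V(g)$name)
  if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  g
}

#' Write a sample-specific network as edge-list TSV
#' @param net a `sample_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
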