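#' Construct a protein-protein interaction network
#'
#' Undirected simple graph over gene symbols: self-loops and duplicate
#' edges are removed, symbols uppercased.
#'
#' @param edges Two-column character matrix or data.frame of endpoint
#'   symbols (one edge per row); may be empty.
#' @param nodes Optional extra isolated nodes to include.
#'
#' @return An object of class `ppi_network`: list with `graph` (igraph),
#'   `nodes`, `edges` (canonical two-column data.frame) and `n_self_loops`,
#'   the number of self-loops dropped.
#' @export
ppi_network <- function(edges, nodes = character()) {
  if (is.null(dim(edges)))
    edges <- matrix(character(), ncol = 2L)
  edges <- matrix(toupper(trimws(as.matrix(edges))), ncol = 2L)
  nodes <- toupper(trimws(as.character(nodes)))
  self <- edges[, 1L] == edges[, 2L]
  n_self <- sum(self)
  if (n_self) {
    message("dropped ", n_self, " self-loop(s)")
    edges <- edges[!self, , drop = FALSE]
  }
  # canonical orientation so (a,b) and (b,a) deduplicate together
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  all_nodes <- sort(unique(c(as.vector(edges), nodes)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  edge_df <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edge_df) <- c("protein_a", "protein_b")
  rownames(edge_df) <- NULL
  structure(list(graph = g, nodes = all_nodes, edges = edge_df,
                 n_self_loops = n_self),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network: ", length(x$nodes), " proteins, ", nrow(x$edges),
      " interactions\n", sep = "")
  invisible(x)
}

#' Node degrees of a PPI network
#'
#' @param net A [ppi_network()].
#' @return Named integer vector, one entry per node.
#' @export
ppi_degree <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  d <- igraph::degree(net$graph)
  d[order(names(d))]
}

#' Read a PPI edge list from TSV
#'
#' Expected format: `protein_a<TAB>protein_b` with an optional third numeric
#' score column, no header (a header line starting with `protein` is
#' tolerated and skipped).  Self-loops are dropped with a message and
#' duplicate edges collapsed.
#'
#' @param path Path to the edge-list file.
#' @param score_threshold If not `NULL` and a score column is present, keep
#'   only edges with score >= the threshold.
#'
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path, score_threshold = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^protein", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  if (!length(lines))
    return(ppi_network(matrix(character(), ncol = 2L)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed edge at line ", which(nf < 2L)[1L], " of ", path,
         call. = FALSE)
  a <- vapply(parts, `[[`, character(1L), 1L)
  b <- vapply(parts, `[[`, character(1L), 2L)
  if (!is.null(score_threshold)) {
    score <- rep(NA_real_, length(parts))
    has3 <- nf >= 3L
    score[has3] <- suppressWarnings(
      as.numeric(vapply(parts[has3], `[[`, character(1L), 3L)))
    keep <- !is.na(score) & score >= score_threshold
    a <- a[keep]; b <- b[keep]
  }
  ppi_network(cbind(a, b))
}

#' Subnetwork induced by a gene set
#'
#' Restricts the network to the nodes present in `genes`, keeping edges with
#' both endpoints retained — e.g. the PPI subnetwork over the DEGs shared
#' between the focal disease and its risk factors.
#'
#' @param net A [ppi_network()].
#' @param genes Character vector of gene symbols.
#' @return A `ppi_network` over `nodes(net)` intersect `genes`.
#' @export
induced_subnetwork <- function(net, genes) {
  stopifnot(inherits(net, "ppi_network"))
  keep <- intersect(net$nodes, toupper(trimws(genes)))
  e <- net$edges
  e <- e[e[[1L]] %in% keep & e[[2L]] %in% keep, , drop = FALSE]
  ppi_network(as.matrix(e), nodes = keep)
}

#' Rank hub proteins by degree
#'
#' Sorts nodes by degree descending, ties broken lexicographically so the
#' ranking is reproducible, and returns the top `k`.  With
#' `include_ties = TRUE` every node tied with the k-th degree is kept.
#'
#' @param net A [ppi_network()].
#' @param k Number of hubs requested (default 10).
#' @param include_ties Keep all nodes tied at the k-th degree?
#'
#' @return A `hub_report`: data.frame `rank`, `protein`, `degree` with
#'   attribute `k`.
#' @export
top_hubs <- function(net, k = 10L, include_ties = FALSE) {
  stopifnot(inherits(net, "ppi_network"), k >= 1L)
  d <- ppi_degree(net)
  if (!length(d)) {
    warning("empty network: no hubs to report", call. = FALSE)
    out <- data.frame(rank = integer(), protein = character(),
                      degree = integer())
    return(structure(out, k = as.integer(k),
                     class = c("hub_report", "data.frame")))
  }
  ord <- order(-d, names(d))
  d <- d[ord]
  n_keep <- min(k, length(d))
  if (include_ties && length(d) > n_keep)
    n_keep <- max(which(d == d[n_keep]))
  out <- data.frame(rank = seq_len(n_keep),
                    protein = names(d)[seq_len(n_keep)],
                    degree = unname(d[seq_len(n_keep)]))
  structure(out, k = as.integer(k), class = c("hub_report", "data.frame"))
}

#' Write PPI results
#'
#' `write_hub_report()` writes `rank<TAB>protein<TAB>degree`;
#' `write_ppi_graphml()` writes the network as GraphML, optionally carrying
#' a `memberships` node attribute (comma-joined list of the risk factors
#' whose shared-DEG set contains each protein).
#'
#' @param report A `hub_report` from [top_hubs()].
#' @param net A `ppi_network`.
#' @param memberships Optional named list: protein -> character vector of
#'   group labels.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hub_report <- function(report, path) {
  stopifnot(inherits(report, "hub_report"))
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hub_report
#' @export
write_ppi_graphml <- function(net, path, memberships = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  if (!is.null(memberships)) {
    memb <- vapply(igraph::V(g)$name, function(v) {
      m <- memberships[[v]]
      if (is.null(m)) "" else paste(sort(unique(m)), collapse = ",")
    }, character(1L))
    g <- igraph::set_vertex_attr(g, "memberships", value = unname(memb))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
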