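#' Directional DEG sets for one disease
#'
#' Holds the up- and down-regulated gene symbols called for a cohort.
#' Symbols are uppercased so that cohorts annotated with mixed-case symbols
#' match (HGNC symbols are uppercase).
#'
#' @param disease_id Disease label.
#' @param up_genes,down_genes Character vectors of gene symbols.
#'
#' @return An object of class `disease_gene_sets` with elements
#'   `disease_id`, `up` and `down` (disjoint sorted sets).
#' @export
disease_gene_sets <- function(disease_id, up_genes = character(),
                              down_genes = character()) {
  up <- sort(unique(toupper(as.character(up_genes))))
  down <- sort(unique(toupper(as.character(down_genes))))
  both <- intersect(up, down)
  if (length(both))
    stop("gene(s) listed as both up and down: ",
         paste(both, collapse = ", "), call. = FALSE)
  structure(list(disease_id = as.character(disease_id)[1L],
                 up = up, down = down),
            class = "disease_gene_sets")
}

#' @export
print.disease_gene_sets <- function(x, ...) {
  cat("disease_gene_sets '", x$disease_id, "': ", length(x$up), " up / ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

#' Number of dysregulated genes shared by two diseases
#'
#' The size of the intersection of the two gene sets,
#' \eqn{n_{ij} = |G_i \cap G_j|}.
#'
#' @param sets_i,sets_j Character vectors of gene symbols.
#' @return Integer count.
#' @export
shared_gene_count <- function(sets_i, sets_j) {
  length(intersect(unique(sets_i), unique(sets_j)))
}

#' Jaccard edge-prediction score between two gene sets
#'
#' \eqn{E(i, j) = |G_i \cap G_j| / |G_i \cup G_j|}, the similarity score
#' used to weight disease-disease links in the diseasome.
#'
#' @param sets_i,sets_j Character vectors of gene symbols.
#' @return A number in \[0, 1\]; `NA` with a warning when both sets are
#'   empty (the score is undefined).
#' @export
jaccard_score <- function(sets_i, sets_j) {
  u <- length(union(sets_i, sets_j))
  if (u == 0L) {
    warning("Jaccard score undefined for two empty sets", call. = FALSE)
    return(NA_real_)
  }
  length(intersect(unique(sets_i), unique(sets_j))) / u
}

#' Merge several focal-disease cohorts into one gene-set object
#'
#' Per-direction union of the input sets; genes called up in one cohort and
#' down in another are direction-conflicted, removed from both sets and
#' reported in the `conflicted` attribute so the exclusion can be audited.
#'
#' @param sets_list List of [disease_gene_sets()].
#' @param combined_id Label for the merged disease.
#'
#' @return A `disease_gene_sets` with attribute `conflicted` (character
#'   vector of excluded symbols, possibly empty).
#' @export
combine_focal_datasets <- function(sets_list, combined_id) {
  stopifnot(length(sets_list) >= 1L,
            all(vapply(sets_list, inherits, logical(1L), "disease_gene_sets")))
  up <- sort(unique(unlist(lapply(sets_list, `[[`, "up"))))
  down <- sort(unique(unlist(lapply(sets_list, `[[`, "down"))))
  conflicted <- intersect(up, down)
  if (length(conflicted))
    message(length(conflicted), " direction-conflicted gene(s) excluded: ",
            paste(utils::head(conflicted, 10L), collapse = ", "))
  out <- disease_gene_sets(combined_id,
                           up_genes = setdiff(up, conflicted),
                           down_genes = setdiff(down, conflicted))
  attr(out, "conflicted") <- conflicted
  out
}

sets_by_direction <- function(dgs, direction) {
  switch(direction,
         up = dgs$up,
         down = dgs$down,
         combined = union(dgs$up, dgs$down))
}

#' Build the gene-disease bipartite ("diseasome") network
#'
#' Connects the focal disease and each risk factor to the genes they share
#' with the focal disease, one layer per direction (separate up- and
#' down-regulated networks, as diseasome figures are usually drawn), and
#' computes for every unordered disease pair that shares at least one gene
#' the shared count and Jaccard score, per direction and combined.
#'
#' @param focal A [disease_gene_sets()] for the focal disease.
#' @param risk_factors List of `disease_gene_sets` for the risk factors.
#'
#' @return An object of class `diseasome_network`: list with
#'   `diseases` (ids, focal first), `edges` (data.frame `disease`, `gene`,
#'   `direction`), `pair_stats` (data.frame `disease_i`, `disease_j`,
#'   `direction`, `n_shared`, `jaccard`), `gene_sets` (the inputs) and
#'   `graph` (igraph bipartite graph with vertex attribute `type` in
#'   disease/gene and edge attribute `direction`).
#' @export
build_diseasome <- function(focal, risk_factors) {
  stopifnot(inherits(focal, "disease_gene_sets"), length(risk_factors) >= 1L,
            all(vapply(risk_factors, inherits, logical(1L),
                       "disease_gene_sets")))
  if (length(focal$up) + length(focal$down) == 0L)
    stop("focal disease has no DEGs", call. = FALSE)
  all_sets <- c(list(focal), risk_factors)
  ids <- vapply(all_sets, `[[`, character(1L), "disease_id")
  if (anyDuplicated(ids))
    stop("duplicate disease_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  names(all_sets) <- ids

  edges <- list()
  for (dir in c("up", "down")) {
    fg <- sets_by_direction(focal, dir)
    for (rf in risk_factors) {
      shared <- intersect(fg, sets_by_direction(rf, dir))
      if (length(shared)) {
        edges[[length(edges) + 1L]] <-
          data.frame(disease = rf$disease_id, gene = shared, direction = dir)
        edges[[length(edges) + 1L]] <-
          data.frame(disease = focal$disease_id, gene = shared,
                     direction = dir)
      }
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(disease = character(), gene = character(),
               direction = character())
  edges <- edges[order(edges$direction, edges$disease, edges$gene), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  pairs <- utils::combn(ids, 2L)
  stats <- list()
  for (k in seq_len(ncol(pairs))) {
    di <- all_sets[[pairs[1L, k]]]
    dj <- all_sets[[pairs[2L, k]]]
    for (dir in c("up", "down", "combined")) {
      gi <- sets_by_direction(di, dir)
      gj <- sets_by_direction(dj, dir)
      n <- shared_gene_count(gi, gj)
      if (n >= 1L)
        stats[[length(stats) + 1L]] <- data.frame(
          disease_i = di$disease_id, disease_j = dj$disease_id,
          direction = dir, n_shared = n, jaccard = jaccard_score(gi, gj))
    }
  }
  pair_stats <- if (length(stats)) do.call(rbind, stats) else
    data.frame(disease_i = character(), disease_j = character(),
               direction = character(), n_shared = integer(),
               jaccard = numeric())
  rownames(pair_stats) <- NULL

  g <- igraph::make_empty_graph(directed = FALSE)
  gene_nodes <- sort(unique(edges$gene))
  g <- igraph::add_vertices(g, length(ids), name = ids, type = "disease")
  g <- igraph::add_vertices(g, length(gene_nodes), name = gene_nodes,
                            type = "gene")
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$disease, edges$gene),
                           direction = edges$direction)

  structure(list(diseases = ids, edges = edges, pair_stats = pair_stats,
                 gene_sets = all_sets, graph = g),
            class = "diseasome_network")
}

#' @export
print.diseasome_network <- function(x, ...) {
  cat("diseasome_network: ", length(x$diseases), " diseases, ",
      length(unique(x$edges$gene)), " shared genes, ",
      nrow(x$edges), " bipartite edges\n", sep = "")
  invisible(x)
}

#' Genes shared across multiple diseases
#'
#' Lists every (gene, direction) whose bipartite degree — the number of
#' diseases it links — reaches `min_diseases`, the multi-disease membership
#' patterns the diseasome exists to reveal.
#'
#' @param network A [build_diseasome()] result.
#' @param min_diseases Minimum number of linked diseases (default 2).
#'
#' @return data.frame `gene`, `direction`, `n_diseases`, `diseases`
#'   (comma-joined sorted ids), sorted by degree descending then symbol.
#' @export
membership_patterns <- function(network, min_diseases = 2L) {
  stopifnot(inherits(network, "diseasome_network"), min_diseases >= 1L)
  e <- network$edges
  if (!nrow(e))
    return(data.frame(gene = character(), direction = character(),
                      n_diseases = integer(), diseases = character()))
  key <- paste(e$gene, e$direction, sep = "\r")
  spl <- split(e$disease, key)
  out <- data.frame(
    gene = sub("\r.*$", "", names(spl)),
    direction = sub("^.*\r", "", names(spl)),
    n_diseases = lengths(spl),
    diseases = vapply(spl, function(d) paste(sort(d), collapse = ","),
                      character(1L)),
    row.names = NULL)
  out <- out[out$n_diseases >= min_diseases, , drop = FALSE]
  out <- out[order(-out$n_diseases, out$gene, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a diseasome network
#'
#' `write_diseasome_graphml()` writes GraphML with vertex attribute `type`
#' (disease/gene) and edge attribute `direction`;
#' `write_diseasome_sif()` writes SIF lines `disease<TAB>direction<TAB>gene`;
#' `write_pair_stats()` writes the disease-pair overlap table as TSV.
#'
#' @param network A `diseasome_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diseasome_graphml <- function(network, path) {
  stopifnot(inherits(network, "diseasome_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_diseasome_graphml
#' @export
write_diseasome_sif <- function(network, path) {
  stopifnot(inherits(network, "diseasome_network"))
  e <- network$edges
  writeLines(paste(e$disease, e$direction, e$gene, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_diseasome_graphml
#' @export
write_pair_stats <- function(network, path) {
  stopifnot(inherits(network, "diseasome_network"))
  utils::write.table(network$pair_stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
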