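#' Specify a multi-cohort simulation
#'
#' Describes case/control expression cohorts on a shared gene universe with
#' planted up-/down-regulated genes.  Values are drawn on the log2 scale as
#' `Normal(baseline_mean, noise_sd)`; a planted (gene, disease, up) entry
#' shifts that gene's case samples by `+effect_size`, a down entry by
#' `-effect_size`, so the planted log2 fold change equals `effect_size` in
#' expectation and recovery rates are analytic.
#'
#' @param n_genes Size of the gene universe; genes are named `G00001`, ....
#' @param diseases data.frame with columns `disease_id`, `n_case`,
#'   `n_control` (each at least 3).
#' @param planted data.frame with columns `gene`, `disease`, `direction`
#'   (`up`/`down`); may have zero rows.
#' @param effect_size Planted shift in log2 units (default 2).
#' @param noise_sd Standard deviation of the Gaussian noise (default 0.5).
#' @param baseline_mean Baseline log2 expression level (default 7).
#' @param seed Root seed; per-disease substream seeds are derived from it so
#'   adding a cohort does not reshuffle the others.
#'
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes, diseases, planted = NULL,
                              effect_size = 2, noise_sd = 0.5,
                              baseline_mean = 7, seed = 1L) {
  stopifnot(n_genes >= 1L, effect_size > 0, noise_sd > 0,
            is.data.frame(diseases),
            all(c("disease_id", "n_case", "n_control") %in% names(diseases)))
  if (anyDuplicated(diseases$disease_id))
    stop("duplicate disease_id in design", call. = FALSE)
  if (any(diseases$n_case < 3L) || any(diseases$n_control < 3L))
    stop("each cohort needs at least 3 case and 3 control samples",
         call. = FALSE)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  if (is.null(planted))
    planted <- data.frame(gene = character(), disease = character(),
                          direction = character())
  stopifnot(all(c("gene", "disease", "direction") %in% names(planted)))
  if (nrow(planted)) {
    bad <- setdiff(planted$gene, gene_ids)
    if (length(bad))
      stop("planted gene(s) outside the universe: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    stopifnot(all(planted$disease %in% diseases$disease_id),
              all(planted$direction %in% c("up", "down")))
    if (anyDuplicated(planted[, c("gene", "disease")]))
      stop("a gene may be planted at most once per disease", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 diseases = diseases, planted = planted,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Plant a focal-plus-risk-factor overlap structure
#'
#' Convenience constructor for the `planted` table of a
#' [simulation_design()]: the first disease (the focal one) receives `n_up`
#' up- and `n_down` down-regulated genes; every other disease receives
#' `n_shared_up`/`n_shared_down` genes drawn from the focal sets (same
#' direction) plus private genes of its own up to `n_up`/`n_down`, giving
#' known directional overlap with the focal disease.
#'
#' @param disease_ids Character vector, focal disease first.
#' @param gene_ids Gene universe (as in the design).
#' @param n_up,n_down Planted genes per disease and direction.
#' @param n_shared_up,n_shared_down How many of each non-focal disease's
#'   planted genes are drawn from the focal sets.
#' @param seed Seed for the draws.
#'
#' @return data.frame `gene`, `disease`, `direction` for
#'   [simulation_design()].
#' @export
plant_membership <- function(disease_ids, gene_ids, n_up = 30L, n_down = 30L,
                             n_shared_up = 10L, n_shared_down = 10L,
                             seed = 1L) {
  stopifnot(length(disease_ids) >= 1L, n_shared_up <= n_up,
            n_shared_down <= n_down,
            length(gene_ids) >= length(disease_ids) * (n_up + n_down))
  set.seed(seed)
  pool <- sample(gene_ids)  # shuffled; consumed left to right
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  rows <- list()
  focal_up <- take(n_up)
  focal_down <- take(n_down)
  rows[[1L]] <- data.frame(gene = c(focal_up, focal_down),
                           disease = disease_ids[1L],
                           direction = rep(c("up", "down"),
                                           c(n_up, n_down)))
  for (id in disease_ids[-1L]) {
    up <- c(sample(focal_up, n_shared_up), take(n_up - n_shared_up))
    down <- c(sample(focal_down, n_shared_down), take(n_down - n_shared_down))
    rows[[length(rows) + 1L]] <-
      data.frame(gene = c(up, down), disease = id,
                 direction = rep(c("up", "down"),
                                 c(length(up), length(down))))
  }
  do.call(rbind, rows)
}

substream_seed <- function(root, i) {
  as.integer((as.numeric(root) + 104729 * i) %% 2147483629)
}

truth_pair_stats <- function(sets) {
  ids <- vapply(sets, `[[`, character(1L), "disease_id")
  if (length(ids) < 2L)
    return(data.frame(disease_i = character(), disease_j = character(),
                      direction = character(), n_shared = integer(),
                      jaccard = numeric()))
  pairs <- utils::combn(ids, 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    si <- sets[[which(ids == pairs[1L, k])]]
    sj <- sets[[which(ids == pairs[2L, k])]]
    for (dir in c("up", "down", "combined")) {
      gi <- sets_by_direction(si, dir)
      gj <- sets_by_direction(sj, dir)
      inter <- length(intersect(gi, gj))
      uni <- length(union(gi, gj))
      rows[[length(rows) + 1L]] <- data.frame(
        disease_i = si$disease_id, disease_j = sj$disease_id,
        direction = dir, n_shared = inter,
        jaccard = if (uni == 0L) NA_real_ else inter / uni)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate case/control expression cohorts with planted DEGs
#'
#' Draws each cohort's matrix from the design's Gaussian model and returns
#' the datasets together with the ground truth they were generated from.
#' Deterministic: the same design (including its seed) yields bit-identical
#' matrices.
#'
#' @param design A [simulation_design()].
#'
#' @return List with `datasets` (named list of [expression_dataset()]) and
#'   `truth` — a list with `sets` (per-disease true [disease_gene_sets()])
#'   and `pair_stats` (true per-pair shared counts and Jaccard scores for
#'   up/down/combined, including zero-overlap pairs).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  datasets <- list()
  sets <- list()
  for (i in seq_len(nrow(design$diseases))) {
    id <- design$diseases$disease_id[i]
    nc <- design$diseases$n_case[i]
    nk <- design$diseases$n_control[i]
    set.seed(substream_seed(design$seed, i))
    samples <- c(sprintf("%s_case%02d", id, seq_len(nc)),
                 sprintf("%s_ctrl%02d", id, seq_len(nk)))
    vals <- matrix(stats::rnorm(design$n_genes * (nc + nk),
                                mean = design$baseline_mean,
                                sd = design$noise_sd),
                   nrow = design$n_genes,
                   dimnames = list(design$gene_ids, samples))
    pl <- design$planted[design$planted$disease == id, , drop = FALSE]
    if (nrow(pl)) {
      shift <- ifelse(pl$direction == "up", design$effect_size,
                      -design$effect_size)
      vals[pl$gene, seq_len(nc)] <-
        vals[pl$gene, seq_len(nc), drop = FALSE] + shift
    }
    groups <- stats::setNames(rep(c("case", "control"), c(nc, nk)), samples)
    datasets[[id]] <- expression_dataset(vals, groups, id)
    sets[[id]] <- disease_gene_sets(id,
                                    up_genes = pl$gene[pl$direction == "up"],
                                    down_genes = pl$gene[pl$direction == "down"])
  }
  list(datasets = datasets,
       truth = list(sets = sets, pair_stats = truth_pair_stats(sets)))
}

#' Simulate a PPI network with planted hubs
#'
#' Builds a random simple undirected graph in which each planted hub is
#' wired to exactly `min_degree` non-hub partners and every non-hub node is
#' capped at `min(min_degree) - 1` incident edges, so planted hub degrees
#' strictly exceed the maximum non-hub degree by construction.  Additional
#' random non-hub edges are drawn until `n_edges` is reached or the degree
#' cap makes further placement impossible (the realized count is returned).
#'
#' @param n_nodes Number of nodes, named `N0001`, ....
#' @param n_edges Target edge count (including hub edges).
#' @param planted_hubs data.frame with columns `node` (names from the
#'   generated set) and `min_degree` (each at least 2).
#' @param seed Seed.
#'
#' @return List with `network` (a [ppi_network()]) and `truth` — list with
#'   `hubs` (planted node names, by decreasing degree then name) and
#'   `degrees` (their planted degrees).
#' @export
simulate_ppi <- function(n_nodes, n_edges, planted_hubs, seed = 1L) {
  stopifnot(n_nodes >= 3L, n_edges >= 1L, is.data.frame(planted_hubs),
            all(c("node", "min_degree") %in% names(planted_hubs)),
            nrow(planted_hubs) >= 1L)
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  hubs <- as.character(planted_hubs$node)
  mindeg <- as.integer(planted_hubs$min_degree)
  if (!all(hubs %in% nodes))
    stop("planted hub(s) outside the node set", call. = FALSE)
  if (anyDuplicated(hubs))
    stop("duplicate planted hub", call. = FALSE)
  nonhubs <- setdiff(nodes, hubs)
  cap <- min(mindeg) - 1L
  if (cap < 1L)
    stop("planted min_degree must be at least 2", call. = FALSE)
  if (any(mindeg >= n_nodes) || any(mindeg > length(nonhubs)))
    stop("planted min_degree infeasible for the node count", call. = FALSE)
  if (sum(mindeg) > 2L * n_edges)
    stop("edge budget too small for the planted degrees", call. = FALSE)
  if (sum(mindeg) > length(nonhubs) * cap)
    stop("non-hub degree cap cannot absorb the planted hub edges",
         call. = FALSE)

  set.seed(as.integer(seed))
  deg <- stats::setNames(integer(length(nodes)), nodes)
  edges <- matrix(character(), ncol = 2L)
  for (h in seq_along(hubs)) {
    avail <- nonhubs[deg[nonhubs] < cap]
    partners <- sample(avail, mindeg[h])
    edges <- rbind(edges, cbind(hubs[h], partners))
    deg[hubs[h]] <- mindeg[h]
    deg[partners] <- deg[partners] + 1L
  }
  n_left <- n_edges - nrow(edges)
  if (n_left > 0L && length(nonhubs) >= 2L) {
    seen <- new.env(hash = TRUE)
    for (k in seq_len(nrow(edges)))
      assign(paste(sort(edges[k, ]), collapse = "|"), TRUE, envir = seen)
    attempts <- 0L
    max_attempts <- 100L * n_edges
    while (n_left > 0L && attempts < max_attempts) {
      attempts <- attempts + 1L
      open <- nonhubs[deg[nonhubs] < cap]
      if (length(open) < 2L) break
      pair <- sort(sample(open, 2L))
      key <- paste(pair, collapse = "|")
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      edges <- rbind(edges, pair)
      deg[pair] <- deg[pair] + 1L
      n_left <- n_left - 1L
    }
  }
  net <- ppi_network(edges, nodes = nodes)
  ord <- order(-mindeg, hubs)
  list(network = net,
       truth = list(hubs = hubs[ord], degrees = mindeg[ord]))
}

#' Simulate a GMT library with one planted enriched term
#'
#' The planted term contains `ceiling(fraction * |query|)` query genes plus
#' random filler genes; all other terms are drawn uniformly from the
#' universe, so only the planted term is enriched for the query by
#' construction.
#'
#' @param n_terms Number of terms (ids `T001`, ...).
#' @param term_size_range Integer range for term sizes.
#' @param universe Character vector of gene symbols (superset of `query`).
#' @param planted_overlap_fraction Fraction of the query placed in the
#'   planted term, in (0, 1\].
#' @param query Character vector of query genes.
#' @param seed Seed.
#'
#' @return List with `library` (a [gene_set_library()]) and `truth` — list
#'   with `planted_term` (term id) and `planted_overlap` (gene count).
#' @export
simulate_gmt <- function(n_terms, term_size_range = c(10L, 50L), universe,
                         planted_overlap_fraction, query, seed = 1L) {
  universe <- unique(toupper(as.character(universe)))
  query <- unique(toupper(as.character(query)))
  stopifnot(n_terms >= 1L, length(term_size_range) == 2L,
            term_size_range[1L] >= 1L,
            term_size_range[2L] >= term_size_range[1L],
            planted_overlap_fraction > 0, planted_overlap_fraction <= 1,
            length(query) >= 1L)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe", call. = FALSE)
  if (term_size_range[2L] > length(universe))
    stop("term sizes exceed the universe size", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- sprintf("T%03d", seq_len(n_terms))
  planted_idx <- sample(n_terms, 1L)
  k <- ceiling(planted_overlap_fraction * length(query))
  sizes <- sample(seq(term_size_range[1L], term_size_range[2L]),
                  n_terms, replace = TRUE)
  terms <- vector("list", n_terms)
  for (i in seq_len(n_terms)) {
    if (i == planted_idx) {
      core <- if (k == length(query)) query else sample(query, k)
      fill_n <- max(sizes[i] - k, 0L)
      filler <- sample(setdiff(universe, query),
                       min(fill_n, length(universe) - length(query)))
      terms[[i]] <- c(core, filler)
    } else {
      terms[[i]] <- sample(universe, sizes[i])
    }
  }
  names(terms) <- ids
  lib <- gene_set_library(terms, library_id = "synthetic_gmt")
  list(library = lib,
       truth = list(planted_term = ids[planted_idx], planted_overlap = k))
}

#' Write an expression dataset in the pipeline's TSV dialect
#'
#' @param ds An [expression_dataset()].
#' @param matrix_path,groups_path Output paths for the expression matrix and
#'   the sample-group table.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_tsv <- function(ds, matrix_path, groups_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  tab <- data.frame(gene_id = rownames(ds$values), ds$values,
                    check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(ds$groups), group = unname(ds$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(matrix_path)
}

#' Write a PPI network as an edge-list TSV
#'
#' @param net A [ppi_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Materialise a small synthetic demo study on disk
#'
#' Generates a complete input bundle for [run_pipeline()]: two focal
#' cohorts (combined to one focal disease) and two risk-factor cohorts of
#' 500 genes each with planted overlap, a PPI edge list whose planted hubs
#' are genes shared with the focal disease, a pathway-style GMT with a
#' planted term, a benchmark GMT keyed by disease, and a ready-to-run YAML
#' configuration.
#'
#' @param dir Directory to write into (created if needed).
#' @param seed Root seed for every generator.
#'
#' @return Path to the written YAML configuration, invisibly.
#' @export
write_demo_study <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohorts <- c("CAD", "MI", "RF1", "RF2")
  diseases <- data.frame(disease_id = cohorts, n_case = 10L, n_control = 10L)
  gene_ids <- sprintf("G%05d", seq_len(500L))
  planted <- plant_membership(cohorts, gene_ids, n_up = 25L, n_down = 25L,
                              n_shared_up = 10L, n_shared_down = 10L,
                              seed = substream_seed(seed, 11L))
  design <- simulation_design(500L, diseases, planted, seed = seed)
  sim <- simulate_expression(design)

  paths <- list()
  for (id in cohorts) {
    mp <- file.path(dir, paste0(tolower(id), "_expr.tsv"))
    gp <- file.path(dir, paste0(tolower(id), "_groups.tsv"))
    write_expression_tsv(sim$datasets[[id]], mp, gp)
    paths[[id]] <- list(matrix = mp, groups = gp)
  }

  # PPI over the planted genes: hubs drawn from genes the risk factors share
  # with the focal cohorts
  truth_sets <- sim$truth$sets
  focal_genes <- union(union(truth_sets$CAD$up, truth_sets$CAD$down),
                       union(truth_sets$MI$up, truth_sets$MI$down))
  shared <- intersect(focal_genes,
                      union(union(truth_sets$RF1$up, truth_sets$RF1$down),
                            union(truth_sets$RF2$up, truth_sets$RF2$down)))
  pool <- sort(unique(c(focal_genes,
                        unlist(lapply(truth_sets, `[[`, "up")),
                        unlist(lapply(truth_sets, `[[`, "down")))))
  hub_genes <- sort(shared)[seq_len(min(3L, length(shared)))]
  hub_idx <- match(hub_genes, pool)
  ppi_sim <- simulate_ppi(length(pool), n_edges = 4L * length(pool),
                          planted_hubs = data.frame(
                            node = sprintf("N%04d", hub_idx),
                            min_degree = 15L),
                          seed = substream_seed(seed, 12L))
  edges <- as.matrix(ppi_sim$network$edges)
  edges[] <- pool[as.integer(sub("^N", "", edges))]
  ppi_path <- file.path(dir, "ppi_edges.tsv")
  write_edge_list(ppi_network(edges, nodes = pool), ppi_path)

  gmt_sim <- simulate_gmt(50L, c(10L, 40L), universe = gene_ids,
                          planted_overlap_fraction = 0.8,
                          query = sort(shared)[seq_len(min(20L, length(shared)))],
                          seed = substream_seed(seed, 13L))
  pathways_path <- file.path(dir, "pathways.gmt")
  write_gmt(gmt_sim$library, pathways_path)

  bench_terms <- lapply(truth_sets[c("RF1", "RF2")],
                        function(s) union(s$up, s$down))
  names(bench_terms) <- c("RF1", "RF2")
  # decoy disease terms so the benchmark library has a realistic universe
  set.seed(substream_seed(seed, 14L))
  decoys <- lapply(seq_len(20L), function(i) sample(gene_ids, 50L))
  names(decoys) <- sprintf("DECOY%02d", seq_len(20L))
  bench <- gene_set_library(c(bench_terms, decoys), library_id = "benchmark")
  bench_path <- file.path(dir, "benchmark.gmt")
  write_gmt(bench, bench_path)

  cfg <- list(
    combined_focal_id = "CVD",
    focal = list(list(id = "CAD", matrix = paths$CAD$matrix,
                      groups = paths$CAD$groups),
                 list(id = "MI", matrix = paths$MI$matrix,
                      groups = paths$MI$groups)),
    risk_factors = list(list(id = "RF1", matrix = paths$RF1$matrix,
                             groups = paths$RF1$groups),
                        list(id = "RF2", matrix = paths$RF2$matrix,
                             groups = paths$RF2$groups)),
    preprocess = list(log2_policy = "auto", pseudocount = 1,
                      detect_threshold = 50, zscore_ddof = 1),
    deg = list(p_threshold = 0.05, logfc_threshold = 1,
               p_criterion = "raw", test = "student"),
    enrichment = list(p_threshold = 0.05, p_criterion = "raw"),
    ppi_edges = ppi_path,
    hub_k = 10,
    gmt = list(pathways = list(pathways_path),
               benchmarks = list(bench_path)),
    out_dir = file.path(dir, "results"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
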