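#' Load and validate a pipeline configuration
#'
#' The configuration is a declarative YAML (or equivalent list) naming the
#' focal cohort file pairs, the risk-factor cohorts, preprocessing/DEG/
#' enrichment settings, and optional PPI and GMT inputs.  See
#' [write_demo_study()] for a complete generated example.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#'
#' @return A validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    combined_focal_id = "FOCAL",
    preprocess = list(log2_policy = "auto", pseudocount = 1,
                      detect_threshold = 50, zscore_ddof = 1),
    deg = list(p_threshold = 0.05, logfc_threshold = 1,
               p_criterion = "raw", test = "student"),
    enrichment = list(p_threshold = 0.05, p_criterion = "raw"),
    hub_k = 10,
    gmt = list())
  for (key in names(defaults)) {
    if (is.null(config[[key]])) {
      config[[key]] <- defaults[[key]]
    } else if (is.list(defaults[[key]]) && key != "gmt") {
      miss <- setdiff(names(defaults[[key]]), names(config[[key]]))
      config[[key]][miss] <- defaults[[key]][miss]
    }
  }
  if (is.null(config$focal) || !length(config$focal))
    stop("config needs at least one focal dataset", call. = FALSE)
  if (is.null(config$risk_factors) || !length(config$risk_factors))
    stop("config needs at least one risk-factor dataset", call. = FALSE)
  if (is.null(config$out_dir))
    stop("config needs an out_dir", call. = FALSE)
  all_ds <- c(config$focal, config$risk_factors)
  ids <- vapply(all_ds, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("duplicate dataset id in config: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  for (ds in all_ds)
    for (p in c(ds$matrix, ds$groups))
      if (!file.exists(p))
        stop("configured input does not exist: ", p, call. = FALSE)
  for (p in c(config$ppi_edges, unlist(config$gmt)))
    if (!file.exists(p))
      stop("configured input does not exist: ", p, call. = FALSE)
  structure(config, class = c("pipeline_config", "list"))
}

load_and_preprocess <- function(entry, cfg) {
  ds <- read_expression(entry$matrix, entry$groups, entry$id)
  maybe_log2(ds, policy = cfg$preprocess$log2_policy,
             pseudocount = cfg$preprocess$pseudocount,
             detect_threshold = cfg$preprocess$detect_threshold)
}

#' Run the full cross-comparative pipeline
#'
#' Executes the stages in order — preprocess, per-cohort DEG calling, focal
#' combination, diseasome construction, PPI hub ranking, enrichment and
#' benchmark validation — writing every result table and network under the
#' configured output directory together with a JSON manifest (inputs,
#' settings, per-stage row counts).  Stages whose inputs are absent (no PPI
#' edge list, no GMT libraries) are skipped and noted in the manifest.  The
#' run is fully deterministic: no stage draws random numbers.
#'
#' @param config A [read_pipeline_config()] result, a path to a YAML
#'   configuration, or an equivalent list.
#'
#' @return Invisibly, a list of class `pipeline_run` with elements
#'   `manifest`, `deg_tables`, `sets`, `network`, `hub_report` (or `NULL`),
#'   `enrichment` (named list) and `validation` (or `NULL`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), outputs = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name), file.path(out, "failed"))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  note <- function(name, status, counts = list()) {
    manifest$stages[[name]] <<- c(list(status = status), counts)
  }

  all_entries <- c(cfg$focal, cfg$risk_factors)
  focal_ids <- vapply(cfg$focal, `[[`, character(1L), "id")

  datasets <- stage("preprocess", {
    lapply(all_entries, load_and_preprocess, cfg = cfg)
  })
  names(datasets) <- vapply(all_entries, `[[`, character(1L), "id")
  note("preprocess", "completed",
       list(n_datasets = length(datasets),
            genes = lapply(datasets, function(d) nrow(d$values))))

  deg_tables <- stage("deg", {
    tabs <- lapply(datasets, function(d)
      call_degs(d, p_threshold = cfg$deg$p_threshold,
                logfc_threshold = cfg$deg$logfc_threshold,
                p_criterion = cfg$deg$p_criterion, test = cfg$deg$test))
    for (id in names(tabs))
      write_deg_table(tabs[[id]],
                      file.path(out, paste0("deg_", tolower(id), ".tsv")))
    tabs
  })
  sets <- lapply(deg_tables, deg_sets)
  note("deg", "completed",
       list(degs = lapply(sets, function(s) length(s$up) + length(s$down))))

  focal_set <- stage("combine_focal", {
    combine_focal_datasets(sets[focal_ids], cfg$combined_focal_id)
  })
  note("combine_focal", "completed",
       list(n_up = length(focal_set$up), n_down = length(focal_set$down),
            n_conflicted = length(attr(focal_set, "conflicted"))))

  network <- stage("diseasome", {
    net <- build_diseasome(focal_set, unname(sets[setdiff(names(sets),
                                                          focal_ids)]))
    write_pair_stats(net, file.path(out, "pair_stats.tsv"))
    write_diseasome_graphml(net, file.path(out, "diseasome.graphml"))
    write_diseasome_sif(net, file.path(out, "diseasome.sif"))
    utils::write.table(membership_patterns(net, 2L),
                       file.path(out, "membership_patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    net
  })
  shared_genes <- sort(unique(network$edges$gene))
  note("diseasome", "completed",
       list(n_shared_genes = length(shared_genes),
            n_pairs = nrow(network$pair_stats)))

  hub_report <- NULL
  if (!is.null(cfg$ppi_edges)) {
    hub_report <- stage("ppi_hubs", {
      net <- read_edge_list(cfg$ppi_edges)
      sub <- induced_subnetwork(net, shared_genes)
      rep <- top_hubs(sub, k = cfg$hub_k)
      write_hub_report(rep, file.path(out, "hubs.tsv"))
      memberships <- lapply(stats::setNames(nm = sub$nodes), function(g) {
        ids <- network$edges$disease[network$edges$gene == g]
        setdiff(unique(ids), cfg$combined_focal_id)
      })
      write_ppi_graphml(sub, file.path(out, "ppi_subnetwork.graphml"),
                        memberships = memberships)
      rep
    })
    note("ppi_hubs", "completed", list(n_hubs = nrow(hub_report)))
  } else {
    note("ppi_hubs", "skipped (no PPI edge list configured)")
  }

  enrichment <- list()
  for (kind in c("pathways", "ontologies")) {
    paths <- cfg$gmt[[kind]]
    if (is.null(paths) || !length(paths)) {
      note(paste0("enrichment_", kind),
           paste0("skipped (no ", kind, " libraries configured)"))
      next
    }
    res <- stage(paste0("enrichment_", kind), {
      lapply(paths, function(p) {
        lib <- read_gmt(p)
        tab <- enrich(shared_genes, lib,
                      p_threshold = cfg$enrichment$p_threshold,
                      p_criterion = cfg$enrichment$p_criterion)
        write_enrichment_table(tab,
          file.path(out, paste0("enrichment_", lib$library_id, ".tsv")))
        tab
      })
    })
    names(res) <- vapply(paths, function(p) sub("\\.[^.]*$", "", basename(p)),
                         character(1L))
    enrichment <- c(enrichment, res)
    note(paste0("enrichment_", kind), "completed",
         list(n_significant = lapply(res, function(t) sum(t$significant))))
  }

  validation <- NULL
  if (!is.null(cfg$gmt$benchmarks) && length(cfg$gmt$benchmarks)) {
    validation <- stage("validation", {
      libs <- lapply(cfg$gmt$benchmarks, read_gmt)
      risk_ids <- setdiff(names(sets), focal_ids)
      rep <- validate_against_benchmarks(shared_genes, libs, risk_ids,
        p_threshold = cfg$enrichment$p_threshold,
        p_criterion = cfg$enrichment$p_criterion)
      utils::write.table(rep, file.path(out, "benchmark_validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    })
    note("validation", "completed",
         list(n_confirmed = sum(validation$significant)))
  } else {
    note("validation", "skipped (no benchmark libraries configured)")
  }

  cfg_list <- unclass(cfg)
  yaml::write_yaml(cfg_list, file.path(out, "resolved_config.yaml"))
  manifest$config <- cfg_list
  manifest$outputs <- as.list(sort(list.files(out)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(list(manifest = manifest, deg_tables = deg_tables,
                           sets = sets, focal_set = focal_set,
                           network = network, hub_report = hub_report,
                           enrichment = enrichment, validation = validation),
                      class = "pipeline_run"))
}

#' Summarise a pipeline run
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#'
#' @return List of two data.frames: `diseases` (one row per cohort with gene
#'   and DEG counts) and `pairs` (one row per disease pair with shared
#'   up/down/total counts).
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  diseases <- do.call(rbind, lapply(names(run$deg_tables), function(id) {
    tab <- run$deg_tables[[id]]
    data.frame(disease = id, n_genes = nrow(tab),
               n_up = sum(tab$direction == "up"),
               n_down = sum(tab$direction == "down"),
               n_deg = sum(tab$direction != "none"))
  }))
  ps <- run$network$pair_stats
  if (nrow(ps)) {
    key <- paste(ps$disease_i, ps$disease_j, sep = "\t")
    pairs <- do.call(rbind, lapply(unique(key), function(k) {
      sub <- ps[key == k, , drop = FALSE]
      get <- function(dir) {
        v <- sub$n_shared[sub$direction == dir]
        if (length(v)) v else 0L
      }
      data.frame(disease_i = sub$disease_i[1L], disease_j = sub$disease_j[1L],
                 shared_up = get("up"), shared_down = get("down"),
                 shared_total = get("combined"))
    }))
  } else {
    pairs <- data.frame(disease_i = character(), disease_j = character(),
                        shared_up = integer(), shared_down = integer(),
                        shared_total = integer())
  }
  rownames(diseases) <- rownames(pairs) <- NULL
  list(diseases = diseases, pairs = pairs)
}
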