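#' Construct a gene-set library
#'
#' @param terms Named list: term id -> character vector of gene symbols.
#' @param descriptions Optional named character vector of term descriptions.
#' @param library_id Label for the library.
#'
#' @return An object of class `gene_set_library`: list with `library_id`,
#'   `terms` (deduplicated uppercase gene sets), `descriptions` and
#'   `universe` (union of all term genes).
#' @export
gene_set_library <- function(terms, descriptions = NULL,
                             library_id = "library") {
  stopifnot(is.list(terms), !is.null(names(terms)))
  terms <- lapply(terms, function(g) sort(unique(toupper(as.character(g)))))
  empty <- lengths(terms) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty term(s) dropped", call. = FALSE)
    terms <- terms[!empty]
  }
  if (!length(terms))
    stop("library has no non-empty terms", call. = FALSE)
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(terms)), names(terms))
  structure(list(library_id = library_id, terms = terms,
                 descriptions = descriptions[names(terms)],
                 universe = sort(unique(unlist(terms)))),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat("gene_set_library '", x$library_id, "': ", length(x$terms),
      " terms over ", length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set library
#'
#' Standard GMT dialect: one term per line,
#' `term<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate genes within a
#' term are counted once; terms left without genes are dropped with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @param library_id Label; defaults to the file name without extension.
#'
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path, library_id = NULL) {
  if (is.null(library_id))
    library_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("GMT line ", which(keep)[which(nf < 3L)[1L]],
         " has fewer than 3 fields in ", path, call. = FALSE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id in ", path, ": ", ids[duplicated(ids)][1L],
         call. = FALSE)
  desc <- stats::setNames(vapply(parts, `[[`, character(1L), 2L), ids)
  genes <- lapply(parts, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(genes) <- ids
  gene_set_library(genes, desc, library_id)
}

#' Write a gene-set library as GMT
#'
#' @param lib A [gene_set_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path) {
  stopifnot(inherits(lib, "gene_set_library"))
  lines <- vapply(names(lib$terms), function(id) {
    paste(c(id, lib$descriptions[[id]], lib$terms[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' One-sided hypergeometric (Fisher exact) test per term: with universe size
#' `N`, term size `K`, query size `n` (after restriction to the universe)
#' and overlap `x`, the p-value is `P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)`.  P-values are BH-adjusted across all terms
#' of the library; terms are flagged significant at `p <= p_threshold`
#' on the raw p-value by default.
#'
#' By default the background universe is the set of genes appearing in the
#' library (the convention of popular enrichment servers); supply
#' `background` to use the measured-gene universe instead, in which case
#' term sets are restricted to it.
#'
#' @param query Character vector of gene symbols.
#' @param lib A [gene_set_library()].
#' @param background Optional character vector defining the universe.
#' @param p_threshold Significance threshold (default 0.05).
#' @param p_criterion Flag significance on the `"raw"` (default) or
#'   `"adjusted"` p-value.
#'
#' @return An `enrichment_table`: data.frame with one row per term —
#'   `term`, `description`, `overlap_count`, `term_size`, `query_size`,
#'   `universe_size`, `p`, `p_adj`, `significant`, `genes` (comma-joined
#'   overlap) — sorted by p ascending.
#' @export
enrich <- function(query, lib, background = NULL, p_threshold = 0.05,
                   p_criterion = c("raw", "adjusted")) {
  stopifnot(inherits(lib, "gene_set_library"),
            p_threshold > 0, p_threshold < 1)
  p_criterion <- match.arg(p_criterion)
  universe <- if (is.null(background)) lib$universe else
    sort(unique(toupper(as.character(background))))
  query <- unique(toupper(as.character(query)))
  query_in <- intersect(query, universe)
  empty <- data.frame(term = character(), description = character(),
                      overlap_count = integer(), term_size = integer(),
                      query_size = integer(), universe_size = integer(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), genes = character())
  if (!length(query_in)) {
    warning("query does not intersect the universe; empty result",
            call. = FALSE)
    return(structure(empty, class = c("enrichment_table", "data.frame")))
  }
  N <- length(universe)
  n <- length(query_in)
  rows <- lapply(names(lib$terms), function(id) {
    term_genes <- intersect(lib$terms[[id]], universe)
    K <- length(term_genes)
    ov <- intersect(query_in, term_genes)
    x <- length(ov)
    p <- if (K == 0L) 1 else
      stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = id, description = lib$descriptions[[id]],
               overlap_count = x, term_size = K, query_size = n,
               universe_size = N, p = p,
               genes = paste(sort(ov), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p)
  crit <- if (p_criterion == "raw") out$p else out$p_adj
  out$significant <- crit <= p_threshold
  out <- out[order(out$p, out$term),
             c("term", "description", "overlap_count", "term_size",
               "query_size", "universe_size", "p", "p_adj", "significant",
               "genes")]
  rownames(out) <- NULL
  structure(out, library_id = lib$library_id,
            class = c("enrichment_table", "data.frame"))
}

#' Check a gene list against disease-gene benchmark libraries
#'
#' Runs [enrich()] against each benchmark library (GMT with one disease per
#' term) and reports, for every target term, whether it is testable (present
#' in the library) and whether it comes out significant — the standard way
#' of validating that a DEG list recovers known disease associations from
#' curated databases.
#'
#' @param query Character vector of gene symbols.
#' @param benchmark_libs List of [gene_set_library()] objects.
#' @param target_terms Character vector of term ids to look up.
#' @param ... Passed on to [enrich()] (threshold, criterion, background).
#'
#' @return data.frame `library`, `term`, `testable`, `significant`, `p`,
#'   `p_adj`, `overlap_count`, `genes`.
#' @export
validate_against_benchmarks <- function(query, benchmark_libs, target_terms,
                                        ...) {
  stopifnot(length(benchmark_libs) >= 1L,
            all(vapply(benchmark_libs, inherits, logical(1L),
                       "gene_set_library")))
  if (!length(query)) {
    warning("empty query; nothing to validate", call. = FALSE)
    return(data.frame(library = character(), term = character(),
                      testable = logical(), significant = logical(),
                      p = numeric(), p_adj = numeric(),
                      overlap_count = integer(), genes = character()))
  }
  rows <- list()
  for (lib in benchmark_libs) {
    tab <- enrich(query, lib, ...)
    for (tt in target_terms) {
      hit <- tab[tab$term == tt, , drop = FALSE]
      rows[[length(rows) + 1L]] <- if (nrow(hit)) {
        data.frame(library = lib$library_id, term = tt, testable = TRUE,
                   significant = hit$significant, p = hit$p,
                   p_adj = hit$p_adj, overlap_count = hit$overlap_count,
                   genes = hit$genes)
      } else {
        data.frame(library = lib$library_id, term = tt, testable = FALSE,
                   significant = FALSE, p = NA_real_, p_adj = NA_real_,
                   overlap_count = 0L, genes = "")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param table An `enrichment_table` from [enrich()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  stopifnot(inherits(table, "enrichment_table"))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
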