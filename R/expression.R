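#' Construct an expression dataset
#'
#' Bundles a genes x samples expression matrix with case/control labels for
#' one disease cohort and validates the pieces against each other.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene or probe
#'   identifiers), samples in columns (colnames = sample identifiers).
#' @param groups Named character vector mapping every sample identifier to
#'   `"case"` or `"control"`.
#' @param disease_id Short label for the cohort, e.g. `"HTN"`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `disease_id`, `values` and `groups` (groups reordered to match the
#'   matrix columns).
#' @export
expression_dataset <- function(values, groups, disease_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  rn <- rownames(values)
  if (any(!nzchar(rn)) || anyNA(rn))
    stop("empty gene identifiers in expression matrix", call. = FALSE)
  if (anyDuplicated(rn))
    stop("duplicated gene/probe identifiers: ",
         paste(utils::head(unique(rn[duplicated(rn)]), 5L), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("sample(s) missing from group labels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  groups <- groups[colnames(values)]
  bad <- !groups %in% c("case", "control")
  if (any(bad))
    stop("group labels must be 'case' or 'control'; offending sample(s): ",
         paste(names(groups)[bad], collapse = ", "), call. = FALSE)
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L)
    stop("need at least 2 case and 2 control samples; got ",
         sum(groups == "case"), " case / ", sum(groups == "control"),
         " control", call. = FALSE)
  structure(
    list(disease_id = as.character(disease_id)[1L],
         values = values, groups = groups),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset '", x$disease_id, "': ",
      nrow(x$values), " genes x ", ncol(x$values), " samples (",
      sum(x$groups == "case"), " case / ",
      sum(x$groups == "control"), " control)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and its sample groups from TSV files
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and gene/probe identifiers in the first column.  The groups file has two
#' columns, `sample_id` and `case`/`control`, no header required.  Rows whose
#' gene identifier is empty are dropped (with a message), mirroring the
#' "delete empty gene rows" cleaning step of typical GEO workflows.
#'
#' @param matrix_path Path to the expression TSV.
#' @param groups_path Path to the two-column groups TSV.
#' @param disease_id Cohort label attached to the result.
#'
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, groups_path, disease_id) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop("expression file needs a gene column plus at least one sample: ",
         matrix_path, call. = FALSE)
  gene_ids <- raw[[1L]]
  keep <- nzchar(trimws(gene_ids)) & !is.na(gene_ids)
  if (any(!keep))
    message("dropped ", sum(!keep), " row(s) with empty gene identifier")
  raw <- raw[keep, , drop = FALSE]
  gene_ids <- trimws(raw[[1L]])

  num <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L)
  for (j in seq_len(ncol(raw) - 1L)) {
    col <- raw[[j + 1L]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) & !is.na(col) & nzchar(col) &
                   toupper(col) != "NA")
    if (length(bad))
      stop("non-numeric value '", col[bad[1L]], "' at row ", bad[1L],
           " (gene ", gene_ids[bad[1L]], "), column '",
           colnames(raw)[j + 1L], "' of ", matrix_path, call. = FALSE)
    num[, j] <- val
  }
  dimnames(num) <- list(gene_ids, colnames(raw)[-1L])

  grp <- utils::read.delim(groups_path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (identical(tolower(grp[1L, 1L]), "sample_id")) grp <- grp[-1L, , drop = FALSE]
  if (ncol(grp) < 2L)
    stop("groups file needs two columns (sample, case|control): ",
         groups_path, call. = FALSE)
  groups <- stats::setNames(tolower(trimws(grp[[2L]])), trimws(grp[[1L]]))
  expression_dataset(num, groups, disease_id)
}

#' Collapse probe-level rows to one row per gene symbol
#'
#' Probes absent from `probe_map`, or mapped to an empty symbol, are dropped
#' (with a message giving the count).  When several probes map to the same
#' symbol one row is retained according to `rule`:
#' \describe{
#'   \item{`max_abs_logfc`}{probe with the largest absolute difference of
#'     case and control means (ties: lexicographically smallest probe id).}
#'   \item{`max_abs_t`}{probe with the largest absolute Student t statistic.}
#'   \item{`mean`}{per-sample average over the gene's probes.}
#' }
#'
#' @param ds An [expression_dataset()] whose rownames are probe identifiers.
#' @param probe_map Named character vector, probe id -> gene symbol.
#' @param rule Collapse rule, see Details.
#'
#' @return An `ExpressionDataset` with unique gene-symbol rownames.
#' @export
collapse_probes <- function(ds, probe_map,
                            rule = c("max_abs_logfc", "max_abs_t", "mean")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  rule <- match.arg(rule)
  probes <- rownames(ds$values)
  sym <- probe_map[probes]
  mapped <- !is.na(sym) & nzchar(sym)
  if (any(!mapped))
    message("dropped ", sum(!mapped), " unmapped probe(s)")
  if (!any(mapped))
    stop("no probes left after applying the probe map", call. = FALSE)
  vals <- ds$values[mapped, , drop = FALSE]
  sym <- as.character(sym[mapped])

  if (rule == "mean") {
    collapsed <- rowsum(vals, group = sym, reorder = TRUE)
    counts <- as.vector(table(sym)[rownames(collapsed)])
    collapsed <- collapsed / counts
  } else {
    score <- if (rule == "max_abs_logfc") {
      abs(rowMeans(vals[, ds$groups == "case", drop = FALSE]) -
            rowMeans(vals[, ds$groups == "control", drop = FALSE]))
    } else {
      abs(row_t_test(vals, ds$groups)$t)
    }
    # per symbol: highest score wins, ties to the smallest probe id
    ord <- order(sym, -score, rownames(vals), method = "radix")
    pick <- ord[!duplicated(sym[ord])]
    collapsed <- vals[pick, , drop = FALSE]
    rownames(collapsed) <- sym[pick]
    collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  }
  expression_dataset(collapsed, ds$groups, ds$disease_id)
}

#' Log2-transform an expression matrix when appropriate
#'
#' With `policy = "auto"` the transform `log2(x + pseudocount)` is applied
#' only when the data look like raw intensities: the 99th percentile exceeds
#' `detect_threshold` and no value is negative.  Matrices containing negative
#' values are taken to be on a log scale already and are returned unchanged
#' even under `policy = "always"` (with a message).
#'
#' @param ds An [expression_dataset()].
#' @param policy One of `"auto"`, `"always"`, `"never"`.
#' @param pseudocount Non-negative offset added before taking logs.
#' @param detect_threshold Intensity scale cut-off used by `"auto"`.
#'
#' @return The dataset, log2-transformed if the policy decided so; the
#'   attribute `log2_applied` records the decision.
#' @export
maybe_log2 <- function(ds, policy = c("auto", "always", "never"),
                       pseudocount = 1, detect_threshold = 50) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            pseudocount >= 0, detect_threshold > 0)
  policy <- match.arg(policy)
  if (anyNA(ds$values))
    stop("expression matrix contains missing values", call. = FALSE)
  has_neg <- any(ds$values < 0)
  apply_log <- switch(policy,
    never  = FALSE,
    always = !has_neg,
    auto   = !has_neg &&
      stats::quantile(ds$values, 0.99, names = FALSE) > detect_threshold)
  if (policy == "always" && has_neg)
    message("negative values present; treating matrix as already log-scale")
  if (apply_log)
    ds$values <- log2(ds$values + pseudocount)
  attr(ds, "log2_applied") <- apply_log
  ds
}

#' Z-score each gene row across all samples
#'
#' Standardises every gene to mean 0 and standard deviation 1 over all
#' samples of the cohort (cases and controls jointly), the transformation
#' used to put cohorts from different platforms on a comparable scale.
#' Rows with zero variance cannot be standardised and are dropped with a
#' warning.
#'
#' @param ds An [expression_dataset()].
#' @param ddof Degrees-of-freedom correction for the standard deviation:
#'   1 (sample sd, default) or 0 (population sd).
#'
#' @return The dataset with standardised rows.
#' @export
zscore_rows <- function(ds, ddof = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"), ddof %in% c(0, 1))
  x <- ds$values
  n <- ncol(x)
  mu <- rowMeans(x)
  ss <- rowSums((x - mu)^2)
  sd <- sqrt(ss / (n - ddof))
  zero <- sd <= 0 | !is.finite(sd)
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene row(s) dropped", call. = FALSE)
    x <- x[!zero, , drop = FALSE]
    mu <- mu[!zero]
    sd <- sd[!zero]
  }
  if (nrow(x) == 0L)
    stop("no rows left after removing zero-variance genes", call. = FALSE)
  ds$values <- (x - mu) / sd
  ds
}
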