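#' Row-wise two-sample t-tests on an expression matrix
#'
#' Vectorised unpaired t-test of case versus control for every gene row,
#' using the pooled-variance Student form (default) or the Welch form.
#' Degenerate rows (zero variance in both groups) yield `t = 0, p = 1` when
#' the group means agree and `p = 0` with a warning when they do not.
#'
#' @param values Numeric matrix, genes x samples.
#' @param groups Named character vector of `"case"`/`"control"` labels
#'   covering the matrix columns.
#' @param test `"student"` (pooled variance) or `"welch"`.
#'
#' @return A data.frame with one row per gene: `logfc` (case mean minus
#'   control mean), `t`, `df`, `p`.
#' @export
row_t_test <- function(values, groups, test = c("student", "welch")) {
  test <- match.arg(test)
  case <- values[, names(groups)[groups == "case"], drop = FALSE]
  ctrl <- values[, names(groups)[groups == "control"], drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1L)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1L)
  diff <- m1 - m2

  if (test == "student") {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }

  t <- diff / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- se == 0 | !is.finite(se)
  if (any(degen)) {
    same <- degen & diff == 0
    sep <- degen & diff != 0
    t[same] <- 0; p[same] <- 1; df[same] <- NA_real_
    if (any(sep)) {
      warning(sum(sep),
              " gene(s) with zero within-group variance but unequal means; ",
              "p set to 0", call. = FALSE)
      t[sep] <- sign(diff[sep]) * Inf; p[sep] <- 0; df[sep] <- NA_real_
    }
  }
  data.frame(gene = rownames(values), logfc = unname(diff), t = unname(t),
             df = unname(df), p = unname(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Unpaired two-sample t-test for a single gene
#'
#' @param case_values,control_values Numeric vectors (length >= 2 each).
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#'
#' @return List with `t`, `df`, `p` (two-sided) and `logfc`
#'   (mean(case) - mean(control)).
#' @export
t_test_gene <- function(case_values, control_values,
                        test = c("student", "welch")) {
  stopifnot(all(is.finite(case_values)), all(is.finite(control_values)))
  vals <- matrix(c(case_values, control_values), nrow = 1L)
  n1 <- length(case_values); n2 <- length(control_values)
  ids <- paste0("s", seq_len(n1 + n2))
  dimnames(vals) <- list("g", ids)
  groups <- stats::setNames(rep(c("case", "control"), c(n1, n2)), ids)
  res <- row_t_test(vals, groups, test = match.arg(test))
  list(t = res$t, df = res$df, p = res$p, logfc = res$logfc)
}

#' Log2 fold change between two groups
#'
#' Difference of group means on the log2 scale, `mean(case) - mean(control)`
#' (the standard two-group convention).
#'
#' @param case_values,control_values Numeric vectors of log2-scale values.
#' @return A single number.
#' @export
log_fold_change <- function(case_values, control_values) {
  if (!length(case_values) || !length(control_values))
    stop("both groups must be non-empty", call. = FALSE)
  mean(case_values) - mean(control_values)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`): sort the p-values ascending, take
#' `min(1, m * p_(j) / j)`, and enforce monotonicity from the largest rank
#' down.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes for one cohort
#'
#' Computes per-gene log2 fold change, t statistic, raw and BH-adjusted
#' p-values, and a direction call: `up` when the p criterion holds and
#' `logfc >= logfc_threshold`, `down` when it holds and
#' `logfc <= -logfc_threshold`, otherwise `none`.  All comparisons are
#' inclusive.  The matrix is expected on the log2 scale (the t statistic is
#' invariant to per-row affine rescaling such as Z-scoring, but the fold
#' change is not, so call DEGs before standardising).
#'
#' @param ds An [expression_dataset()], collapsed and log2-scaled.
#' @param p_threshold Significance threshold (default 0.05).
#' @param logfc_threshold Minimum absolute log2 fold change (default 1).
#' @param p_criterion Apply the threshold to the `"raw"` (default) or
#'   `"adjusted"` p-value.  Both are always reported.
#' @param test `"student"` or `"welch"`.
#'
#' @return A `deg_table`: data.frame `gene`, `logfc`, `t`, `p`, `p_adj`,
#'   `direction`, sorted by p ascending, with attribute `disease_id`.
#' @export
call_degs <- function(ds, p_threshold = 0.05, logfc_threshold = 1,
                      p_criterion = c("raw", "adjusted"),
                      test = c("student", "welch")) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            p_threshold > 0, p_threshold < 1, logfc_threshold > 0)
  p_criterion <- match.arg(p_criterion)
  res <- row_t_test(ds$values, ds$groups, test = match.arg(test))
  res$p_adj <- benjamini_hochberg(res$p)
  crit_p <- if (p_criterion == "raw") res$p else res$p_adj
  res$direction <- "none"
  res$direction[crit_p <= p_threshold & res$logfc >= logfc_threshold] <- "up"
  res$direction[crit_p <= p_threshold & res$logfc <= -logfc_threshold] <- "down"
  res$df <- NULL
  res <- res[order(res$p, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, disease_id = ds$disease_id,
            class = c("deg_table", "data.frame"))
}

#' Extract the up- and down-regulated gene sets from a DEG table
#'
#' @param table A `deg_table` from [call_degs()].
#' @return A [disease_gene_sets()] object (symbols uppercased).
#' @export
deg_sets <- function(table) {
  stopifnot(inherits(table, "deg_table"))
  disease_gene_sets(attr(table, "disease_id"),
                    up_genes = table$gene[table$direction == "up"],
                    down_genes = table$gene[table$direction == "down"])
}

#' Write a DEG table as TSV
#'
#' Columns `gene`, `logFC`, `t`, `p`, `p_adj`, `direction`, sorted by
#' ascending p.
#'
#' @param table A `deg_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  stopifnot(inherits(table, "deg_table"))
  out <- data.frame(gene = table$gene, logFC = table$logfc, t = table$t,
                    p = table$p, p_adj = table$p_adj,
                    direction = table$direction)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
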