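# Shared fixture builders: tiny in-memory cohorts and their TSV renderings.

tiny_dataset <- function(values = NULL, disease_id = "D1") {
  if (is.null(values)) {
    values <- matrix(c(5, 6, 1, 2,
                       3, 3, 3.5, 2.5,
                       8, 9, 4, 5),
                     nrow = 3L, byrow = TRUE,
                     dimnames = list(c("GA", "GB", "GC"),
                                     c("s1", "s2", "s3", "s4")))
  }
  groups <- stats::setNames(c("case", "case", "control", "control"),
                            colnames(values))
  expression_dataset(values, groups, disease_id)
}

write_tiny_study <- function(dir, matrix_lines = NULL, group_lines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(matrix_lines))
    matrix_lines <- c("gene_id\ts1\ts2\ts3\ts4",
                      "GA\t5\t6\t1\t2",
                      "GB\t3\t3\t3.5\t2.5",
                      "GC\t8\t9\t4\t5")
  if (is.null(group_lines))
    group_lines <- c("s1\tcase", "s2\tcase", "s3\tcontrol", "s4\tcontrol")
  mp <- file.path(dir, "expr.tsv")
  gp <- file.path(dir, "groups.tsv")
  writeLines(matrix_lines, mp)
  writeLines(group_lines, gp)
  list(matrix = mp, groups = gp)
}

# definitional step-up BH: for the p at ascending rank k,
# min over j >= k of min(1, m * p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (j in k:m) best <- min(best, min(1, m * sorted[j] / j))
    adj[k] <- best
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exhaustive hypergeometric tail: enumerate every size-n draw from the
# universe and count draws overlapping the term by >= x
hyper_tail_oracle <- function(N, term_idx, n, x) {
  draws <- utils::combn(N, n)
  memb <- matrix(draws %in% term_idx, nrow = n)
  mean(colSums(memb) >= x)
}

random_gene_set <- function(universe, max_size = length(universe)) {
  sample(universe, sample.int(max_size, 1L))
}
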