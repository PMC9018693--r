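# compact container for a single test result
stat_result <- function(test, statistic, p_value, n, estimate = NA_real_,
                        groups = NULL, note = "") {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 estimate = estimate, n = n, groups = groups, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$test, "\n", sep = "")
  cat(sprintf("  statistic = %.4g, p = %.4g, n = %d\n",
              x$statistic, x$p_value, x$n))
  if (!is.na(x$estimate)) cat(sprintf("  estimate  = %.4g\n", x$estimate))
  if (nzchar(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way ANOVA (between/within mean squares) of a
#' numeric response across group labels, e.g. mean methylation across
#' developmental stages.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 values).
#' @return A `stat_result` with the F statistic and p-value; when the
#'   within-group variance is zero the p-value limit 0 is flagged in `note`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2L, all(table(groups) >= 2L))
  fit <- stats::lm(values ~ groups)
  # a perfect fit (zero within-group variance) draws an advisory from
  # anova.lm; the degenerate case is handled explicitly below
  a <- suppressWarnings(stats::anova(fit))
  fstat <- a[["F value"]][1L]
  p <- a[["Pr(>F)"]][1L]
  note <- ""
  if (a[["Mean Sq"]][2L] < .Machine$double.eps * mean(values^2 + 1)) {
    note <- "zero within-group variance: F unbounded, p -> 0 limit"
    if (!is.finite(fstat)) { fstat <- Inf; p <- 0 }
  }
  stat_result("one-way ANOVA", fstat, p, length(values), groups = levels(groups),
              note = note)
}

#' Pairwise two-sample t tests between all group pairs
#'
#' Follow-up comparisons after ANOVA: one two-sample t test per pair of
#' groups (e.g. P1-P15, P1-P60, P15-P60). Welch's unequal-variance t is the
#' default; `var_equal = TRUE` gives the pooled-variance test (for which a
#' two-group ANOVA satisfies F = t^2). No multiple-testing correction is
#' applied by default; Holm is available.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param var_equal Pooled-variance t instead of Welch.
#' @param correction `"none"` or `"holm"`.
#' @return `data.frame` with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p_value`, `p_adjusted`.
#' @export
pairwise_t_tests <- function(values, groups, var_equal = FALSE,
                             correction = c("none", "holm")) {
  correction <- match.arg(correction)
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2L, all(table(groups) >= 2L))
  pairs <- utils::combn(levels(groups), 2L)
  out <- do.call(rbind, apply(pairs, 2L, function(pr) {
    x <- values[groups == pr[1L]]
    y <- values[groups == pr[2L]]
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(group1 = pr[1L], group2 = pr[2L],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = correction)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between methylation and expression
#'
#' @param mean_meth Numeric vector of per-sample mean methylation.
#' @param rel_expr Matched numeric vector of per-sample relative expression
#'   (2^-dCt).
#' @return `stat_result` with `estimate` = Pearson r and a two-sided
#'   p-value; an explicit `NA` result (note set) when either vector is
#'   constant.
#' @export
methylation_expression_correlation <- function(mean_meth, rel_expr) {
  stopifnot(length(mean_meth) == length(rel_expr), length(mean_meth) >= 3L)
  if (stats::sd(mean_meth) == 0 || stats::sd(rel_expr) == 0) {
    return(stat_result("Pearson correlation", NA_real_, NA_real_,
                       length(mean_meth), estimate = NA_real_,
                       note = "correlation undefined: constant input"))
  }
  ct <- stats::cor.test(mean_meth, rel_expr, method = "pearson")
  stat_result("Pearson correlation", unname(ct$statistic), ct$p.value,
              length(mean_meth), estimate = unname(ct$estimate))
}

# internal: correlation matrix of feature columns vs expression, by tissue
cor_by_tissue <- function(feat, rel_expr, tissue) {
  stopifnot(nrow(feat) == length(rel_expr), length(tissue) == length(rel_expr))
  tissues <- unique(tissue)
  r <- p <- matrix(NA_real_, nrow = ncol(feat), ncol = length(tissues),
                   dimnames = list(colnames(feat), tissues))
  nmat <- matrix(0L, nrow = ncol(feat), ncol = length(tissues),
                 dimnames = dimnames(r))
  for (ts in tissues) {
    sel <- tissue == ts
    if (sum(sel) < 3L)
      stop("tissue ", ts, " has fewer than 3 samples; correlation needs n >= 3")
    for (j in seq_len(ncol(feat))) {
      x <- feat[sel, j]; y <- rel_expr[sel]
      nmat[j, ts] <- sum(sel)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y, method = "pearson")
      r[j, ts] <- unname(ct$estimate)
      p[j, ts] <- ct$p.value
    }
  }
  list(r = r, p = p, n = nmat)
}

#' Epiallele-class vs expression correlation heatmap
#'
#' Per tissue (stages pooled), the Pearson correlation between each
#' epiallele-class proportion and relative expression across that tissue's
#' samples. The expected signature of methylation-driven silencing is a
#' positive correlation for the fully unmethylated class and negative
#' correlations for the high-methylation classes.
#'
#' @param class_props Matrix of class proportions (samples x classes, from
#'   [class_distribution]).
#' @param rel_expr Per-sample relative expression, aligned with the rows of
#'   `class_props`.
#' @param tissue Per-sample tissue labels.
#' @return Object of class `correlation_heatmap`: list with matrices `r`,
#'   `p`, `n` (rows = classes, columns = tissues) and `rows`, `columns`.
#' @export
class_expression_heatmap <- function(class_props, rel_expr, tissue) {
  res <- cor_by_tissue(class_props, rel_expr, tissue)
  structure(c(res, list(rows = rownames(res$r), columns = colnames(res$r),
                        kind = "class")),
            class = "correlation_heatmap")
}

#' Epiallele vs expression correlation heatmap
#'
#' Per tissue (stages pooled), the Pearson correlation between each retained
#' epiallele's frequency and relative expression. Epialleles whose mean
#' frequency across all samples falls below `min_mean_freq` are excluded and
#' listed in the result.
#'
#' @param table An `epiallele_table`.
#' @param rel_expr Per-sample relative expression, named by sample id or
#'   aligned with the table rows.
#' @param tissue Per-sample tissue labels (taken from `table$meta$tissue`
#'   when omitted).
#' @param min_mean_freq Minimum mean frequency for an epiallele row (default
#'   0.01).
#' @return A `correlation_heatmap` (rows = epiallele strings) with an
#'   `excluded` character vector of below-floor epialleles.
#' @export
epiallele_expression_heatmap <- function(table, rel_expr, tissue = NULL,
                                         min_mean_freq = 0.01) {
  stopifnot(inherits(table, "epiallele_table"))
  if (is.null(tissue)) {
    if (is.null(table$meta) || is.null(table$meta$tissue))
      stop("tissue labels are required (table$meta$tissue or the tissue argument)")
    tissue <- table$meta$tissue
  }
  if (!is.null(names(rel_expr)))
    rel_expr <- rel_expr[rownames(table$counts)]
  freq <- table$counts / rowSums(table$counts)
  keep <- colMeans(freq) >= min_mean_freq
  excluded <- colnames(freq)[!keep & colSums(table$counts) > 0L]
  res <- cor_by_tissue(freq[, keep, drop = FALSE], as.numeric(rel_expr), tissue)
  structure(c(res, list(rows = rownames(res$r), columns = colnames(res$r),
                        kind = "epiallele", excluded = excluded,
                        min_mean_freq = min_mean_freq)),
            class = "correlation_heatmap")
}

#' @export
print.correlation_heatmap <- function(x, ...) {
  cat("<correlation_heatmap> ", x$kind, " x expression (Pearson r)\n", sep = "")
  cat("  rows: ", length(x$rows), ", tissues: ",
      paste(x$columns, collapse = ", "), "\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' @export
plot.correlation_heatmap <- function(x, ...) {
  r <- x$r
  r[is.na(r)] <- 0
  if (requireNamespace("pheatmap", quietly = TRUE) && nrow(r) > 1L) {
    pheatmap::pheatmap(r, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = seq(-1, 1, length.out = 101), ...)
  } else {
    graphics::image(t(r), zlim = c(-1, 1), axes = FALSE, ...)
    graphics::axis(1, at = seq(0, 1, length.out = ncol(r)), labels = colnames(r))
  }
  invisible(x)
}

#' Write a correlation heatmap as TSV
#'
#' Long format: row label, tissue, r, p, n.
#'
#' @param x A `correlation_heatmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(x, path) {
  stopifnot(inherits(x, "correlation_heatmap"))
  df <- expand.grid(row = x$rows, tissue = x$columns,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$r <- as.numeric(x$r[cbind(df$row, df$tissue)])
  df$p <- as.numeric(x$p[cbind(df$row, df$tissue)])
  df$n <- as.integer(x$n[cbind(df$row, df$tissue)])
  write_tsv(df, path)
}
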