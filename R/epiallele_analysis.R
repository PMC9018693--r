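#' Build the sample-by-epiallele count table
#'
#' Counts, per sample, the retained reads carrying each complete epiallele
#' string. The column space enumerates all `2^k` binary strings in
#' lexicographic order (leftmost bit = most 5' CpG); absent epialleles are
#' zero. Samples with zero retained reads are dropped with a warning. This is
#' the in-memory analogue of the BIOM profile table of amplicon methylation
#' pipelines.
#'
#' @param calls `data.frame` of read calls (from [call_epialleles], possibly
#'   after [filter_by_conversion]) covering one or more samples.
#' @param spec An [amplicon_spec].
#' @param meta Optional `data.frame` of sample metadata with columns
#'   `sample_id`, `tissue`, `stage`, `replicate`.
#' @return Object of class `epiallele_table`: list with `counts` (integer
#'   matrix, samples x `2^k`), `k`, `meta`, `amplicon`,
#'   `rarefied_depth` (`NULL` until [rarefy] is applied).
#' @export
build_count_table <- function(calls, spec, meta = NULL) {
  stopifnot(inherits(spec, "amplicon_spec"))
  k <- n_cpgs(spec)
  eps <- all_epialleles(k)
  samples <- unique(calls$sample_id)
  ok <- !is.na(calls$epiallele) & grepl("^[01]+$", calls$epiallele)
  calls <- calls[ok, , drop = FALSE]
  if (nrow(calls) > 0L && any(nchar(calls$epiallele) != k))
    stop("epiallele string length does not match the amplicon CpG count")
  counts <- matrix(0L, nrow = length(samples), ncol = length(eps),
                   dimnames = list(samples, eps))
  if (nrow(calls) > 0L) {
    tab <- table(calls$sample_id, factor(calls$epiallele, levels = eps))
    counts[rownames(tab), ] <- as.integer(tab)
  }
  empty <- rowSums(counts) == 0L
  if (any(empty)) {
    warning("dropping sample(s) with zero retained reads: ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (!is.null(meta)) {
    meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(counts = counts, k = k, meta = meta,
                 amplicon = spec$name, rarefied_depth = NULL),
            class = "epiallele_table")
}

#' Construct an epiallele table directly from counts
#'
#' Lower-level constructor used by the simulator and the tests.
#'
#' @param counts Integer matrix, samples x epialleles; column names must be
#'   all `2^k` binary strings (columns are reordered lexicographically) or a
#'   subset, in which case missing epialleles are filled with zeros.
#' @param meta Optional sample metadata.
#' @param amplicon Amplicon name.
#' @return An `epiallele_table`.
#' @export
epiallele_table <- function(counts, meta = NULL, amplicon = "amplicon") {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)),
            !is.null(rownames(counts)))
  k <- unique(nchar(colnames(counts)))
  stopifnot(length(k) == 1L)
  eps <- all_epialleles(k)
  full <- matrix(0L, nrow = nrow(counts), ncol = length(eps),
                 dimnames = list(rownames(counts), eps))
  full[, colnames(counts)] <- as.integer(counts)
  structure(list(counts = full, k = as.integer(k), meta = meta,
                 amplicon = amplicon, rarefied_depth = NULL),
            class = "epiallele_table")
}

#' @export
print.epiallele_table <- function(x, ...) {
  cat("<epiallele_table> ", x$amplicon, "\n", sep = "")
  cat("  samples:   ", nrow(x$counts), "\n", sep = "")
  cat("  epialleles:", ncol(x$counts), " (k = ", x$k, ")\n", sep = "")
  cat("  observed:  ", sum(colSums(x$counts) > 0L), " distinct\n", sep = "")
  rs <- rowSums(x$counts)
  cat("  depth:     ", min(rs), "-", max(rs),
      if (!is.null(x$rarefied_depth))
        paste0(" (rarefied to ", x$rarefied_depth, ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' Rarefy an epiallele count table
#'
#' Subsamples every sample's reads, uniformly without replacement, to exactly
#' `depth` reads, making epiallele counts comparable across samples. Samples
#' with fewer reads than `depth` are dropped and reported. A single rarefied
#' table is drawn (with a recorded seed), following common practice in
#' profile-table normalization.
#'
#' @param table An `epiallele_table`.
#' @param depth Target depth; default is the minimum row sum.
#' @param seed Integer seed.
#' @return A rarefied `epiallele_table` (`rarefied_depth` set).
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "epiallele_table"))
  rs <- rowSums(table$counts)
  if (is.null(depth)) depth <- min(rs)
  depth <- as.integer(depth)
  if (depth <= 0L) stop("depth must be positive")
  keep <- rs >= depth
  if (!all(keep)) {
    message("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(names(rs)[!keep], collapse = ", "))
  }
  counts <- table$counts[keep, , drop = FALSE]
  # vegan warns when every count exceeds 1 (suspecting non-count data);
  # epiallele tables are genuine counts, so that advisory is muted
  rare <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  out <- table
  out$counts <- matrix(as.integer(rare), nrow = nrow(rare),
                       dimnames = dimnames(counts))
  if (!is.null(table$meta))
    out$meta <- table$meta[match(rownames(out$counts),
                                 table$meta$sample_id), , drop = FALSE]
  out$rarefied_depth <- depth
  out
}

#' Epiallele-class distribution
#'
#' The class of an epiallele is its number of methylated CpGs (Hamming
#' weight), regardless of position. Returns per-sample class proportions.
#'
#' @param table An `epiallele_table`.
#' @return Numeric matrix, samples x classes `0..k`; rows sum to 1.
#' @export
class_distribution <- function(table) {
  stopifnot(inherits(table, "epiallele_table"), nrow(table$counts) > 0L)
  w <- epiallele_class(colnames(table$counts))
  agg <- t(rowsum(t(table$counts), group = w))
  # ensure all classes 0..k present
  out <- matrix(0, nrow = nrow(agg), ncol = table$k + 1L,
                dimnames = list(rownames(table$counts), as.character(0:table$k)))
  out[, colnames(agg)] <- agg
  out / rowSums(table$counts)
}

#' Mean and per-CpG methylation from a count table
#'
#' `mean_methylation` is the average methylated fraction over all molecules
#' and CpGs of a sample; `per_cpg_methylation` gives the methylated fraction
#' at each CpG. The identity `mean == rowMeans(per_cpg)` holds exactly.
#'
#' @param table An `epiallele_table`.
#' @return `mean_methylation`: named numeric vector (fractions in `[0,1]`).
#'   `per_cpg_methylation`: numeric matrix, samples x k (columns named by the
#'   amplicon's TSS-relative CpG labels when `labels` are supplied).
#' @export
mean_methylation <- function(table) {
  stopifnot(inherits(table, "epiallele_table"), nrow(table$counts) > 0L)
  w <- epiallele_class(colnames(table$counts))
  v <- as.numeric(table$counts %*% w) / (rowSums(table$counts) * table$k)
  stats::setNames(v, rownames(table$counts))
}

#' @rdname mean_methylation
#' @param labels Optional CpG labels for the columns (e.g.
#'   `spec$cpg_labels`).
#' @export
per_cpg_methylation <- function(table, labels = NULL) {
  stopifnot(inherits(table, "epiallele_table"), nrow(table$counts) > 0L)
  B <- epiallele_bits(colnames(table$counts))   # 2^k x k
  m <- (table$counts %*% B) / rowSums(table$counts)
  colnames(m) <- if (!is.null(labels)) as.character(labels)
                 else paste0("cpg", seq_len(table$k))
  m
}

#' Ordination of epiallele distributions
#'
#' Embeds samples by the similarity of their epiallele profiles. The default
#' is principal coordinates analysis (PCoA) of Bray-Curtis dissimilarities
#' between rarefied epiallele counts, the standard beta-diversity treatment
#' of profile count tables; plain PCA of the epiallele frequency rows is
#' available. If the table has not been rarefied, rows are normalized to
#' frequencies first. Axis signs are fixed by making the largest-magnitude
#' coordinate on each axis positive.
#'
#' @param table An `epiallele_table` with at least 3 samples.
#' @param metric Distance metric for PCoA: `"bray"` (Bray-Curtis) or
#'   `"euclidean"` (on frequency rows).
#' @param method `"pcoa"` or `"pca"`.
#' @param n_axes Number of axes to return (default 2).
#' @return Object of class `epiallele_ordination`: list with `coords`
#'   (samples x axes), `var_explained` (fraction per axis, non-increasing),
#'   `metric`, `method`, `meta`.
#' @export
ordinate <- function(table, metric = c("bray", "euclidean"),
                     method = c("pcoa", "pca"), n_axes = 2L) {
  stopifnot(inherits(table, "epiallele_table"))
  metric <- match.arg(metric)
  method <- match.arg(method)
  n <- nrow(table$counts)
  if (n < 3L) stop("ordination requires at least 3 samples")
  x <- if (!is.null(table$rarefied_depth) && metric == "bray")
    table$counts else table$counts / rowSums(table$counts)
  n_axes <- min(as.integer(n_axes), n - 1L)

  if (method == "pcoa") {
    d <- vegan::vegdist(x, method = metric)
    if (all(d < 1e-12)) {
      coords <- matrix(0, nrow = n, ncol = n_axes,
                       dimnames = list(rownames(x),
                                       paste0("Axis", seq_len(n_axes))))
      ve <- rep(0, n_axes)
    } else {
      # Bray-Curtis is non-Euclidean: some eigenvalues may be negative, which
      # cmdscale reports as a warning; variance fractions use positive ones
      mds <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
      eig <- mds$eig
      pos <- eig[eig > 1e-12]
      ve_all <- eig / sum(pos)
      got <- ncol(mds$points)
      coords <- mds$points[, seq_len(min(n_axes, got)), drop = FALSE]
      ve <- pmax(ve_all[seq_len(ncol(coords))], 0)
      colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
    }
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    got <- min(n_axes, ncol(pc$x))
    coords <- pc$x[, seq_len(got), drop = FALSE]
    tot <- sum(pc$sdev^2)
    ve <- if (tot > 0) (pc$sdev^2)[seq_len(got)] / tot else rep(0, got)
    colnames(coords) <- paste0("Axis", seq_len(got))
  }
  # sign convention: largest-magnitude coordinate positive on each axis
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  structure(list(coords = coords, var_explained = as.numeric(ve),
                 metric = if (method == "pcoa") metric else "euclidean-on-frequencies",
                 method = method, meta = table$meta),
            class = "epiallele_ordination")
}

#' @export
print.epiallele_ordination <- function(x, ...) {
  cat("<epiallele_ordination> ", toupper(x$method), " on ", x$metric,
      " distances\n", sep = "")
  cat("  samples: ", nrow(x$coords), "\n", sep = "")
  cat("  variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.epiallele_ordination <- function(x, color_by = NULL, ...) {
  cols <- "black"
  leg <- NULL
  if (!is.null(color_by) && !is.null(x$meta) && color_by %in% names(x$meta)) {
    f <- factor(x$meta[[color_by]])
    cols <- as.integer(f) + 1L
    leg <- levels(f)
  }
  graphics::plot(x$coords[, 1L], x$coords[, 2L], col = cols, pch = 19,
                 xlab = sprintf("Axis 1 (%.1f%%)", 100 * x$var_explained[1L]),
                 ylab = sprintf("Axis 2 (%.1f%%)", 100 * x$var_explained[2L]),
                 ...)
  if (!is.null(leg))
    graphics::legend("topright", legend = leg, col = seq_along(leg) + 1L,
                     pch = 19, bty = "n")
  invisible(x)
}

#' Write an epiallele table as TSV and BIOM-format JSON
#'
#' The TSV is dense (samples x epialleles, observed columns only); the BIOM
#' file is the sparse JSON interchange format of profile count tables.
#'
#' @param table An `epiallele_table`.
#' @param tsv_path,biom_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_count_table <- function(table, tsv_path = NULL, biom_path = NULL) {
  stopifnot(inherits(table, "epiallele_table"))
  obs <- table$counts[, colSums(table$counts) > 0L, drop = FALSE]
  if (!is.null(tsv_path)) {
    df <- data.frame(sample_id = rownames(obs), obs, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, tsv_path)
  }
  if (!is.null(biom_path)) {
    b <- biomformat::make_biom(t(obs))
    b$date <- "1970-01-01T00:00:00"  # fixed so identical runs are byte-identical
    biomformat::write_biom(b, biom_path)
  }
  invisible(c(tsv_path, biom_path))
}
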