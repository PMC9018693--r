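# deterministic sub-seed derivation (kept inside 32-bit integer range)
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) * 1009
  for (i in seq_along(idx)) s <- s * 31 + as.double(idx[i]) * 101
  as.integer(s %% 2147483646) + 1L
}

#' Build a pipeline run configuration
#'
#' Validates a configuration list (or YAML file) and fills in defaults. The
#' configuration fully determines a run: amplicon geometry, the sample sheet
#' (tissue x developmental stage x replicate), the simulation error model and
#' per-group methylation targets, processing thresholds, rarefaction,
#' ordination and statistics options, and the master seed.
#'
#' @param config A named list, or the path of a YAML file with the same
#'   keys. See [default_run_config] for the full key set.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  d <- default_run_config(outdir = config$outdir %||% tempfile("epiamplicon_run"))
  # deep-merge named sub-lists; replace unnamed lists (e.g. amplicons) whole
  cfg <- d
  for (key in names(config)) {
    v <- config[[key]]
    if (is.list(v) && !is.null(names(v)) && all(nzchar(names(v))) &&
        is.list(cfg[[key]]))
      cfg[[key]] <- utils::modifyList(cfg[[key]], v)
    else
      cfg[[key]] <- v
  }
  if (length(cfg$amplicons) == 0L) stop("config has no amplicons")
  n_samples <- length(cfg$samples$tissues) * length(cfg$samples$stages) *
    cfg$samples$replicates
  if (n_samples == 0L) stop("config defines zero samples")
  for (a in cfg$amplicons) {
    if (is.null(a$n_cpgs) || is.null(a$length) || is.null(a$labels))
      stop("each amplicon needs n_cpgs, length and labels")
    for (ts in cfg$samples$tissues)
      for (st in cfg$samples$stages)
        if (is.null(cfg$simulation$mean_methylation[[ts]][[st]]))
          stop("missing mean_methylation for ", ts, "/", st)
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default demonstration configuration
#'
#' Two synthetic promoter amplicons (7 CpGs in 388 bp and 8 CpGs in 403 bp),
#' two tissues (brain, heart) at three post-natal stages (P1, P15, P60) with
#' 3 replicates each. Mean methylation rises over the stages in brain and
#' falls in heart, and relative expression is negatively coupled to
#' methylation, so the demo reproduces qualitatively the promoter-silencing
#' situation targeted amplicon studies examine.
#'
#' @param outdir Output directory.
#' @param reads_per_sample Simulated molecules per sample per amplicon.
#' @param seed Master seed.
#' @return Config list (pass to [run_config]/[run_pipeline]).
#' @export
default_run_config <- function(outdir = tempfile("epiamplicon_run"),
                               reads_per_sample = 10000L, seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    write_fastq = FALSE,
    amplicons = list(
      list(name = "prom_a", n_cpgs = 7L, length = 388L,
           labels = c(-118L, -91L, -47L, -3L, 92L, 112L, 131L), seed = 101L),
      list(name = "prom_b", n_cpgs = 8L, length = 403L,
           labels = c(-227L, -180L, -113L, -71L, -51L, 22L, 89L, 160L),
           seed = 202L)),
    samples = list(tissues = c("brain", "heart"),
                   stages = c("P1", "P15", "P60"),
                   replicates = 3L),
    simulation = list(
      reads_per_sample = as.integer(reads_per_sample),
      conversion_rate = 0.995,
      inappropriate_conversion_rate = 0.005,
      seq_error_rate = 0.001,
      read_len = 251L,
      mean_methylation = list(
        brain = list(P1 = 0.10, P15 = 0.22, P60 = 0.32),
        heart = list(P1 = 0.35, P15 = 0.15, P60 = 0.10)),
      replicate_sd = 0.02,
      spikein = list(n_reads = 5000L, conversion_rate = 0.995)),
    expression = list(coupling = -2.0, noise_sd = 0.1, base_expr = 1.0,
                      ct_housekeeping = 20, n_housekeeping_rep = 3L),
    thresholds = list(min_overlap = 40L, max_mismatch_frac = 0.1,
                      max_len_dev = 0.1, max_n_frac = 0.02,
                      min_primer_score = 0.8, min_identity = 0.8,
                      max_ambiguous = 0L, min_read_conversion = 0.95),
    rarefaction = list(depth = NULL, seed = 7L),
    ordination = list(metric = "bray", method = "pcoa"),
    stats = list(min_mean_freq = 0.01, var_equal = FALSE,
                 correction = "none"))
}

# sample sheet from the config
config_sample_sheet <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$samples$replicates),
                      stage = cfg$samples$stages,
                      tissue = cfg$samples$tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("tissue", "stage", "replicate")]
  grid$sample_id <- sprintf("%s_%s_r%d", grid$tissue, grid$stage,
                            grid$replicate)
  grid
}

# stage/tissue-specific per-CpG methylation probabilities: same overall mean
# as the target but a distinct per-CpG weighting per tissue x stage, so the
# epiallele support (not just the mean) differs between groups
group_cpg_probs <- function(target, k, amp_seed, tissue_i, stage_i) {
  w <- withr::with_seed(derive_seed(amp_seed, tissue_i * 13L, stage_i),
                        stats::runif(k, 0.3, 1))
  p <- target * w / mean(w)
  pmin(pmax(p, 0.005), 0.98)
}

#' Run the full pipeline
#'
#' Simulate (or, via a custom config, load) every sample's reads, merge read
#' pairs, quality-filter, call epialleles with conversion QC, build raw and
#' rarefied count tables, compute class distributions and mean/per-CpG
#' methylation, ordinate the epiallele distributions, derive coupled qPCR
#' expression, and run the statistical layer (one-way ANOVA across stages,
#' pairwise t tests, methylation-expression Pearson correlation, and the
#' class/epiallele x expression correlation heatmaps). All output tables are
#' written under `config$outdir` together with a manifest sufficient to
#' re-run bit-identically.
#'
#' @param config A `run_config`, a plain list, or a YAML path.
#' @return Object of class `epiallele_run`: list with one entry per amplicon
#'   (tables, ordination, stats, spike-in estimate) plus `config`, `sheet`
#'   and `outdir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  sheet <- config_sample_sheet(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds
  sim <- cfg$simulation
  results <- list()

  # spike-in conversion control (one per run)
  spike <- simulate_spikein(sim$spikein$n_reads %||% 5000L,
                            sim$spikein$conversion_rate %||% sim$conversion_rate,
                            seed = derive_seed(cfg$seed, 999L))
  conv_est <- estimate_conversion_efficiency(spike$reads, spike$reference)
  write_tsv(data.frame(estimate = conv_est$estimate,
                       ci_lo = conv_est$conf_int[1L],
                       ci_hi = conv_est$conf_int[2L],
                       n_reads = conv_est$n_reads,
                       n_c_positions = conv_est$n_c_positions),
            file.path(cfg$outdir, "conversion_spikein.tsv"))

  for (ai in seq_along(cfg$amplicons)) {
    acfg <- cfg$amplicons[[ai]]
    adir <- file.path(cfg$outdir, acfg$name)
    dir.create(adir, showWarnings = FALSE)
    spec <- make_amplicon_spec(acfg$n_cpgs, acfg$length, acfg$labels,
                               seed = acfg$seed %||% derive_seed(cfg$seed, ai))
    spec$name <- acfg$name
    write_amplicon_spec(spec, file.path(adir, "amplicon.yaml"))
    k <- n_cpgs(spec)

    calls_all <- list()
    truth_all <- list()
    summary_rows <- list()
    for (si in seq_len(nrow(sheet))) {
      smp <- sheet[si, ]
      target <- sim$mean_methylation[[smp$tissue]][[smp$stage]]
      sseed <- derive_seed(cfg$seed, ai, si)
      jitter <- withr::with_seed(derive_seed(sseed, 1L),
                                 stats::rnorm(1, 0, sim$replicate_sd %||% 0))
      p_cpg <- group_cpg_probs(max(target + jitter, 0.005), k,
                               acfg$seed %||% ai,
                               match(smp$tissue, cfg$samples$tissues),
                               match(smp$stage, cfg$samples$stages))
      mix <- mixture_spec(bernoulli_mixture(p_cpg, k),
                          n_molecules = sim$reads_per_sample,
                          conversion_rate = sim$conversion_rate,
                          inappropriate_conversion_rate =
                            sim$inappropriate_conversion_rate,
                          seq_error_rate = sim$seq_error_rate,
                          seed = sseed)
      rd <- simulate_bisulfite_reads(spec, mix, sample_id = smp$sample_id,
                                     read_len = sim$read_len %||% 251L)
      if (isTRUE(cfg$write_fastq)) {
        fqdir <- file.path(adir, "fastq")
        dir.create(fqdir, showWarnings = FALSE)
        write_fastq(rd$fw, file.path(fqdir, paste0(smp$sample_id, "_R1.fastq")))
        write_fastq(rd$rv, file.path(fqdir, paste0(smp$sample_id, "_R2.fastq")))
      }
      truth_all[[si]] <- data.frame(sample_id = smp$sample_id,
                                    epiallele = names(table(rd$truth)),
                                    count = as.integer(table(rd$truth)),
                                    stringsAsFactors = FALSE)
      mg <- merge_read_pairs(rd$fw, rd$rv, min_overlap = th$min_overlap,
                             max_mismatch_frac = th$max_mismatch_frac)
      merged <- mg$seq[!is.na(mg$seq)]
      qf <- quality_filter(merged, spec, max_len_dev = th$max_len_dev,
                           max_n_frac = th$max_n_frac,
                           min_primer_score = th$min_primer_score)
      kept <- merged[qf$pass]
      calls <- call_epialleles(kept, spec, sample_id = smp$sample_id,
                               max_ambiguous = th$max_ambiguous,
                               min_identity = th$min_identity)
      fc <- filter_by_conversion(calls[!calls$rejected, , drop = FALSE],
                                 th$min_read_conversion)
      calls_all[[si]] <- fc$calls
      summary_rows[[si]] <- data.frame(
        sample_id = smp$sample_id, tissue = smp$tissue, stage = smp$stage,
        replicate = smp$replicate,
        reads_total = length(rd$fw), reads_merged = mg$n_merged,
        reads_filtered = length(kept),
        reads_called = sum(!calls$rejected),
        reads_retained = nrow(fc$calls),
        bisulfite_efficiency = mean(fc$calls$read_conversion),
        stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, calls_all)
    summary_df <- do.call(rbind, summary_rows)
    write_tsv(summary_df, file.path(adir, "sample_summary.tsv"))
    write_tsv(do.call(rbind, truth_all), file.path(adir, "truth_counts.tsv"))
    write_tsv(calls[, c("sample_id", "epiallele", "read_conversion")],
              file.path(adir, "read_calls.tsv"))
    filter_counts <- data.frame(
      sample_id = summary_df$sample_id,
      merge_rejected = summary_df$reads_total - summary_df$reads_merged,
      filter_rejected = summary_df$reads_merged - summary_df$reads_filtered,
      call_rejected = summary_df$reads_filtered - summary_df$reads_called,
      conversion_rejected = summary_df$reads_called - summary_df$reads_retained,
      retained = summary_df$reads_retained, stringsAsFactors = FALSE)
    write_tsv(filter_counts, file.path(adir, "filter_report.tsv"))

    tbl <- build_count_table(calls, spec, meta = sheet)
    write_count_table(tbl, file.path(adir, "count_table.tsv"),
                      file.path(adir, "count_table.biom"))
    rtbl <- rarefy(tbl, depth = cfg$rarefaction$depth,
                   seed = cfg$rarefaction$seed)
    write_count_table(rtbl, file.path(adir, "count_table_rarefied.tsv"))

    cls <- class_distribution(rtbl)
    write_tsv(data.frame(sample_id = rownames(cls), cls, check.names = FALSE),
              file.path(adir, "class_distribution.tsv"))
    mm <- mean_methylation(rtbl)
    pc <- per_cpg_methylation(rtbl, labels = spec$cpg_labels)
    write_tsv(data.frame(sample_id = names(mm), mean_methylation = mm),
              file.path(adir, "mean_methylation.tsv"))
    write_tsv(data.frame(sample_id = rownames(pc), pc, check.names = FALSE),
              file.path(adir, "per_cpg_methylation.tsv"))

    ord <- ordinate(rtbl, metric = cfg$ordination$metric,
                    method = cfg$ordination$method)
    write_tsv(data.frame(sample_id = rownames(ord$coords), ord$coords,
                         check.names = FALSE),
              file.path(adir, "ordination.tsv"))
    write_tsv(data.frame(axis = seq_along(ord$var_explained),
                         var_explained = ord$var_explained),
              file.path(adir, "ordination_variance.tsv"))

    # expression coupled to the realized mean methylation
    ct_tab <- simulate_expression(
      mm, coupling = cfg$expression$coupling,
      noise_sd = cfg$expression$noise_sd,
      seed = derive_seed(cfg$seed, ai, 555L),
      transcript = acfg$name,
      base_expr = cfg$expression$base_expr %||% 1,
      ct_housekeeping = cfg$expression$ct_housekeeping %||% 20,
      n_housekeeping_rep = cfg$expression$n_housekeeping_rep %||% 3L)
    write_tsv(ct_tab, file.path(adir, "expression_ct.tsv"))
    expr <- delta_ct_table(ct_tab)
    write_tsv(expr, file.path(adir, "expression.tsv"))
    rel <- stats::setNames(expr$rel_expr, expr$sample_id)[names(mm)]

    meta <- rtbl$meta
    stats_rows <- list(); pair_rows <- list(); cor_rows <- list()
    for (ts in unique(meta$tissue)) {
      sel <- meta$tissue == ts
      an <- anova_oneway(mm[sel], meta$stage[sel])
      stats_rows[[ts]] <- data.frame(tissue = ts, test = an$test,
                                     statistic = an$statistic,
                                     p_value = an$p_value, n = an$n,
                                     stringsAsFactors = FALSE)
      pt <- pairwise_t_tests(mm[sel], meta$stage[sel],
                             var_equal = cfg$stats$var_equal %||% FALSE,
                             correction = cfg$stats$correction %||% "none")
      pt <- cbind(tissue = ts, pt)
      pair_rows[[ts]] <- pt
      ct <- methylation_expression_correlation(mm[sel], rel[sel])
      cor_rows[[ts]] <- data.frame(tissue = ts, r = ct$estimate,
                                   p_value = ct$p_value, n = ct$n,
                                   stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, stats_rows), file.path(adir, "stats_anova.tsv"))
    write_tsv(do.call(rbind, pair_rows), file.path(adir, "stats_pairwise.tsv"))
    write_tsv(do.call(rbind, cor_rows), file.path(adir, "stats_correlation.tsv"))

    hm_cls <- class_expression_heatmap(class_distribution(rtbl), rel,
                                       meta$tissue)
    write_heatmap_tsv(hm_cls, file.path(adir, "heatmap_class.tsv"))
    hm_epi <- epiallele_expression_heatmap(rtbl, rel,
                                           min_mean_freq =
                                             cfg$stats$min_mean_freq %||% 0.01)
    write_heatmap_tsv(hm_epi, file.path(adir, "heatmap_epiallele.tsv"))

    results[[acfg$name]] <- list(
      spec = spec, table = tbl, rarefied = rtbl,
      class_distribution = cls, mean_methylation = mm,
      per_cpg_methylation = pc, ordination = ord,
      expression = expr, summary = summary_df,
      anova = do.call(rbind, stats_rows),
      pairwise = do.call(rbind, pair_rows),
      correlation = do.call(rbind, cor_rows),
      heatmap_class = hm_cls, heatmap_epiallele = hm_epi)
  }

  manifest <- list(
    package = "epiamplicon",
    version = as.character(utils::packageVersion("epiamplicon")),
    seed = cfg$seed,
    amplicons = vapply(cfg$amplicons, `[[`, "", "name"),
    n_samples = nrow(sheet),
    reads_per_sample = sim$reads_per_sample,
    thresholds = th,
    rarefaction = cfg$rarefaction,
    ordination = cfg$ordination,
    conversion_estimate = conv_est$estimate)
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))

  structure(list(amplicons = results, config = cfg, sheet = sheet,
                 outdir = cfg$outdir, conversion = conv_est),
            class = "epiallele_run")
}

#' @export
print.epiallele_run <- function(x, ...) {
  cat("<epiallele_run> ", length(x$amplicons), " amplicon(s), ",
      nrow(x$sheet), " samples\n", sep = "")
  for (nm in names(x$amplicons)) {
    a <- x$amplicons[[nm]]
    cat("  ", nm, ": k = ", a$table$k,
        ", rarefied depth = ", a$rarefied$rarefied_depth,
        ", axis-1 variance = ",
        sprintf("%.1f%%", 100 * a$ordination$var_explained[1L]), "\n", sep = "")
  }
  cat("  spike-in conversion estimate: ",
      sprintf("%.4f", x$conversion$estimate), "\n", sep = "")
  cat("  outputs: ", x$outdir, "\n", sep = "")
  invisible(x)
}
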