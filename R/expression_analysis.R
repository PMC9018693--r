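#' Relative expression from qPCR Ct values (2^-dCt)
#'
#' dCt is the target Ct minus the mean housekeeping Ct; relative expression
#' is `2^-dCt`, so one extra cycle to threshold halves the estimate.
#' Housekeeping replicates are averaged on the Ct scale before the
#' difference.
#'
#' @param ct_target Numeric scalar, target-transcript Ct (cycles, finite,
#'   > 0).
#' @param ct_housekeeping Numeric vector of housekeeping Ct measurements
#'   (>= 1 value).
#' @return Relative expression (positive scalar).
#' @examples
#' delta_ct_expression(25, c(20, 22))  # 2^-4 = 0.0625
#' @export
delta_ct_expression <- function(ct_target, ct_housekeeping) {
  if (length(ct_housekeeping) == 0L || any(is.na(ct_housekeeping)))
    stop("housekeeping Ct values are required")
  stopifnot(length(ct_target) == 1L, is.finite(ct_target), ct_target > 0,
            all(is.finite(ct_housekeeping)), all(ct_housekeeping > 0))
  2^-(ct_target - mean(ct_housekeeping))
}

#' Relative expression table from a long Ct table
#'
#' Applies [delta_ct_expression] per sample and transcript. Target
#' replicates, like housekeeping replicates, are averaged on the Ct scale.
#'
#' @param ct_table `data.frame` with columns `sample_id`, `transcript`, `ct`,
#'   `role` (see [read_ct_table]); housekeeping rows are shared across
#'   transcripts of a sample.
#' @return `data.frame` with columns `sample_id`, `transcript`, `ct_target`,
#'   `ct_housekeeping` (mean), `rel_expr`.
#' @export
delta_ct_table <- function(ct_table) {
  need <- c("sample_id", "transcript", "ct", "role")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  tg <- ct_table[ct_table$role == "target", , drop = FALSE]
  hk <- ct_table[ct_table$role == "housekeeping", , drop = FALSE]
  if (nrow(hk) == 0L) stop("housekeeping Ct values are required")
  hk_mean <- tapply(hk$ct, hk$sample_id, mean)
  key <- unique(tg[, c("sample_id", "transcript")])
  out <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    s <- key$sample_id[i]; tr <- key$transcript[i]
    ctt <- mean(tg$ct[tg$sample_id == s & tg$transcript == tr])
    if (!s %in% names(hk_mean))
      stop("no housekeeping Ct for sample ", s)
    data.frame(sample_id = s, transcript = tr, ct_target = ctt,
               ct_housekeeping = as.numeric(hk_mean[s]),
               rel_expr = delta_ct_expression(ctt, hk$ct[hk$sample_id == s]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
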