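# substitution matrix for bisulfite-aware global alignment: Y (the converted
# reference's C-or-T at CpG positions) matches both C and T at full score
bisulfite_submat <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "Y", "N")
  m <- matrix(mismatch, 6, 6, dimnames = list(letters, letters))
  diag(m) <- match
  m["Y", "C"] <- m["C", "Y"] <- match
  m["Y", "T"] <- m["T", "Y"] <- match
  m["N", ] <- m[, "N"] <- 0
  m
}

#' Align a merged read to an amplicon
#'
#' Reads the same length as the reference take a fast identity-mapping path
#' (the amplicon design produces full-length merged molecules; indels are
#' rare). Anything else is globally aligned (affine gaps) against the
#' bisulfite-converted reference in which CpG cytosines are the ambiguity
#' code Y, so both the methylated (C) and unmethylated (T) read bases score
#' as matches. The result reports the read base over every reference
#' position.
#'
#' @param read Character scalar, a merged read that passed filtering.
#' @param spec An [amplicon_spec].
#' @param min_identity Identity floor (C/T-tolerant at original-C positions);
#'   reads below it are rejected.
#' @return List with `aligned` (character scalar: the read projected onto
#'   reference coordinates, `-` at deletions), `identity`, and `rejected`
#'   (logical).
#' @export
align_to_amplicon <- function(read, spec, min_identity = 0.8) {
  stopifnot(inherits(spec, "amplicon_spec"), is.character(read),
            length(read) == 1L)
  conv <- converted_reference(spec, cpg_as = "Y")
  L <- nchar(conv)
  if (nchar(read) == L) {
    aligned <- read
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(read), conv, type = "global",
      substitutionMatrix = bisulfite_submat(),
      gapOpening = 6, gapExtension = 2)
    aligned <- as.character(Biostrings::aligned(pa))[1L]
  }
  id <- alignment_identity(aligned, conv)
  list(aligned = aligned, identity = id, rejected = id < min_identity)
}

# identity of a reference-coordinate read against the Y-form converted
# reference; Y matches C or T
alignment_identity <- function(aligned, conv) {
  a <- strsplit(aligned, "", fixed = TRUE)[[1L]]
  r <- strsplit(conv, "", fixed = TRUE)[[1L]]
  n <- min(length(a), length(r))
  a <- a[seq_len(n)]; r <- r[seq_len(n)]
  ok <- a == r | (r == "Y" & a %in% c("C", "T"))
  sum(ok) / length(r)
}

#' Call epialleles from merged reads
#'
#' For each read aligned to the amplicon, every scored CpG position is read
#' as `"1"` (C, methylated), `"0"` (T, unmethylated) or ambiguous (any other
#' base or a gap). A read with more than `max_ambiguous` ambiguous CpGs is
#' rejected: an incomplete string cannot be placed in the `2^k` epiallele
#' space. Per-read conversion QC is the fraction of non-CpG reference
#' cytosines read as T.
#'
#' Reads whose length equals the reference length are scored by direct
#' position lookup; others go through [align_to_amplicon].
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of merged,
#'   filtered reads.
#' @param spec An [amplicon_spec].
#' @param sample_id Sample identifier.
#' @param max_ambiguous Maximum ambiguous CpGs per read (default 0).
#' @param min_identity Alignment identity floor.
#' @return `data.frame` with one row per input read: `sample_id`,
#'   `epiallele` (`NA` when rejected), `n_ambiguous`, `read_conversion`,
#'   `rejected`, `reject_reason` (`""`, `"ambiguous_cpg"` or
#'   `"low_identity"`).
#' @export
call_epialleles <- function(reads, spec, sample_id = "sample1",
                            max_ambiguous = 0L, min_identity = 0.8) {
  stopifnot(inherits(spec, "amplicon_spec"))
  reads <- as.character(reads)
  n <- length(reads)
  L <- nchar(spec$reference_seq)
  k <- n_cpgs(spec)
  ncc <- spec$non_cpg_c_offsets
  conv <- converted_reference(spec, cpg_as = "Y")

  epiallele <- rep(NA_character_, n)
  n_amb <- integer(n)
  read_conv <- rep(NA_real_, n)
  reject_reason <- rep("", n)
  if (n == 0L)
    return(data.frame(sample_id = character(0), epiallele = character(0),
                      n_ambiguous = integer(0), read_conversion = numeric(0),
                      rejected = logical(0), reject_reason = character(0),
                      stringsAsFactors = FALSE))

  # project every read onto reference coordinates
  aligned <- character(n)
  identity <- numeric(n)
  full_len <- nchar(reads) == L
  aligned[full_len] <- reads[full_len]
  for (i in which(!full_len)) {
    al <- align_to_amplicon(reads[i], spec, min_identity = min_identity)
    aligned[i] <- al$aligned
  }

  # byte-matrix scoring: all projected reads have reference length
  m <- matrix(unlist(lapply(aligned, charToRaw), use.names = FALSE), nrow = L)
  refY <- charToRaw(conv)
  C <- charToRaw("C"); T <- charToRaw("T"); Y <- charToRaw("Y")
  eq <- m == as.vector(refY)
  tol <- (as.vector(refY) == as.vector(Y)) & (m == as.vector(C) | m == as.vector(T))
  identity <- colSums(eq | tol) / L

  cpg <- m[spec$cpg_offsets, , drop = FALSE]
  bit <- matrix(NA_character_, nrow = k, ncol = n)
  bit[cpg == as.vector(C)] <- "1"
  bit[cpg == as.vector(T)] <- "0"
  n_amb <- colSums(is.na(bit))
  complete <- n_amb <= max_ambiguous
  if (any(complete)) {
    bit_c <- bit[, complete, drop = FALSE]
    bit_c[is.na(bit_c)] <- "?"  # masked positions (only if max_ambiguous > 0)
    epiallele[complete] <- apply(bit_c, 2L, paste, collapse = "")
  }
  if (length(ncc) > 0L) {
    ncm <- m[ncc, , drop = FALSE]
    read_conv <- colSums(ncm == as.vector(T)) / length(ncc)
  } else {
    read_conv <- rep(NA_real_, n)
  }

  low_id <- identity < min_identity
  reject_reason[!complete] <- "ambiguous_cpg"
  reject_reason[low_id] <- "low_identity"
  rejected <- low_id | !complete
  epiallele[rejected] <- NA_character_

  data.frame(sample_id = sample_id, epiallele = epiallele,
             n_ambiguous = as.integer(n_amb), read_conversion = read_conv,
             rejected = rejected, reject_reason = reject_reason,
             stringsAsFactors = FALSE)
}

#' Filter read calls by per-read conversion QC
#'
#' Discards reads whose fraction of converted non-CpG cytosines falls below
#' the threshold: molecules that escaped bisulfite conversion would otherwise
#' inflate apparent methylation.
#'
#' @param calls `data.frame` from [call_epialleles].
#' @param min_read_conversion Minimum per-read conversion fraction.
#' @return List with `calls` (retained rows), `n_discarded`, and `report`
#'   (per-sample counts and mean conversion of retained reads, the
#'   "bisulphite efficiency" summary column).
#' @export
filter_by_conversion <- function(calls, min_read_conversion = 0.95) {
  keep <- !is.na(calls$read_conversion) &
    calls$read_conversion >= min_read_conversion
  retained <- calls[keep, , drop = FALSE]
  if (nrow(retained) == 0L) {
    return(list(calls = retained, n_discarded = sum(!keep),
                report = data.frame(sample_id = character(0),
                                    mean_read_conversion = numeric(0),
                                    n_retained = integer(0))))
  }
  agg <- stats::aggregate(read_conversion ~ sample_id, data = retained,
                          FUN = mean)
  names(agg)[2L] <- "mean_read_conversion"
  agg$n_retained <- as.integer(table(retained$sample_id)[agg$sample_id])
  list(calls = retained, n_discarded = sum(!keep), report = agg)
}

#' Estimate bisulfite conversion efficiency from spike-in reads
#'
#' Pools, across all reads matching the fully unmethylated spike-in
#' reference, the fraction of reference cytosine positions read as T, with an
#' exact binomial 95% confidence interval. Reads are length-matched to the
#' reference (the spike-in amplicon is short enough to be read in full);
#' reads that do not match the reference at `min_identity` or better are
#' excluded.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector of spike-in
#'   reads.
#' @param reference Spike-in reference sequence (default
#'   [spikein_reference()]).
#' @param min_identity Identity floor for counting a read as spike-in
#'   (C/T-tolerant at C positions).
#' @return Object of class `conversion_estimate`: list with `estimate`
#'   (fraction, `NA` if no read aligned), `conf_int` (length-2), `n_reads`,
#'   `n_c_positions` (pooled Bernoulli trials).
#' @export
estimate_conversion_efficiency <- function(reads,
                                           reference = spikein_reference(),
                                           min_identity = 0.8) {
  reads <- as.character(reads)
  L <- nchar(reference)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  cpos <- which(ref_chars == "C")
  reads <- reads[nchar(reads) == L]
  out <- structure(list(estimate = NA_real_, conf_int = c(NA_real_, NA_real_),
                        n_reads = 0L, n_c_positions = 0L),
                   class = "conversion_estimate")
  if (length(reads) == 0L) return(out)
  m <- matrix(unlist(lapply(reads, charToRaw), use.names = FALSE), nrow = L)
  refraw <- charToRaw(reference)
  C <- charToRaw("C"); T <- charToRaw("T")
  # identity tolerant at C positions (C or T both fine there)
  eq <- m == as.vector(refraw)
  eq[cpos, ] <- eq[cpos, , drop = FALSE] |
    m[cpos, , drop = FALSE] == as.vector(T)
  keep <- colSums(eq) / L >= min_identity
  if (!any(keep)) return(out)
  m <- m[, keep, drop = FALSE]
  sub <- m[cpos, , drop = FALSE]
  n_t <- sum(sub == as.vector(T))
  n_tot <- sum(sub == as.vector(T) | sub == as.vector(C))
  if (n_tot == 0L) return(out)
  bt <- stats::binom.test(n_t, n_tot)
  structure(list(estimate = n_t / n_tot,
                 conf_int = as.numeric(bt$conf.int),
                 n_reads = sum(keep), n_c_positions = n_tot),
            class = "conversion_estimate")
}

#' @export
print.conversion_estimate <- function(x, ...) {
  if (is.na(x$estimate)) {
    cat("<conversion_estimate> no aligned spike-in reads; no estimate\n")
  } else {
    cat(sprintf(
      "<conversion_estimate> %.4f (95%% CI %.4f-%.4f) from %d reads, %d C positions\n",
      x$estimate, x$conf_int[1L], x$conf_int[2L], x$n_reads, x$n_c_positions))
  }
  invisible(x)
}
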