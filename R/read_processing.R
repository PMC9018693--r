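#' Merge one pair of amplicon reads by overlap
#'
#' The reverse read is reverse-complemented, then every
#' suffix(forward)/prefix(reverse) overlap of length at least `min_overlap`
#' is scored by its mismatch fraction. The best candidate (smallest mismatch
#' fraction; ties broken by the longest overlap) is accepted when its
#' mismatch fraction is at most `max_mismatch_frac`; mismatched overlap
#' positions are resolved in favour of the forward read. Rejection is a
#' value, not an error.
#'
#' @param fw,rv Character reads (the reverse mate in sequencer orientation).
#' @param min_overlap Minimum overlap length (default 40, the standard
#'   amplicon-assembly threshold).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the
#'   overlap.
#' @return A list with `merged` (logical), `seq` (consensus or `NA`),
#'   `overlap`, `mismatches`.
#' @examples
#' s <- strrep("ACGT", 30)
#' fw <- substr(s, 1, 80)
#' rv <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAStringSet(substr(s, 41, 120))))
#' merge_read_pair(fw, rv)$seq == s
#' @export
merge_read_pair <- function(fw, rv, min_overlap = 40L,
                            max_mismatch_frac = 0.1) {
  stopifnot(is.character(fw), is.character(rv),
            length(fw) == 1L, length(rv) == 1L,
            nzchar(fw), nzchar(rv))
  rv_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rv)))
  res <- merge_pairs_cpp(fw, rv_rc, as.integer(min_overlap),
                         max_mismatch_frac)
  list(merged = !is.na(res$seq[1L]),
       seq = res$seq[1L],
       overlap = res$overlap[1L],
       mismatches = res$mismatches[1L])
}

#' Merge many read pairs
#'
#' Vectorised merging of matched forward/reverse read sets (same contract as
#' [merge_read_pair]).
#'
#' @param fw,rv [Biostrings::DNAStringSet] or character vectors of equal
#'   length (reverse mates in sequencer orientation).
#' @param min_overlap,max_mismatch_frac See [merge_read_pair].
#' @return List with `seq` (character; `NA` where rejected), `overlap`,
#'   `mismatches`, `n_merged`, `n_rejected`.
#' @export
merge_read_pairs <- function(fw, rv, min_overlap = 40L,
                             max_mismatch_frac = 0.1) {
  fw <- as.character(fw); rv <- as.character(rv)
  stopifnot(length(fw) == length(rv))
  if (length(fw) == 0L)
    return(list(seq = character(0), overlap = integer(0),
                mismatches = integer(0), n_merged = 0L, n_rejected = 0L))
  rv_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rv)))
  res <- merge_pairs_cpp(fw, rv_rc, as.integer(min_overlap),
                         max_mismatch_frac)
  list(seq = res$seq, overlap = res$overlap, mismatches = res$mismatches,
       n_merged = sum(!is.na(res$seq)), n_rejected = sum(is.na(res$seq)))
}

#' Quality-filter merged reads against an amplicon
#'
#' A read fails when (checked in this order, first failure recorded as the
#' reason): its length deviates from the reference length by more than
#' `max_len_dev`; its N fraction exceeds `max_n_frac`; or neither primer
#' anchor matches its end of the read at identity `min_primer_score` or
#' better. Primer identity is computed against the bisulfite-converted
#' reference with C/T-tolerant comparison at every original-cytosine position
#' (mirroring degenerate bisulfite primers).
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of merged
#'   reads.
#' @param spec An [amplicon_spec].
#' @param max_len_dev Maximum relative length deviation.
#' @param max_n_frac Maximum N fraction.
#' @param min_primer_score Minimum primer anchor identity.
#' @return List with `pass` (logical), `reason` (character: `"pass"`,
#'   `"length"`, `"n_frac"`, `"primer"`) and `report` (a `data.frame` of
#'   reason counts that partitions the input).
#' @export
quality_filter <- function(reads, spec, max_len_dev = 0.1,
                           max_n_frac = 0.02, min_primer_score = 0.8) {
  stopifnot(inherits(spec, "amplicon_spec"))
  reads <- as.character(reads)
  n <- length(reads)
  L <- nchar(spec$reference_seq)
  reason <- rep("pass", n)

  len_ok <- abs(nchar(reads) - L) <= max_len_dev * L
  reason[!len_ok] <- "length"

  n_frac <- ifelse(nchar(reads) > 0,
                   vapply(gregexpr("N", reads, fixed = TRUE),
                          function(g) sum(g > 0L), 0) / nchar(reads), 0)
  reason[reason == "pass" & n_frac > max_n_frac] <- "n_frac"

  conv <- converted_reference(spec, cpg_as = "Y")
  ref_chars <- strsplit(conv, "", fixed = TRUE)[[1L]]
  idx <- which(reason == "pass")
  if (length(idx) > 0L) {
    fw_len <- nchar(spec$primer_fw)
    rv_len <- nchar(spec$primer_rv)
    fw_ref <- ref_chars[seq_len(fw_len)]
    rv_ref <- ref_chars[(L - rv_len + 1L):L]
    score_anchor <- function(read_part, anchor) {
      rc <- strsplit(read_part, "", fixed = TRUE)[[1L]]
      if (length(rc) < length(anchor)) return(0)
      rc <- rc[seq_along(anchor)]
      ok <- rc == anchor | (anchor == "Y" & rc %in% c("C", "T"))
      mean(ok)
    }
    for (i in idx) {
      r <- reads[i]
      s_fw <- score_anchor(substr(r, 1L, fw_len), fw_ref)
      s_rv <- score_anchor(
        substr(r, max(1L, nchar(r) - rv_len + 1L), nchar(r)), rv_ref)
      if (s_fw < min_primer_score && s_rv < min_primer_score)
        reason[i] <- "primer"
    }
  }
  tab <- table(factor(reason, levels = c("pass", "length", "n_frac", "primer")))
  report <- data.frame(reason = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(pass = reason == "pass", reason = reason, report = report)
}
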