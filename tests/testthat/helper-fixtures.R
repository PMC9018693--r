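# shared fixtures and independent oracles used across test files

# small deterministic amplicon
tiny_spec <- function(k = 2L, len = NULL, seed = 11L) {
  if (is.null(len)) len <- max(60L, 20L * k)
  make_amplicon_spec(k, len, labels = seq_len(k) * 10L - 25L, seed = seed)
}

# the two demo-scale amplicon geometries
spec7 <- function(seed = 1L)
  make_amplicon_spec(7L, 388L, c(-118L, -91L, -47L, -3L, 92L, 112L, 131L),
                     seed = seed)
spec8 <- function(seed = 2L)
  make_amplicon_spec(8L, 403L, c(-227L, -180L, -113L, -71L, -51L, 22L, 89L,
                                 160L), seed = seed)

# error-free mixture over the given epiallele probabilities
clean_mixture <- function(probs, n, seed = 1L) {
  mixture_spec(probs, n, conversion_rate = 1,
               inappropriate_conversion_rate = 0, seq_error_rate = 0,
               seed = seed)
}

# exhaustive R-level overlap-merge oracle (independent of the C++ kernel):
# scans every candidate overlap, scores mismatch fractions with strsplit
merge_oracle <- function(fw, rv_rc, min_overlap = 40L, max_mm = 0.1) {
  a <- strsplit(fw, "")[[1]]; b <- strsplit(rv_rc, "")[[1]]
  na <- length(a); nb <- length(b)
  best <- NULL
  for (o in seq.int(min_overlap, min(na, nb))) {
    mm <- sum(a[(na - o + 1):na] != b[1:o])
    frac <- mm / o
    if (frac <= max_mm) {
      if (is.null(best) || frac < best$frac - 1e-12 ||
          (frac <= best$frac + 1e-12 && o > best$o))
        best <- list(o = o, mm = mm, frac = frac)
    }
  }
  if (is.null(best)) return(NULL)
  list(seq = paste0(fw, substr(rv_rc, best$o + 1, nb)),
       overlap = best$o, mismatches = best$mm)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# random DNA string
rand_dna <- function(n, seed = NULL) {
  f <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# random epiallele count table for property tests
random_table <- function(n_samples = 5L, k = 4L, depth = 200L, seed = 1L) {
  withr::with_seed(seed, {
    eps <- all_epialleles(k)
    counts <- t(stats::rmultinom(n_samples, depth,
                                 prob = stats::runif(length(eps))))
    rownames(counts) <- sprintf("s%02d", seq_len(n_samples))
    colnames(counts) <- eps
    epiallele_table(counts)
  })
}

# analytic push-forward of a truth mixture through the per-CpG read channel:
# conversion (unmethylated C -> T at conv; methylated C -> T at inappr), then
# uniform substitution error, then complete-profile calling (ambiguous CpG
# rejects the read). Returns expected called-profile probabilities.
expected_called_dist <- function(probs, conv, inappr, err) {
  k <- nchar(names(probs)[1])
  # channel per CpG: rows truth bit (0/1), cols called (0, 1, ambiguous)
  ch <- function(b) {
    p_c_after <- if (b == 1L) 1 - inappr else 1 - conv  # base C pre-error
    p_t_after <- 1 - p_c_after
    read_c <- p_c_after * (1 - err) + p_t_after * err / 3
    read_t <- p_t_after * (1 - err) + p_c_after * err / 3
    c(`0` = read_t, `1` = read_c, amb = 1 - read_t - read_c)
  }
  ch0 <- ch(0L); ch1 <- ch(1L)
  eps <- all_epialleles(k)
  out <- stats::setNames(numeric(length(eps)), eps)
  bits_out <- epiallele_bits(eps)
  for (te in names(probs)) {
    tb <- as.integer(strsplit(te, "")[[1]])
    for (j in seq_along(eps)) {
      cb <- bits_out[j, ]
      pr <- 1
      for (i in seq_len(k)) {
        chn <- if (tb[i] == 1L) ch1 else ch0
        pr <- pr * chn[[as.character(cb[i])]]
      }
      out[j] <- out[j] + probs[[te]] * pr
    }
  }
  out / sum(out)  # condition on no ambiguous CpG
}
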