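#' Generate a random amplicon reference with a controlled CpG layout
#'
#' Builds a synthetic top-strand reference of the requested length containing
#' exactly `n_cpgs` CpG dinucleotides at well-separated positions, plus at
#' least `n_cpgs` additional non-CpG cytosines (required for per-read
#' bisulfite-conversion QC), with fixed primer anchors at both ends. The
#' background sequence avoids accidental CpGs and accidental C/G adjacency so
#' the scored CpG set is exactly the requested one.
#'
#' @param n_cpgs Number of CpG sites (1..12).
#' @param length Reference length in bp; must be at least `20 * n_cpgs`.
#' @param labels Integer TSS-relative labels, strictly increasing, one per
#'   CpG.
#' @param seed Integer seed; the spec is deterministic given the seed.
#' @param primer_len Primer anchor length (default 24).
#' @return An [amplicon_spec].
#' @examples
#' sp <- make_amplicon_spec(7, 388, c(-118, -91, -47, -3, 92, 112, 131), seed = 1)
#' n_cpgs(sp)
#' @export
make_amplicon_spec <- function(n_cpgs, length, labels, seed,
                               primer_len = 24L) {
  n_cpgs <- as.integer(n_cpgs)
  length <- as.integer(length)
  if (n_cpgs < 1L || n_cpgs > 12L) stop("n_cpgs must be in 1..12")
  if (length < 20L * n_cpgs)
    stop("impossible geometry: length must be >= 20 * n_cpgs")
  labels <- as.integer(labels)
  if (length(labels) != n_cpgs || any(diff(labels) <= 0L))
    stop("labels must be strictly increasing with one label per CpG")
  withr::with_seed(seed, {
    # space CpGs evenly inside the interior, away from the primer anchors
    lo <- primer_len + 2L
    hi <- length - primer_len - 2L
    pos <- round(seq(lo, hi, length.out = n_cpgs + 2L))[2:(n_cpgs + 1L)]
    pos <- as.integer(pos + sample(-3:3, n_cpgs, replace = TRUE))
    pos <- sort(unique(pmin(pmax(pos, lo), hi)))
    if (length(pos) < n_cpgs) stop("impossible geometry: CpGs cannot be separated")
    # background: no C directly followed by G arises because every background
    # C is immediately followed by A or T
    chars <- character(length)
    bg <- c("A", "T", "G")
    chars[] <- sample(bg, length, replace = TRUE)
    # sprinkle non-CpG cytosines (for conversion QC): C followed by A/T
    n_extra_c <- max(2L * n_cpgs, 8L)
    cand <- setdiff(seq_len(length - 1L), c(pos, pos + 1L, pos - 1L))
    extra_c <- sort(sample(cand, n_extra_c))
    # keep them non-adjacent so a C is never followed by G or by another C
    extra_c <- extra_c[c(TRUE, diff(extra_c) > 1L)]
    chars[extra_c] <- "C"
    chars[extra_c + 1L] <- sample(c("A", "T"), length(extra_c), replace = TRUE)
    # avoid G right before any C (would create a new CpG only if C follows G:
    # GC is fine; CG is what we must control) -- ensure no background C
    # precedes a G
    gpos <- which(chars == "G")
    gpos <- gpos[gpos > 1L]
    bad <- gpos[chars[gpos - 1L] == "C"]
    chars[bad] <- sample(c("A", "T"), length(bad), replace = TRUE)
    # place the scored CpGs
    chars[pos] <- "C"
    chars[pos + 1L] <- "G"
    # make sure the base after each CpG G is not C-with-G etc. (already safe)
    seq <- paste(chars, collapse = "")
    spec <- amplicon_spec(
      name = sprintf("synthetic_%dcpg", n_cpgs),
      reference_seq = seq,
      cpg_offsets = pos,
      cpg_labels = labels,
      primer_len = primer_len)
    if (length(spec$non_cpg_c_offsets) < n_cpgs)
      stop("internal error: too few non-CpG cytosines generated")
    spec
  })
}

#' Ground-truth epiallele mixture for simulation
#'
#' Describes the molecule population of one simulated sample: the epiallele
#' probabilities, how many molecules to draw and the error model of the
#' simulated assay.
#'
#' @param epiallele_probs Named numeric vector; names are binary strings of
#'   equal length `k` (1 = methylated CpG), values sum to 1.
#' @param n_molecules Number of molecules to draw.
#' @param conversion_rate Probability that an unmethylated C is converted
#'   (read as T). Real kits achieve ~0.99+.
#' @param inappropriate_conversion_rate Probability that a methylated CpG C is
#'   erroneously converted (read as T).
#' @param seq_error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(epiallele_probs, n_molecules,
                         conversion_rate = 0.995,
                         inappropriate_conversion_rate = 0.005,
                         seq_error_rate = 0.001,
                         seed = 1L) {
  p <- as.numeric(epiallele_probs)
  nm <- names(epiallele_probs)
  if (is.null(nm)) stop("epiallele_probs must be named by epiallele strings")
  k <- unique(nchar(nm))
  if (length(k) != 1L) stop("all epiallele strings must have the same length")
  if (!all(grepl("^[01]+$", nm))) stop("epiallele strings must be over {0,1}")
  if (abs(sum(p) - 1) > 1e-9) stop("epiallele probabilities must sum to 1")
  if (any(p < 0)) stop("negative probability")
  stopifnot(n_molecules >= 1,
            conversion_rate >= 0, conversion_rate <= 1,
            inappropriate_conversion_rate >= 0,
            inappropriate_conversion_rate <= 1,
            seq_error_rate >= 0, seq_error_rate < 1)
  structure(
    list(epiallele_probs = stats::setNames(p, nm),
         k = as.integer(k),
         n_molecules = as.integer(n_molecules),
         conversion_rate = conversion_rate,
         inappropriate_conversion_rate = inappropriate_conversion_rate,
         seq_error_rate = seq_error_rate,
         seed = as.integer(seed)),
    class = "mixture_spec")
}

#' Product-Bernoulli epiallele mixture
#'
#' Convenience constructor: each CpG is independently methylated with its own
#' probability, giving a full distribution over all `2^k` epialleles.
#'
#' @param p Per-CpG methylation probabilities (recycled to length `k`).
#' @param k Number of CpGs.
#' @return Named probability vector over all `2^k` epialleles (lexicographic
#'   order), suitable for [mixture_spec].
#' @export
bernoulli_mixture <- function(p, k) {
  p <- rep_len(p, k)
  eps <- all_epialleles(k)
  bits <- epiallele_bits(eps)
  pr <- apply(bits, 1L, function(b) prod(ifelse(b == 1L, p, 1 - p)))
  stats::setNames(pr / sum(pr), eps)
}

#' Draw ground-truth molecules from a mixture
#'
#' @param spec An [amplicon_spec]; its CpG count must match the mixture's
#'   string length.
#' @param mix A [mixture_spec].
#' @return Character vector of `n_molecules` epiallele strings (ground
#'   truth). Deterministic given `mix$seed`.
#' @export
sample_molecules <- function(spec, mix) {
  stopifnot(inherits(spec, "amplicon_spec"), inherits(mix, "mixture_spec"))
  if (mix$k != n_cpgs(spec))
    stop("mixture string length does not match the amplicon CpG count")
  withr::with_seed(mix$seed,
    sample(names(mix$epiallele_probs), mix$n_molecules, replace = TRUE,
           prob = mix$epiallele_probs))
}

# Vectorised bisulfite conversion + sequencing error for a set of molecules.
# Works on a raw byte matrix (one column per molecule) for speed; returns the
# full-length converted sequences (character vector).
convert_molecules <- function(molecules, spec, mix) {
  L <- nchar(spec$reference_seq)
  n <- length(molecules)
  if (n == 0L) return(character(0))
  Traw <- charToRaw("T")
  m <- matrix(rep(charToRaw(spec$reference_seq), n), nrow = L, ncol = n)
  ncc <- spec$non_cpg_c_offsets
  if (length(ncc) > 0L) {
    conv <- matrix(stats::runif(length(ncc) * n) < mix$conversion_rate,
                   nrow = length(ncc))
    sub <- m[ncc, , drop = FALSE]
    sub[conv] <- Traw
    m[ncc, ] <- sub
  }
  k <- n_cpgs(spec)
  bits <- epiallele_bits(molecules)           # n x k
  u <- matrix(stats::runif(n * k), nrow = n)  # n x k
  to_t <- t(ifelse(bits == 1L,
                   u < mix$inappropriate_conversion_rate,
                   u < mix$conversion_rate))  # k x n
  sub <- m[spec$cpg_offsets, , drop = FALSE]
  sub[to_t] <- Traw
  m[spec$cpg_offsets, ] <- sub
  if (mix$seq_error_rate > 0) {
    err <- which(stats::runif(L * n) < mix$seq_error_rate)
    if (length(err) > 0L) {
      bases <- charToRaw("ACGT")
      cur <- m[err]
      # substitute with one of the three other bases, uniformly
      repl <- bases[sample.int(4L, length(err), replace = TRUE)]
      clash <- repl == cur
      while (any(clash)) {
        repl[clash] <- bases[sample.int(4L, sum(clash), replace = TRUE)]
        clash <- repl == cur
      }
      m[err] <- repl
    }
  }
  big <- rawToChar(as.vector(m))
  substring(big, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
}

#' Simulate paired bisulfite reads for one sample
#'
#' Draws `n_molecules` ground-truth epialleles from the mixture, applies
#' bisulfite conversion (unmethylated Cs convert to T at `conversion_rate`;
#' methylated CpG Cs convert at `inappropriate_conversion_rate`) and per-base
#' substitution error, then emits a forward read from the 5' end and a
#' reverse-complemented read from the 3' end, both of length
#' `min(read_len, amplicon length)`, so the pair overlaps by at least the
#' merge threshold for amplicons up to `2 * read_len - 40` bp. Only the
#' bisulfite top strand is simulated (directional amplicon design). Quality
#' strings are constant.
#'
#' @param spec An [amplicon_spec].
#' @param mix A [mixture_spec].
#' @param sample_id Sample identifier used in read names.
#' @param read_len Read length (default 251, a 251x2-cycle paired run).
#' @return List with `fw`, `rv` ([Biostrings::DNAStringSet] of the two
#'   mates), `truth` (character vector of ground-truth epialleles, one per
#'   pair) and `sample_id`. Deterministic given `mix$seed`.
#' @export
simulate_bisulfite_reads <- function(spec, mix, sample_id = "sample1",
                                     read_len = 251L) {
  stopifnot(inherits(spec, "amplicon_spec"), inherits(mix, "mixture_spec"))
  L <- nchar(spec$reference_seq)
  rl <- min(as.integer(read_len), L)
  withr::with_seed(mix$seed, {
    molecules <- sample(names(mix$epiallele_probs), mix$n_molecules,
                        replace = TRUE, prob = mix$epiallele_probs)
    seqs <- convert_molecules(molecules, spec, mix)
  })
  fw <- substr(seqs, 1L, rl)
  rv_raw <- substr(seqs, L - rl + 1L, L)
  rv <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rv_raw)))
  ids <- sprintf("%s_read%06d", sample_id, seq_along(seqs))
  fw_set <- Biostrings::DNAStringSet(fw); names(fw_set) <- ids
  rv_set <- Biostrings::DNAStringSet(rv); names(rv_set) <- ids
  list(fw = fw_set, rv = rv_set, truth = molecules, sample_id = sample_id)
}

#' Bisulfite-convert a single molecule and emit one read pair
#'
#' Single-molecule wrapper around the vectorised simulator; useful for
#' constructing exact test cases.
#'
#' @param molecule Epiallele string of length `k`.
#' @param spec An [amplicon_spec].
#' @param mix A [mixture_spec] (its `epiallele_probs`/`n_molecules` are
#'   ignored; only the error model and seed are used).
#' @param read_len Read length.
#' @return List with `fw` and `rv` character reads and the converted
#'   full-length `seq`.
#' @export
bisulfite_convert_and_read <- function(molecule, spec, mix, read_len = 251L) {
  stopifnot(nchar(molecule) == n_cpgs(spec))
  L <- nchar(spec$reference_seq)
  rl <- min(as.integer(read_len), L)
  seq <- withr::with_seed(mix$seed, convert_molecules(molecule, spec, mix))
  fw <- substr(seq, 1L, rl)
  rv <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(seq, L - rl + 1L, L))))
  list(fw = fw, rv = rv, seq = seq)
}

#' Bundled fully unmethylated spike-in control reference
#'
#' A fixed, C-rich synthetic control fragment standing in for the fully
#' unmethylated DNA (classically an unmethylated phage genome fragment)
#' spiked into bisulfite reactions to measure conversion efficiency. Being
#' unmethylated by construction, every C should read as T after complete
#' conversion.
#'
#' @return Character scalar DNA sequence (180 bp, 46 cytosines, no CpG
#'   scoring positions).
#' @export
spikein_reference <- function() {
  paste0(
    "ATTCAGTCAATGCATTCGATCCATAGCTTACCATGACATCGTACATTGCAATCGTTACCA",
    "TGCAATCCATTGACTCAGTACATCGATTCCAATGCATACGTTCAGTCATACCATGCAATC",
    "GATACCATTCGTACATGCAATCCATTACGATCAGTCCATACGATTCAATGCGTACCATTC")
}

#' Simulate spike-in control reads
#'
#' Generates single (already merged) reads of the full spike-in reference
#' with every C independently converted to T at `conversion_rate`, plus
#' optional substitution error.
#'
#' @param n_reads Number of reads (>= 1).
#' @param conversion_rate Conversion probability per C.
#' @param seed Integer seed.
#' @param seq_error_rate Per-base substitution error.
#' @return List with `reads` (a [Biostrings::DNAStringSet]) and `reference`
#'   (the spike-in reference sequence). Deterministic given `seed`.
#' @export
simulate_spikein <- function(n_reads, conversion_rate, seed = 1L,
                             seq_error_rate = 0) {
  stopifnot(n_reads >= 1, conversion_rate >= 0, conversion_rate <= 1)
  ref <- spikein_reference()
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  cpos <- which(chars == "C")
  L <- length(chars)
  withr::with_seed(seed, {
    m <- matrix(rep(charToRaw(ref), n_reads), nrow = L, ncol = n_reads)
    Traw <- charToRaw("T")
    conv <- matrix(stats::runif(length(cpos) * n_reads) < conversion_rate,
                   nrow = length(cpos))
    sub <- m[cpos, , drop = FALSE]
    sub[conv] <- Traw
    m[cpos, ] <- sub
    if (seq_error_rate > 0) {
      err <- which(stats::runif(L * n_reads) < seq_error_rate)
      if (length(err) > 0L) {
        bases <- charToRaw("ACGT")
        cur <- m[err]
        repl <- bases[sample.int(4L, length(err), replace = TRUE)]
        clash <- repl == cur
        while (any(clash)) {
          repl[clash] <- bases[sample.int(4L, sum(clash), replace = TRUE)]
          clash <- repl == cur
        }
        m[err] <- repl
      }
    }
    big <- rawToChar(as.vector(m))
    seqs <- substring(big, (seq_len(n_reads) - 1L) * L + 1L,
                      seq_len(n_reads) * L)
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("spikein_read%05d", seq_len(n_reads))
    list(reads = reads, reference = ref)
  })
}

#' Simulate coupled qPCR expression for a set of samples
#'
#' Generates a long-format Ct table in which the true relative expression is
#' linear in mean methylation: `rel_true = base_expr + coupling * meth`
#' (negative `coupling` makes expression decrease with methylation, the
#' promoter-silencing situation). Target Ct is derived as
#' `mean(housekeeping Ct) - log2(rel_true)` plus Gaussian noise on the Ct
#' scale; housekeeping Ct is constant plus the same noise.
#'
#' @param mean_methylation Named numeric vector (names = sample ids), values
#'   in `[0, 1]`.
#' @param coupling Slope of true expression in methylation (finite; negative
#'   for silencing).
#' @param noise_sd Ct-scale noise standard deviation (cycles, >= 0).
#' @param seed Integer seed.
#' @param transcript Transcript name.
#' @param base_expr Expression at zero methylation (must keep
#'   `base_expr + coupling * meth > 0`).
#' @param ct_housekeeping Housekeeping Ct level (cycles).
#' @param n_housekeeping_rep Housekeeping replicate measurements per sample.
#' @return Long-format `data.frame` with columns `sample_id`, `transcript`,
#'   `ct`, `role` (`"target"` or `"housekeeping"`); feed to
#'   [delta_ct_table()]. Deterministic given `seed`.
#' @export
simulate_expression <- function(mean_methylation, coupling, noise_sd,
                                seed = 1L, transcript = "synthetic_tx",
                                base_expr = 1.0, ct_housekeeping = 20,
                                n_housekeeping_rep = 3L) {
  stopifnot(is.finite(coupling), noise_sd >= 0)
  ids <- names(mean_methylation)
  if (is.null(ids)) ids <- sprintf("sample%02d", seq_along(mean_methylation))
  rel_true <- base_expr + coupling * as.numeric(mean_methylation)
  if (any(rel_true <= 0))
    stop("base_expr + coupling * methylation must stay positive")
  n <- length(ids)
  withr::with_seed(seed, {
    hk <- data.frame(
      sample_id = rep(ids, each = n_housekeeping_rep),
      transcript = transcript,
      ct = ct_housekeeping + stats::rnorm(n * n_housekeeping_rep, 0, noise_sd),
      role = "housekeeping",
      stringsAsFactors = FALSE)
    hk_mean <- tapply(hk$ct, hk$sample_id, mean)[ids]
    tg <- data.frame(
      sample_id = ids,
      transcript = transcript,
      ct = as.numeric(hk_mean) - log2(rel_true) + stats::rnorm(n, 0, noise_sd),
      role = "target",
      stringsAsFactors = FALSE)
    rbind(tg, hk)
  })
}
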