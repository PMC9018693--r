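#' Amplicon reference specification
#'
#' An `amplicon_spec` describes one bisulfite amplicon: the unconverted
#' top-strand reference sequence, the positions of the CpG cytosines that will
#' be scored, TSS-relative display labels for those CpGs, and the primer
#' anchors at either end of the amplicon. All offsets are 1-based positions
#' into `reference_seq` (TSS-relative labels are presentation-layer only and
#' never enter any computation).
#'
#' @param name Amplicon name (e.g. the promoter it covers).
#' @param reference_seq Character scalar, unconverted top-strand DNA
#'   (A/C/G/T).
#' @param cpg_offsets Integer vector, strictly increasing, 1-based positions
#'   of the C of each scored CpG dinucleotide.
#' @param cpg_labels Integer vector of TSS-relative labels, one per CpG
#'   (negative = upstream of the TSS).
#' @param primer_fw,primer_rv Primer anchor sequences. Default: the first and
#'   last `primer_len` bases of `reference_seq` (the reverse anchor is stored
#'   in reference orientation).
#' @param primer_len Length of the default primer anchors.
#'
#' @return An object of class `amplicon_spec`: a list with elements `name`,
#'   `reference_seq`, `cpg_offsets`, `cpg_labels`, `primer_fw`, `primer_rv`
#'   and the derived `non_cpg_c_offsets` (every other C position, used for
#'   per-read conversion QC).
#' @export
amplicon_spec <- function(name, reference_seq, cpg_offsets, cpg_labels,
                          primer_fw = NULL, primer_rv = NULL,
                          primer_len = 24L) {
  stopifnot(is.character(reference_seq), length(reference_seq) == 1L)
  reference_seq <- toupper(reference_seq)
  chars <- strsplit(reference_seq, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("reference_seq must contain only A/C/G/T")
  cpg_offsets <- as.integer(cpg_offsets)
  cpg_labels <- as.integer(cpg_labels)
  if (length(cpg_offsets) != length(cpg_labels))
    stop("cpg_offsets and cpg_labels must have the same length")
  if (length(cpg_offsets) == 0L) stop("at least one CpG is required")
  if (any(diff(cpg_offsets) <= 0L)) stop("cpg_offsets must be strictly increasing")
  if (any(cpg_offsets < 1L) || any(cpg_offsets >= length(chars)))
    stop("cpg_offsets out of range")
  if (!all(chars[cpg_offsets] == "C" & chars[cpg_offsets + 1L] == "G"))
    stop("every cpg_offset must point at the C of a CpG dinucleotide")
  all_c <- which(chars == "C")
  non_cpg_c <- setdiff(all_c, cpg_offsets)
  if (is.null(primer_fw))
    primer_fw <- substr(reference_seq, 1L, min(primer_len, nchar(reference_seq)))
  if (is.null(primer_rv)) {
    n <- nchar(reference_seq)
    primer_rv <- substr(reference_seq, max(1L, n - primer_len + 1L), n)
  }
  structure(
    list(name = name,
         reference_seq = reference_seq,
         cpg_offsets = cpg_offsets,
         cpg_labels = cpg_labels,
         primer_fw = toupper(primer_fw),
         primer_rv = toupper(primer_rv),
         non_cpg_c_offsets = as.integer(non_cpg_c)),
    class = "amplicon_spec")
}

#' Number of scored CpG sites of an amplicon
#' @param spec An `amplicon_spec`.
#' @return Integer, the number of CpG sites (`k`).
#' @export
n_cpgs <- function(spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  length(spec$cpg_offsets)
}

#' Bisulfite-converted reference sequence
#'
#' Returns the in-silico fully converted top strand: every cytosine outside a
#' scored CpG becomes T. Scored CpG cytosines are left as `C` when
#' `cpg_as = "C"`, replaced by the IUPAC ambiguity code `Y` (C or T) when
#' `cpg_as = "Y"` (the form used for alignment and primer matching, where a
#' CpG may legitimately read as either base), or converted to `T` when
#' `cpg_as = "T"` (the fully unmethylated molecule).
#'
#' @param spec An `amplicon_spec`.
#' @param cpg_as One of "Y", "C", "T".
#' @return Character scalar.
#' @export
converted_reference <- function(spec, cpg_as = c("Y", "C", "T")) {
  stopifnot(inherits(spec, "amplicon_spec"))
  cpg_as <- match.arg(cpg_as)
  chars <- strsplit(spec$reference_seq, "", fixed = TRUE)[[1L]]
  chars[spec$non_cpg_c_offsets] <- "T"
  chars[spec$cpg_offsets] <- switch(cpg_as, Y = "Y", C = "C", T = "T")
  paste(chars, collapse = "")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat("<amplicon_spec> ", x$name, "\n", sep = "")
  cat("  length:        ", nchar(x$reference_seq), " bp\n", sep = "")
  cat("  CpG sites:     ", length(x$cpg_offsets),
      " (labels ", paste(x$cpg_labels, collapse = ", "), ")\n", sep = "")
  cat("  non-CpG Cs:    ", length(x$non_cpg_c_offsets),
      " (conversion QC positions)\n", sep = "")
  cat("  primer anchors:", nchar(x$primer_fw), "/", nchar(x$primer_rv),
      " bp\n", sep = "")
  invisible(x)
}

#' Write / read an amplicon specification as a plain config file
#'
#' The on-disk format is YAML with keys `name`, `reference_seq`,
#' `cpg_offsets`, `cpg_labels`, `primer_fw`, `primer_rv`.
#'
#' @param spec An `amplicon_spec`.
#' @param path File path.
#' @return `write_amplicon_spec` returns `path` invisibly;
#'   `read_amplicon_spec` returns an `amplicon_spec`.
#' @export
write_amplicon_spec <- function(spec, path) {
  stopifnot(inherits(spec, "amplicon_spec"))
  yaml::write_yaml(
    list(name = spec$name,
         reference_seq = spec$reference_seq,
         cpg_offsets = spec$cpg_offsets,
         cpg_labels = spec$cpg_labels,
         primer_fw = spec$primer_fw,
         primer_rv = spec$primer_rv),
    path)
  invisible(path)
}

#' @rdname write_amplicon_spec
#' @export
read_amplicon_spec <- function(path) {
  x <- yaml::read_yaml(path)
  amplicon_spec(x$name, x$reference_seq, x$cpg_offsets, x$cpg_labels,
                primer_fw = x$primer_fw, primer_rv = x$primer_rv)
}
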