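#' Read and write FASTQ / FASTA
#'
#' Thin wrappers around Biostrings IO. `write_fastq` writes standard 4-line
#' FASTQ with a constant phred+33 quality character (quality-aware analysis
#' is out of scope for amplicon bisulfite calling, which filters on sequence
#' features).
#'
#' @param x A [Biostrings::DNAStringSet] (named).
#' @param path File path.
#' @param quality_char Constant quality character (default "I", Q40).
#' @return `write_fastq`/`write_fasta` return `path` invisibly; readers
#'   return a [Biostrings::DNAStringSet].
#' @export
write_fastq <- function(x, path, quality_char = "I") {
  stopifnot(methods::is(x, "DNAStringSet"))
  quals <- Biostrings::BStringSet(
    vapply(Biostrings::width(x),
           function(w) strrep(quality_char, w), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @rdname write_fastq
#' @export
write_fasta <- function(x, path) {
  stopifnot(methods::is(x, "DNAStringSet"))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' Convert a FASTQ file to FASTA
#'
#' Identity on record ids and sequences; qualities are dropped and record
#' count and order are preserved.
#'
#' @param in_path Input FASTQ path (or a `DNAStringSet` to convert in
#'   memory).
#' @param out_path Output FASTA path; omit to return the records without
#'   writing.
#' @return The records as a [Biostrings::DNAStringSet], invisibly when
#'   written to a file.
#' @export
fastq_to_fasta <- function(in_path, out_path = NULL) {
  x <- if (methods::is(in_path, "DNAStringSet")) in_path else read_fastq(in_path)
  if (!is.null(out_path)) {
    write_fasta(x, out_path)
    return(invisible(x))
  }
  x
}

#' Read a qPCR Ct table
#'
#' Expects a TSV with columns `sample_id`, `transcript`, `ct`, `role`
#' (`"target"` or `"housekeeping"`).
#'
#' @param path TSV path.
#' @return `data.frame` in the long Ct format.
#' @export
read_ct_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "transcript", "ct", "role")
  if (!all(need %in% names(x)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (!all(x$role %in% c("target", "housekeeping")))
    stop("role must be 'target' or 'housekeeping'")
  x
}

# write a data.frame as TSV (no quotes, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
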