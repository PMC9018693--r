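#' Enumerate the epiallele space
#'
#' All `2^k` binary methylation profiles over `k` CpG sites, in lexicographic
#' order (leftmost character = most 5' CpG; `"1"` = methylated).
#'
#' @param k Number of CpG sites (1..12).
#' @return Character vector of length `2^k`.
#' @examples
#' length(all_epialleles(7))  # 128
#' @export
all_epialleles <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 12L)
  ints <- 0:(2L^k - 1L)
  m <- vapply(seq.int(k - 1L, 0L), function(b) bitwAnd(bitwShiftR(ints, b), 1L),
              integer(length(ints)))
  apply(m, 1L, paste, collapse = "")
}

# binary-string epialleles -> integer matrix (n x k) of 0/1 bits
epiallele_bits <- function(epialleles) {
  k <- unique(nchar(epialleles))
  stopifnot(length(k) == 1L)
  m <- matrix(as.integer(unlist(strsplit(epialleles, "", fixed = TRUE))),
              ncol = k, byrow = TRUE)
  rownames(m) <- NULL
  m
}

#' Epiallele class (number of methylated CpGs)
#'
#' @param epialleles Character vector of binary epiallele strings.
#' @return Integer vector of Hamming weights (class `0` = fully
#'   unmethylated).
#' @export
epiallele_class <- function(epialleles) {
  if (length(epialleles) == 0L) return(integer(0))
  rowSums(epiallele_bits(epialleles))
}
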