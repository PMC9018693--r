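#include <Rcpp.h>
using namespace Rcpp;

// Overlap-merge of paired amplicon reads. For each pair, rv must already be
// reverse-complemented. Every suffix(fw)/prefix(rv) overlap of length o in
// [min_overlap, min(n_fw, n_rv)] is scored by its mismatch fraction; the
// candidate with the smallest fraction (ties: longest overlap) wins provided
// the fraction is <= max_mismatch_frac. Mismatched overlap positions are
// resolved in favour of the forward read, so the consensus is
// fw + rv[o..end]. Rejections are returned as NA, not errors.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector fw, CharacterVector rv_rc,
                     int min_overlap, double max_mismatch_frac) {
  int n = fw.size();
  if (rv_rc.size() != n) stop("fw and rv_rc must have equal length");
  CharacterVector merged(n);
  IntegerVector overlap(n), mismatches(n);
  for (int i = 0; i < n; ++i) {
    if (fw[i] == NA_STRING || rv_rc[i] == NA_STRING) {
      merged[i] = NA_STRING; overlap[i] = NA_INTEGER; mismatches[i] = NA_INTEGER;
      continue;
    }
    const char *a = CHAR(fw[i]);
    const char *b = CHAR(rv_rc[i]);
    int na = LENGTH(fw[i]);
    int nb = LENGTH(rv_rc[i]);
    int omax = na < nb ? na : nb;
    int best_o = -1, best_mm = 0;
    double best_frac = 2.0;
    for (int o = min_overlap; o <= omax; ++o) {
      int allowed = (int)(max_mismatch_frac * o);
      int mm = 0;
      const char *as = a + (na - o);
      bool ok = true;
      for (int j = 0; j < o; ++j) {
        if (as[j] != b[j]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (!ok) continue;
      double frac = (double)mm / o;
      if (frac < best_frac - 1e-12 ||
          (frac <= best_frac + 1e-12 && o > best_o)) {
        best_frac = frac; best_o = o; best_mm = mm;
      }
    }
    if (best_o < 0) {
      merged[i] = NA_STRING; overlap[i] = NA_INTEGER; mismatches[i] = NA_INTEGER;
    } else {
      std::string out(a, na);
      out.append(b + best_o, nb - best_o);
      merged[i] = out;
      overlap[i] = best_o;
      mismatches[i] = best_mm;
    }
  }
  return List::create(_["seq"] = merged, _["overlap"] = overlap,
                      _["mismatches"] = mismatches);
}
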