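#include <Rcpp.h>
using namespace Rcpp;

// Semi-global alignment score: the read is aligned end-to-end, the
// reference contributes a free-floating window (no charge for unaligned
// reference prefix/suffix, interior reference gaps are charged).
// Linear gap penalty; any base outside A/C/G/T (e.g. N) mismatches
// everything, including itself.
static double score_pair(const std::string &read, const std::string &ref,
                         double match, double mismatch, double gap) {
  const int n = read.size(), m = ref.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = 0.0;  // free start anywhere in ref
  for (int i = 1; i <= n; ++i) {
    cur[0] = gap * i;                           // read must be consumed
    const char rc = read[i - 1];
    const bool rc_ok = (rc == 'A' || rc == 'C' || rc == 'G' || rc == 'T');
    for (int j = 1; j <= m; ++j) {
      const char sc = ref[j - 1];
      const bool hit = rc_ok && rc == sc;
      double best = prev[j - 1] + (hit ? match : mismatch);
      const double del = prev[j] + gap;   // gap in reference (read base skipped)
      const double ins = cur[j - 1] + gap; // gap in read (ref base skipped)
      if (del > best) best = del;
      if (ins > best) best = ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  double out = prev[0];
  for (int j = 1; j <= m; ++j) if (prev[j] > out) out = prev[j];
  return out;
}

// [[Rcpp::export(name = ".semiglobal_scores")]]
NumericVector semiglobal_scores(CharacterVector reads, std::string ref,
                                double match = 1.0, double mismatch = -1.0,
                                double gap = -2.0) {
  const int n = reads.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = score_pair(as<std::string>(reads[i]), ref, match, mismatch, gap);
  }
  return out;
}
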