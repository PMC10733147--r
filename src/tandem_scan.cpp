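#include <Rcpp.h>
using namespace Rcpp;

// Per-period self-match scan for tandem arrays.
//
// For each period p in 1..max_period a position i (0-based, i >= p) "matches"
// when seq[i] == seq[i - p].  Maximal scoring segments (match +match_weight,
// mismatch -mismatch_penalty, Kadane-style: a segment is emitted at its best
// prefix whenever the running score falls to zero, and scanning resumes after
// it) are reported when the best score reaches min_score, the purity
// (matches / span) reaches min_purity and the segment spans at least one
// period.  A span [a..b] over match indices corresponds to the repeat region
// [a - p, b + 1) in sequence coordinates (the first unit is included).
// Harmonic suppression (a p-periodic array is also np-periodic) is done by
// the R caller.
//
// seq is an integer encoding of the sequence; any coding works as long as
// equal bases share a code.  N/ambiguous bases should be given a unique
// negative code per position so they never match.
// [[Rcpp::export]]
DataFrame tandem_scan_cpp(IntegerVector seq, int max_period,
                          double match_weight, double mismatch_penalty,
                          double min_score, double min_purity) {
  int n = seq.size();
  const int* s = seq.begin();
  std::vector<int> r_start, r_end, r_period, r_matches, r_span;
  std::vector<double> r_score;

  int pmax = std::min(max_period, n / 2);
  for (int p = 1; p <= pmax; ++p) {
    int seg_start = -1, best_end = -1, best_matches = 0, matches_run = 0;
    double run = 0.0, best = 0.0;
    auto emit = [&](void) {
      if (seg_start >= 0 && best_end >= seg_start && best >= min_score) {
        int span = best_end - seg_start + 1;
        double purity = (double)best_matches / span;
        if (purity >= min_purity && span >= p) {
          r_start.push_back(seg_start - p);
          r_end.push_back(best_end + 1);
          r_period.push_back(p);
          r_matches.push_back(best_matches);
          r_span.push_back(span);
          r_score.push_back(best);
        }
      }
    };
    for (int i = p; i < n; ++i) {
      bool m = (s[i] == s[i - p]);
      if (seg_start < 0) {
        if (!m) continue;
        seg_start = i;
        run = 0.0; best = 0.0; best_end = -1;
        matches_run = 0; best_matches = 0;
      }
      if (m) {
        run += match_weight;
        ++matches_run;
      } else {
        run -= mismatch_penalty;
      }
      if (run > best) {
        best = run;
        best_end = i;
        best_matches = matches_run;
      }
      if (run <= 0.0) {
        emit();
        seg_start = -1;
      }
    }
    emit();
  }

  return DataFrame::create(
    _["start"] = r_start, _["end"] = r_end, _["period"] = r_period,
    _["matches"] = r_matches, _["span"] = r_span, _["score"] = r_score);
}
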