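#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped offset alignment of each read against each catalog entry.
// The distance of one read/entry pair at one offset is the number of read
// positions that either mismatch the entry or hang off its ends (read-side
// overhang counts as mismatches; entry-side overhang is free). For each read
// the minimum distance over all entries and offsets is reported together
// with the first entry (in input order) achieving it, so callers control the
// tie order by pre-sorting the catalog.

// [[Rcpp::export(name = ".offset_distance_best")]]
IntegerMatrix offset_distance_best(CharacterVector reads,
                                   CharacterVector entries) {
  const int nr = reads.size(), ne = entries.size();
  std::vector<std::string> es(ne);
  for (int j = 0; j < ne; ++j) es[j] = as<std::string>(entries[j]);
  IntegerMatrix out(nr, 2); // col 0: best entry (1-based, 0 = none), col 1: dist
  for (int i = 0; i < nr; ++i) {
    std::string r = as<std::string>(reads[i]);
    const int rl = (int) r.size();
    int best = rl + 1, best_j = 0;
    for (int j = 0; j < ne; ++j) {
      const std::string &e = es[j];
      const int el = (int) e.size();
      for (int o = -(rl - 1); o <= el - 1; ++o) {
        int matches = 0;
        const int lo = std::max(0, -o), hi = std::min(rl, el - o);
        for (int p = lo; p < hi; ++p)
          if (r[p] == e[p + o]) ++matches;
        const int d = rl - matches;
        if (d < best) { best = d; best_j = j + 1; }
      }
    }
    out(i, 0) = best_j;
    out(i, 1) = best;
  }
  return out;
}
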