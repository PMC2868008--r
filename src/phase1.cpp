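#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Starting-point search: every subsequence of the data seeds a starting
// motif model (probability beta on the word letter, the rest spread evenly).
// Under such a model the likelihood of any candidate site depends only on
// the number of positions where the site letters match the word, so windows
// are packed into 64-bit codes and match counts obtained by XOR + popcount.
// For each word, sites are ranked by likelihood x prior (the best site per
// sequence), and the top-t site sets are scored by the weighted LLR; the
// best word per t is returned.

static inline int field_mismatches(uint64_t z, int bits, uint64_t lowmask) {
  for (int s = 1; s < bits; s <<= 1) z |= z >> s;
  return __builtin_popcountll(z & lowmask);
}

// [[Rcpp::export]]
List cpp_phase1(IntegerVector x,        // concatenated letters, 1-based, NA for mask
                IntegerVector off,      // 0-based sequence offsets
                IntegerVector len,
                int w,
                int asize,
                NumericVector prior,    // effective site prior per global position
                NumericVector weight,   // per-position LLR weight b_{i,j}
                NumericVector p,        // zero-order background marginals
                double beta,
                bool oops,
                IntegerVector tsched,   // ascending; OOPS: single entry
                bool both,
                IntegerVector comp) {   // 1-based complement map (DNA)
  const int n = off.size();
  int bits = 1;
  while ((1 << bits) < asize) ++bits;
  const int capacity = 64 / bits;
  if (w > capacity) stop("phase 1 supports widths up to %d for this alphabet", capacity);
  uint64_t lowmask = 0;
  for (int k = 0; k < w; ++k) lowmask |= (uint64_t)1 << (k * bits);

  // enumerate valid sites (window inside sequence, no mask, prior > 0),
  // ordered by (sequence, position, + strand before -)
  std::vector<uint64_t> scode;
  std::vector<int> sseq, sg, sstrand;
  std::vector<double> spr, swt;
  // words: all mask-free forward windows; wkey is a strand-canonical code
  // (min of the word's code and its reverse complement's) used to break
  // score ties so that mirrored inputs elect mirrored winners
  std::vector<uint64_t> wcode, wkey;
  std::vector<int> wg;

  for (int i = 0; i < n; ++i) {
    const int L = len[i];
    for (int j = 0; j + w <= L; ++j) {
      const int g = off[i] + j;
      bool okwin = true;
      for (int k = 0; k < w; ++k)
        if (x[g + k] == NA_INTEGER) { okwin = false; break; }
      if (!okwin) continue;
      uint64_t cf = 0, cr = 0;
      for (int k = 0; k < w; ++k) {
        cf |= (uint64_t)(x[g + k] - 1) << (k * bits);
        if (both) cr |= (uint64_t)(comp[x[g + w - 1 - k] - 1] - 1) << (k * bits);
      }
      wcode.push_back(cf); wg.push_back(g);
      wkey.push_back(both ? std::min(cf, cr) : cf);
      const double pr = prior[g];
      if (pr > 0) {
        scode.push_back(cf); sseq.push_back(i); sg.push_back(g);
        sstrand.push_back(0); spr.push_back(pr); swt.push_back(weight[g]);
        if (both) {
          // re-scan for mask needed? same window, already mask-free
          scode.push_back(cr); sseq.push_back(i); sg.push_back(g);
          sstrand.push_back(1); spr.push_back(pr); swt.push_back(weight[g]);
        }
      }
    }
  }
  const int nsite = (int)scode.size();
  const int nword = (int)wcode.size();
  if (nsite == 0) stop("no legal sites: every position has zero prior mass");
  if (nword == 0) stop("no starting words: every window contains masked residues");

  // likelihood of a site with m matching positions
  std::vector<double> matchlik(w + 1);
  const double mis = (1.0 - beta) / (asize - 1);
  for (int m = 0; m <= w; ++m)
    matchlik[m] = std::pow(beta, m) * std::pow(mis, w - m);

  const int nt = tsched.size();
  std::vector<double> best_score(nt, R_NegInf);
  std::vector<uint64_t> best_key(nt, ~(uint64_t)0);
  std::vector<int> best_word(nt, -1), best_nsel(nt, 0);
  const double tie_tol = 1e-8;

  std::vector<double> bpost(n);
  std::vector<int> bsite(n);
  std::vector<int> sel;  sel.reserve(n);
  std::vector<int> order(n);
  std::vector<double> counts((size_t)asize * w);
  const double log2e = 1.0 / std::log(2.0);

  for (int wi = 0; wi < nword; ++wi) {
    const uint64_t wc = wcode[wi];
    std::fill(bpost.begin(), bpost.end(), 0.0);
    std::fill(bsite.begin(), bsite.end(), -1);
    for (int s = 0; s < nsite; ++s) {
      const int m = w - field_mismatches(wc ^ scode[s], bits, lowmask);
      const double post = matchlik[m] * spr[s];
      const int i = sseq[s];
      if (post > bpost[i]) { bpost[i] = post; bsite[i] = s; }
    }
    sel.clear();
    for (int i = 0; i < n; ++i) if (bsite[i] >= 0) sel.push_back(i);
    const int nsel = (int)sel.size();
    if (nsel == 0) continue;

    if (!oops) {
      // sort selected sequences by posterior descending; ties by site order
      order.assign(sel.begin(), sel.end());
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        if (bpost[a] != bpost[b]) return bpost[a] > bpost[b];
        return bsite[a] < bsite[b];
      });
    } else {
      order.assign(sel.begin(), sel.end());
    }

    std::fill(counts.begin(), counts.end(), 0.0);
    double nwt = 0.0;
    int ti = 0;
    while (ti < nt && tsched[ti] < 1) ++ti;
    const int tmax = oops ? nsel : std::min(nsel, tsched[nt - 1]);
    for (int r = 0; r < tmax; ++r) {
      const int s = bsite[order[r]];
      const int g = sg[s];
      const double b = swt[s];
      if (sstrand[s] == 0) {
        for (int k = 0; k < w; ++k) counts[(size_t)k * asize + (x[g + k] - 1)] += b;
      } else {
        for (int k = 0; k < w; ++k)
          counts[(size_t)k * asize + (comp[x[g + w - 1 - k] - 1] - 1)] += b;
      }
      nwt += b;
      const int t_now = r + 1;
      bool score_now = false;
      if (oops) score_now = (t_now == tmax);
      else {
        while (ti < nt && tsched[ti] < t_now) ++ti;
        score_now = (ti < nt && tsched[ti] == t_now) || (t_now == tmax);
      }
      if (!score_now || nwt <= 0) continue;
      double llr = 0.0;
      for (int k = 0; k < w; ++k)
        for (int a = 0; a < asize; ++a) {
          const double c = counts[(size_t)k * asize + a];
          if (c > 0) llr += c * std::log(c / (nwt * p[a])) * log2e;
        }
      const int slot = oops ? 0 : ti;
      const double tol = tie_tol * (1.0 + std::fabs(best_score[slot]));
      if (llr > best_score[slot] + tol ||
          (llr > best_score[slot] - tol && wkey[wi] < best_key[slot])) {
        if (llr > best_score[slot]) best_score[slot] = llr;
        best_key[slot] = wkey[wi];
        best_word[slot] = wi;
        best_nsel[slot] = t_now;
      }
    }
  }

  IntegerVector out_word(nt), out_nsel(nt), out_t(nt);
  NumericVector out_score(nt);
  for (int ti = 0; ti < nt; ++ti) {
    out_t[ti] = tsched[ti];
    out_word[ti] = best_word[ti] >= 0 ? wg[best_word[ti]] + 1 : NA_INTEGER; // 1-based global
    out_nsel[ti] = best_nsel[ti];
    out_score[ti] = best_word[ti] >= 0 ? best_score[ti] : NA_REAL;
  }
  return List::create(_["t"] = out_t, _["word_g"] = out_word,
                      _["score"] = out_score, _["nsites"] = out_nsel);
}
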