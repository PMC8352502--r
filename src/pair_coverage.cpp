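#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Brute-force pair co-occurrence counter. Consumes only the emitted member
// lists (1-based individual indices, sorted within each subset), never the
// generating matrices, so it is an implementation-independent oracle for
// the exact-once property.
//
// For each individual i, every subset containing i is walked from the first
// member greater than i (members are sorted), so each unordered pair is
// touched exactly as often as it co-occurs. The fast path marks partners in
// an epoch array (epoch = i, no per-i reset); as long as no partner repeats,
// all those pairs have t = 1. A repeated partner (t >= 2, i.e. a coverage
// violation) triggers an exact recount for that i. Memory stays
// O(n + total membership); the n(n-1)/2 pairs are never materialized.
//
// [[Rcpp::export(name = ".pair_coverage_core")]]
List pair_coverage_core(List subsets, int n, int max_offenders) {
  if (n < 1) stop("n must be positive");
  const R_xlen_t S = subsets.size();

  // flatten subsets into CSR form, checking range and sortedness
  long long total = 0;
  for (R_xlen_t s = 0; s < S; ++s) {
    IntegerVector v(subsets[s]);
    total += v.size();
  }
  std::vector<long long> sub_off(S + 1, 0);
  std::vector<int> flat;
  flat.reserve((size_t) total);
  std::vector<long long> mem_count((size_t) n + 1, 0);
  for (R_xlen_t s = 0; s < S; ++s) {
    IntegerVector v(subsets[s]);
    int prev = 0;
    for (int x : v) {
      if (x == NA_INTEGER || x < 1 || x > n)
        stop("subset member out of range 1..n");
      if (x <= prev)
        stop("subset members must be sorted and distinct");
      prev = x;
      flat.push_back(x);
      mem_count[(size_t) x]++;
    }
    sub_off[s + 1] = sub_off[s] + v.size();
  }

  // membership lists (individual -> subsets containing it), CSR form
  std::vector<long long> mem_off((size_t) n + 2, 0);
  for (int i = 1; i <= n; ++i)
    mem_off[(size_t) i + 1] = mem_off[(size_t) i] + mem_count[(size_t) i];
  std::vector<int> mem_list((size_t) total);
  {
    std::vector<long long> cursor(mem_off.begin(), mem_off.end() - 1);
    for (R_xlen_t s = 0; s < S; ++s) {
      for (long long q = sub_off[s]; q < sub_off[s + 1]; ++q) {
        int x = flat[(size_t) q];
        mem_list[(size_t) cursor[(size_t) x]++] = (int) s;
      }
    }
  }

  std::vector<long long> hist(2, 0);  // hist[t]; grows on demand
  std::vector<int> seen((size_t) n + 1, 0);   // epoch array, epoch = i
  std::vector<int> cnt;                       // slow-path counter (lazy)
  std::vector<int> touched;
  std::vector<int> off_i, off_j, off_t;
  long long n_offending = 0;

  auto record = [&](int i, int j, int t) {
    if ((long long) off_i.size() < max_offenders) {
      off_i.push_back(i); off_j.push_back(j); off_t.push_back(t);
    }
  };

  for (int i = 1; i <= n; ++i) {
    if ((i & 4095) == 0) Rcpp::checkUserInterrupt();
    long long n_gt = 0;
    bool dup = false;
    for (long long q = mem_off[(size_t) i];
         q < mem_off[(size_t) i + 1] && !dup; ++q) {
      int s = mem_list[(size_t) q];
      const int *lo = flat.data() + sub_off[s];
      const int *hi = flat.data() + sub_off[s + 1];
      for (const int *w = std::upper_bound(lo, hi, i); w != hi; ++w) {
        int j = *w;
        if (seen[(size_t) j] == i) { dup = true; break; }
        seen[(size_t) j] = i;
        ++n_gt;
      }
    }
    if (!dup) {
      hist[1] += n_gt;
      long long zeros = (long long) (n - i) - n_gt;
      if (zeros > 0) {
        hist[0] += zeros;
        n_offending += zeros;
        for (int j = i + 1;
             j <= n && (long long) off_i.size() < max_offenders; ++j) {
          if (seen[(size_t) j] != i) record(i, j, 0);
        }
      }
      continue;
    }
    // slow path: exact recount of t(i, j) for all j > i
    if (cnt.empty()) cnt.assign((size_t) n + 1, 0);
    touched.clear();
    for (long long q = mem_off[(size_t) i]; q < mem_off[(size_t) i + 1]; ++q) {
      int s = mem_list[(size_t) q];
      const int *lo = flat.data() + sub_off[s];
      const int *hi = flat.data() + sub_off[s + 1];
      for (const int *w = std::upper_bound(lo, hi, i); w != hi; ++w) {
        int j = *w;
        if (cnt[(size_t) j]++ == 0) touched.push_back(j);
      }
    }
    for (int j : touched) {
      int t = cnt[(size_t) j];
      if ((size_t) t >= hist.size()) hist.resize((size_t) t + 1, 0);
      hist[(size_t) t]++;
      if (t != 1) { n_offending++; record(i, j, t); }
    }
    long long zeros = (long long) (n - i) - (long long) touched.size();
    if (zeros > 0) {
      hist[0] += zeros;
      n_offending += zeros;
      for (int j = i + 1;
           j <= n && (long long) off_i.size() < max_offenders; ++j) {
        if (cnt[(size_t) j] == 0) record(i, j, 0);
      }
    }
    for (int j : touched) cnt[(size_t) j] = 0;
  }

  std::vector<int> t_vals;
  std::vector<double> t_counts;
  for (size_t t = 0; t < hist.size(); ++t) {
    if (hist[t] > 0) {
      t_vals.push_back((int) t);
      t_counts.push_back((double) hist[t]);
    }
  }

  return List::create(
    _["t"] = wrap(t_vals),
    _["count"] = wrap(t_counts),
    _["n_offending"] = (double) n_offending,
    _["off_i"] = wrap(off_i),
    _["off_j"] = wrap(off_j),
    _["off_t"] = wrap(off_t));
}
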