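#include <Rcpp.h>
#include <algorithm>
#include <deque>
using namespace Rcpp;

// van Herk/Gil-Werman running extreme over a centered window of half-width h
// (edge-truncated, matching a flat structuring element that is clipped at
// the spectrum ends)
static NumericVector run_ext(const NumericVector& y, int h, bool take_min) {
  const int n = y.size();
  NumericVector out(n);
  // simple two-pass: prefix extremes within blocks of size w = 2h+1
  // edge truncation makes the block trick fiddly; O(n log h) via deque is
  // simplest and fast enough
  std::deque<int> dq;
  auto better = [&](double a, double b) { return take_min ? a <= b : a >= b; };
  int left = 0;
  for (int i = 0; i < n + h; ++i) {
    if (i < n) {
      while (!dq.empty() && better(y[i], y[dq.back()])) dq.pop_back();
      dq.push_back(i);
    }
    int center = i - h; // window [center-h, center+h]
    if (center >= 0 && center < n) {
      while (dq.front() < center - h) dq.pop_front();
      out[center] = y[dq.front()];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".run_min")]]
NumericVector run_min(NumericVector y, int h) { return run_ext(y, h, true); }

// [[Rcpp::export(name = ".run_max")]]
NumericVector run_max(NumericVector y, int h) { return run_ext(y, h, false); }
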