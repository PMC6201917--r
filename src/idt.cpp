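#include <Rcpp.h>
using namespace Rcpp;

// Dispersion-threshold (I-DT) fixation identification on a cleaned sample
// stream (valid samples only, sorted by time, finite coordinates).
//
// Window semantics, shared with the brute-force oracle used in the tests:
//   * a window [i..j] is coherent iff every between-sample gap inside it is
//     <= max_gap and (max_x - min_x) + (max_y
//     - min_y) <= dispersion;
//   * scanning left to right, the minimal window starting at i that spans
//     min_duration is tested; if coherent it is expanded to the maximal
//     coherent window and emitted, and the scan resumes after it;
//   * otherwise the start advances by one sample.
// Because dispersion and gap violations are monotone in the window end,
// this is equivalent to emitting, greedily from the left, every maximal
// coherent window that spans at least min_duration.
// [[Rcpp::export(name = ".idt_cpp")]]
DataFrame idt_cpp(NumericVector t, NumericVector x, NumericVector y,
                  double dispersion, double min_duration, double max_gap) {
  int n = t.size();
  std::vector<double> t_start, dur, cx, cy;
  std::vector<int> nsamp;
  int i = 0;
  while (i < n) {
    int j = i;
    bool ok = true;
    while (t[j] - t[i] < min_duration) {
      if (j + 1 >= n || t[j + 1] - t[j] > max_gap) { ok = false; break; }
      ++j;
    }
    if (ok) {
      double xmin = x[i], xmax = x[i], ymin = y[i], ymax = y[i];
      for (int k = i + 1; k <= j; ++k) {
        if (x[k] < xmin) xmin = x[k];
        if (x[k] > xmax) xmax = x[k];
        if (y[k] < ymin) ymin = y[k];
        if (y[k] > ymax) ymax = y[k];
      }
      if ((xmax - xmin) + (ymax - ymin) <= dispersion) {
        while (j + 1 < n && t[j + 1] - t[j] <= max_gap) {
          double nxmin = std::min(xmin, x[j + 1]);
          double nxmax = std::max(xmax, x[j + 1]);
          double nymin = std::min(ymin, y[j + 1]);
          double nymax = std::max(ymax, y[j + 1]);
          if ((nxmax - nxmin) + (nymax - nymin) > dispersion) break;
          xmin = nxmin; xmax = nxmax; ymin = nymin; ymax = nymax;
          ++j;
        }
        double sx = 0.0, sy = 0.0;
        for (int k = i; k <= j; ++k) { sx += x[k]; sy += y[k]; }
        int m = j - i + 1;
        t_start.push_back(t[i]);
        dur.push_back(t[j] - t[i]);
        cx.push_back(sx / m);
        cy.push_back(sy / m);
        nsamp.push_back(m);
        i = j + 1;
        continue;
      }
    }
    ++i;
  }
  return DataFrame::create(_["t_start"] = t_start,
                           _["duration"] = dur,
                           _["cx"] = cx,
                           _["cy"] = cy,
                           _["n_samples"] = nsamp);
}
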