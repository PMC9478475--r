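#include <Rcpp.h>
using namespace Rcpp;

// Cascade of time-varying second-order resonators driven by an excitation
// signal: the source-filter core of the vowel synthesizer. Formant centre
// frequencies are given per sample (Hz); bandwidths are fixed per resonator.
// Each section is the standard two-pole resonator
//   y[n] = A x[n] + B y[n-1] + C y[n-2],
//   C = -exp(-2 pi bw / fs), B = 2 exp(-pi bw / fs) cos(2 pi f / fs),
//   A = 1 - B - C  (unity gain at DC).
// [[Rcpp::export(name = ".deresonate_cascade")]]
NumericVector deresonate_cascade(NumericVector input, NumericMatrix freqs,
                                 NumericVector bandwidths, double fs) {
  // inverse (FIR) counterpart: x[n] = (y[n] - B y[n-1] - C y[n-2]) / A
  int n = input.size();
  int nf = freqs.ncol();
  if (freqs.nrow() != n) stop("freqs must have one row per sample");
  if (bandwidths.size() != nf) stop("one bandwidth per formant required");
  NumericVector x = clone(input);
  for (int k = 0; k < nf; ++k) {
    double r = std::exp(-M_PI * bandwidths[k] / fs);
    double c2 = -r * r;
    double y1 = 0.0, y2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double b1 = 2.0 * r * std::cos(2.0 * M_PI * freqs(i, k) / fs);
      double a0 = 1.0 - b1 - c2;
      double yi = x[i];
      x[i] = (yi - b1 * y1 - c2 * y2) / a0;
      y2 = y1;
      y1 = yi;
    }
  }
  return x;
}

// [[Rcpp::export(name = ".resonate_cascade")]]
NumericVector resonate_cascade(NumericVector source, NumericMatrix freqs,
                               NumericVector bandwidths, double fs) {
  int n = source.size();
  int nf = freqs.ncol();
  if (freqs.nrow() != n) stop("freqs must have one row per sample");
  if (bandwidths.size() != nf) stop("one bandwidth per formant required");
  NumericVector x = clone(source);
  for (int k = 0; k < nf; ++k) {
    double r = std::exp(-M_PI * bandwidths[k] / fs);
    double c2 = -r * r;
    double y1 = 0.0, y2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double b1 = 2.0 * r * std::cos(2.0 * M_PI * freqs(i, k) / fs);
      double a0 = 1.0 - b1 - c2;
      double y = a0 * x[i] + b1 * y1 + c2 * y2;
      y2 = y1;
      y1 = y;
      x[i] = y;
    }
  }
  return x;
}
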