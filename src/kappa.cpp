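#include <Rcpp.h>
using namespace Rcpp;

// Window charge-asymmetry machinery for the kappa patterning parameter.
// sigma(window) = NCPR^2 / FCR computed on every length-g window; delta_g is
// the mean squared deviation of window sigma from the full-sequence sigma.

static double sigma_of(int pos, int neg, int len) {
  double fp = (double)pos / len, fm = (double)neg / len;
  double fcr = fp + fm;
  if (fcr == 0.0) return 0.0;
  double ncpr = fp - fm;
  return ncpr * ncpr / fcr;
}

// charges: vector of +1 / -1 / 0 per residue
// [[Rcpp::export]]
double delta_blob_cpp(IntegerVector charges, int g) {
  int n = charges.size();
  if (n < g) stop("sequence shorter than blob size");
  int tot_pos = 0, tot_neg = 0;
  for (int i = 0; i < n; ++i) {
    if (charges[i] > 0) ++tot_pos;
    else if (charges[i] < 0) ++tot_neg;
  }
  double sig = sigma_of(tot_pos, tot_neg, n);
  int pos = 0, neg = 0;
  for (int i = 0; i < g; ++i) {
    if (charges[i] > 0) ++pos; else if (charges[i] < 0) ++neg;
  }
  double acc = 0.0;
  int nw = n - g + 1;
  for (int i = 0;; ++i) {
    double d = sigma_of(pos, neg, g) - sig;
    acc += d * d;
    if (i == nw - 1) break;
    if (charges[i] > 0) --pos; else if (charges[i] < 0) --neg;
    if (charges[i + g] > 0) ++pos; else if (charges[i + g] < 0) ++neg;
  }
  return acc / nw;
}

// Deterministic delta_max construction: maximize delta over the family
//   0^o1  A^i  0^a  B^nB  0^b  A^(nA-i)  0^o2
// for both assignments of (A, B) to (+, -), all splits i of the A block and
// all compositions of the neutral count over the four gaps. Validated
// exhaustively against full enumeration for short sequences.
// [[Rcpp::export]]
double delta_max_cpp(int npos, int nneg, int nneu, int g) {
  int n = npos + nneg + nneu;
  if (n < g) stop("sequence shorter than blob size");
  std::vector<int> ch(n);
  double best = -1.0;
  for (int which = 0; which < 2; ++which) {
    int qa = which == 0 ? 1 : -1;
    int qb = -qa;
    int nA = qa == 1 ? npos : nneg;
    int nB = qa == 1 ? nneg : npos;
    for (int i = 0; i <= nA; ++i) {
      for (int o1 = 0; o1 <= nneu; ++o1) {
        for (int a = 0; a + o1 <= nneu; ++a) {
          for (int b = 0; a + b + o1 <= nneu; ++b) {
            int o2 = nneu - o1 - a - b;
            int k = 0;
            for (int j = 0; j < o1; ++j) ch[k++] = 0;
            for (int j = 0; j < i; ++j) ch[k++] = qa;
            for (int j = 0; j < a; ++j) ch[k++] = 0;
            for (int j = 0; j < nB; ++j) ch[k++] = qb;
            for (int j = 0; j < b; ++j) ch[k++] = 0;
            for (int j = 0; j < nA - i; ++j) ch[k++] = qa;
            for (int j = 0; j < o2; ++j) ch[k++] = 0;
            // inline delta on ch
            double sig = sigma_of(npos, nneg, n);
            int pos = 0, neg = 0;
            for (int j = 0; j < g; ++j) {
              if (ch[j] > 0) ++pos; else if (ch[j] < 0) ++neg;
            }
            double acc = 0.0;
            int nw = n - g + 1;
            for (int w = 0;; ++w) {
              double d = sigma_of(pos, neg, g) - sig;
              acc += d * d;
              if (w == nw - 1) break;
              if (ch[w] > 0) --pos; else if (ch[w] < 0) --neg;
              if (ch[w + g] > 0) ++pos; else if (ch[w + g] < 0) ++neg;
            }
            double delta = acc / nw;
            if (delta > best) best = delta;
          }
        }
      }
    }
  }
  return best;
}
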