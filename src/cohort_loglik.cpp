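#include <Rcpp.h>
using namespace Rcpp;

// Cohort log-likelihood of the asymmetric-learning-rate softmax model,
// vectorized across participants. Mirrors the R reference implementation
// session_log_likelihood() trial by trial; equality of the two routes is
// asserted in the test suite.
//
// raw: N x 3 unconstrained parameters (probit scale)
// ch:  N x Tmax choices (1 = A, 2 = B, NA padding for ragged sessions)
// out: N x Tmax outcomes (+1 / -1)
// resp: N x Tmax responded flags
// nt:  trials per participant
// [[Rcpp::export(name = ".cohort_loglik_cpp")]]
NumericVector cohort_loglik_cpp(NumericMatrix raw, IntegerMatrix ch,
                                NumericMatrix out, LogicalMatrix resp,
                                IntegerVector nt, double beta_max,
                                bool censor, double p_floor) {
  const int n = raw.nrow();
  NumericVector ll(n);
  for (int i = 0; i < n; ++i) {
    const double ap = R::pnorm(raw(i, 0), 0.0, 1.0, 1, 0);
    const double an = R::pnorm(raw(i, 1), 0.0, 1.0, 1, 0);
    const double bt = beta_max * R::pnorm(raw(i, 2), 0.0, 1.0, 1, 0);
    double ev_a = 0.0, ev_b = 0.0, acc = 0.0;
    const int ti = nt[i];
    for (int t = 0; t < ti; ++t) {
      const double p_a = 1.0 / (1.0 + std::exp(-bt * (ev_a - ev_b)));
      const bool chose_a = ch(i, t) == 1;
      if (!censor || resp(i, t)) {
        double p_ch = chose_a ? p_a : 1.0 - p_a;
        if (p_ch < p_floor) p_ch = p_floor;
        acc += std::log(p_ch);
      }
      const double ev_ch = chose_a ? ev_a : ev_b;
      const double pe = out(i, t) - ev_ch;
      const double lr = pe > 0 ? ap : an;
      if (chose_a) ev_a += lr * pe; else ev_b += lr * pe;
    }
    ll[i] = acc;
  }
  return ll;
}
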