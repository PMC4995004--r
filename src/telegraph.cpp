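#include <Rcpp.h>
using namespace Rcpp;

// Stationary distribution of the two-state promoter model:
//   P(x) = [Gamma(kon+x) Gamma(kon+koff) kt^x] /
//          [Gamma(x+1) Gamma(kon+koff+x) Gamma(kon)] * 1F1(kon+x, kon+koff+x, -kt)
// Evaluated in log space. Kummer's transformation gives
//   1F1(kon+x, b, -kt) = exp(-kt) * 1F1(koff, b, kt),  b = kon+koff+x,
// and the transformed series has all-positive terms, so it can be summed by the
// term-ratio recurrence with no cancellation.  A running rescale keeps the
// partial sum inside double range (kt up to ~600 is routine when simulating).
static double log_kummer_series(double koff, double b, double kt) {
  // log of 1F1(koff, b, kt), kt >= 0, b > 0, koff >= 0
  if (kt == 0.0 || koff == 0.0) return 0.0;
  double t = 1.0, S = 1.0, logscale = 0.0;
  const int nmax = 1000000;
  for (int n = 0; n < nmax; ++n) {
    t *= (koff + n) * kt / ((b + n) * (n + 1.0));
    S += t;
    if (t < S * 1e-17 && n > kt) break;
    if (S > 1e280) { logscale += std::log(S); t /= S; S = 1.0; }
  }
  return logscale + std::log(S);
}

static void check_params(double kon, double koff, double kt) {
  if (!R_finite(kon) || !R_finite(koff) || !R_finite(kt) ||
      kon < 0.0 || koff < 0.0 || kt < 0.0)
    stop("kinetic parameters must be finite and non-negative");
}

// [[Rcpp::export]]
NumericVector cpp_telegraph_log_pmf(double kon, double koff, double kt, int xmax) {
  check_params(kon, koff, kt);
  if (xmax < 0) stop("xmax must be >= 0");
  NumericVector out(xmax + 1);
  if (kt == 0.0 || kon == 0.0) {
    // promoter never productive: all mass at zero
    out[0] = 0.0;
    for (int x = 1; x <= xmax; ++x) out[x] = R_NegInf;
    return out;
  }
  const double lg_kon = R::lgammafn(kon);
  const double lg_ab  = R::lgammafn(kon + koff);
  const double lkt    = std::log(kt);
  for (int x = 0; x <= xmax; ++x) {
    double b = kon + koff + x;
    double lpre = R::lgammafn(kon + x) - lg_kon
                + lg_ab - R::lgammafn(b)
                - R::lgammafn(x + 1.0)
                + x * lkt - kt;
    out[x] = lpre + log_kummer_series(koff, b, kt);
  }
  return out;
}

// Build the full lookup table: one row per (kon, koff, kt) triple, kon-major
// order (kon slowest, then koff, kt fastest), columns x = 0..xmax.
// [[Rcpp::export]]
NumericMatrix cpp_build_table(NumericVector kon_values, NumericVector koff_values,
                              NumericVector kt_values, int xmax) {
  const R_xlen_t n_on = kon_values.size(), n_off = koff_values.size(),
                 n_t = kt_values.size();
  const R_xlen_t nrow = n_on * n_off * n_t;
  NumericMatrix tab(nrow, xmax + 1);
  R_xlen_t r = 0;
  for (R_xlen_t i = 0; i < n_on; ++i) {
    for (R_xlen_t j = 0; j < n_off; ++j) {
      for (R_xlen_t k = 0; k < n_t; ++k, ++r) {
        NumericVector row = cpp_telegraph_log_pmf(kon_values[i], koff_values[j],
                                                  kt_values[k], xmax);
        for (int x = 0; x <= xmax; ++x) tab(r, x) = row[x];
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return tab;
}

// Exact stochastic simulation (Gillespie) of the two-state gene:
//   off -> on  at kon;  on -> off at koff;  on -> on + mRNA at kt;
//   mRNA -> 0  at rate 1 per molecule (time in units of mRNA lifetime).
// Returns n independent end states (mRNA count, promoter state) at t_end,
// each trajectory started from (0 mRNA, promoter off). Uses R's RNG so that
// set.seed() governs reproducibility. Also accumulates the fraction of time
// the promoter spends on, returned as an attribute.
// [[Rcpp::export]]
IntegerMatrix cpp_gillespie(double kon, double koff, double kt, double t_end,
                            int n) {
  check_params(kon, koff, kt);
  if (t_end <= 0.0) stop("t_end must be > 0");
  if (n < 1) stop("n must be >= 1");
  IntegerMatrix out(n, 2);
  double time_on = 0.0, time_tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    int state = 0;   // 0 = off, 1 = on
    int m = 0;       // mRNA count
    for (;;) {
      double a_switch = state ? koff : kon;
      double a_txn    = state ? kt : 0.0;
      double a_deg    = (double)m;
      double a_tot    = a_switch + a_txn + a_deg;
      if (a_tot <= 0.0) {  // absorbing (kon == 0, nothing left): jump to end
        if (state) time_on += t_end - t;
        t = t_end;
        break;
      }
      double dt = exp_rand() / a_tot;
      if (t + dt >= t_end) {
        if (state) time_on += t_end - t;
        break;
      }
      if (state) time_on += dt;
      t += dt;
      double u = unif_rand() * a_tot;
      if (u < a_switch) state = 1 - state;
      else if (u < a_switch + a_txn) ++m;
      else --m;
    }
    time_tot += t_end;
    out(i, 0) = m;
    out(i, 1) = state;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  out.attr("fraction_on") = time_on / time_tot;
  return out;
}

// first row index attaining the maximum of each column
// [[Rcpp::export]]
IntegerVector cpp_col_argmax(NumericMatrix m) {
  const R_xlen_t nr = m.nrow(), nc = m.ncol();
  IntegerVector out(nc);
  for (R_xlen_t j = 0; j < nc; ++j) {
    double best = R_NegInf; R_xlen_t bi = 0;
    const double* col = &m(0, j);
    for (R_xlen_t i = 0; i < nr; ++i)
      if (col[i] > best) { best = col[i]; bi = i; }
    out[j] = (int)(bi + 1);
  }
  return out;
}
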