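// Laplace-approximated marginal likelihood for the one-compartment
// infusion model with log-normal random effects on CL and V and a
// proportional residual error. The inner 2-d optimisation over each
// subject's random effects runs here; the covariate model and the outer
// optimisation stay in R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double FMIN = 1e-4;     // floor on predictions inside the variance
static const double TWOPI = 6.283185307179586;

// Concentration at times t for a subject with infusion doses (td, amt, dur).
static void conc(const std::vector<double>& t,
                 const std::vector<double>& td,
                 const std::vector<double>& amt,
                 const std::vector<double>& dur,
                 double cl, double v, std::vector<double>& out) {
  const double ke = cl / v;
  std::fill(out.begin(), out.end(), 0.0);
  for (size_t d = 0; d < td.size(); ++d) {
    const double rate = amt[d] / dur[d];
    const double cend = (rate / cl) * (1.0 - std::exp(-ke * dur[d]));
    for (size_t j = 0; j < t.size(); ++j) {
      const double dt = t[j] - td[d];
      if (dt <= 0.0) continue;
      if (dt <= dur[d]) {
        out[j] += (rate / cl) * (1.0 - std::exp(-ke * dt));
      } else {
        out[j] += cend * std::exp(-ke * (dt - dur[d]));
      }
    }
  }
}

struct SubjectData {
  std::vector<double> y, t, td, amt, dur;
};

// -2 * log joint density of (y, eta) for one subject.
static double h_eta(const SubjectData& s, double tvcl, double tvv,
                    double e1, double e2, double om2cl, double om2v,
                    double sig2, std::vector<double>& work) {
  if (sig2 < 1e-8) sig2 = 1e-8;   // keep the likelihood defined as sigma -> 0
  if (om2cl < 1e-12) om2cl = 1e-12;
  if (om2v < 1e-12) om2v = 1e-12;
  const double cl = tvcl * std::exp(e1);
  const double v = tvv * std::exp(e2);
  conc(s.t, s.td, s.amt, s.dur, cl, v, work);
  double h = 0.0;
  for (size_t j = 0; j < s.y.size(); ++j) {
    const double f = work[j];
    const double fv = (f > FMIN) ? f : FMIN;
    const double var = sig2 * fv * fv;
    const double r = s.y[j] - f;
    h += r * r / var + std::log(var) + std::log(TWOPI);
  }
  h += e1 * e1 / om2cl + std::log(om2cl) + std::log(TWOPI);
  h += e2 * e2 / om2v + std::log(om2v) + std::log(TWOPI);
  return h;
}

// Inner Newton minimisation of h over eta with finite-difference
// derivatives; returns -2 log marginal likelihood (Laplace) and eta-hat.
static double laplace_subject(const SubjectData& s, double tvcl, double tvv,
                              double om2cl, double om2v, double sig2,
                              double& e1, double& e2) {
  std::vector<double> work(s.y.size());
  const double step = 1e-4;
  double h0 = h_eta(s, tvcl, tvv, e1, e2, om2cl, om2v, sig2, work);
  for (int it = 0; it < 60; ++it) {
    const double hp1 = h_eta(s, tvcl, tvv, e1 + step, e2, om2cl, om2v, sig2, work);
    const double hm1 = h_eta(s, tvcl, tvv, e1 - step, e2, om2cl, om2v, sig2, work);
    const double hp2 = h_eta(s, tvcl, tvv, e1, e2 + step, om2cl, om2v, sig2, work);
    const double hm2 = h_eta(s, tvcl, tvv, e1, e2 - step, om2cl, om2v, sig2, work);
    const double g1 = (hp1 - hm1) / (2 * step);
    const double g2 = (hp2 - hm2) / (2 * step);
    if (std::fabs(g1) < 1e-7 && std::fabs(g2) < 1e-7) break;
    const double h11 = (hp1 - 2 * h0 + hm1) / (step * step);
    const double h22 = (hp2 - 2 * h0 + hm2) / (step * step);
    const double hpp = h_eta(s, tvcl, tvv, e1 + step, e2 + step, om2cl, om2v, sig2, work);
    const double h12 = (hpp - hp1 - hp2 + h0) / (step * step);
    double d1, d2;
    const double det = h11 * h22 - h12 * h12;
    if (h11 > 0.0 && det > 0.0) {
      d1 = -(h22 * g1 - h12 * g2) / det;
      d2 = -(h11 * g2 - h12 * g1) / det;
    } else { // fall back to scaled gradient descent
      const double gn = std::sqrt(g1 * g1 + g2 * g2);
      d1 = -0.1 * g1 / gn;
      d2 = -0.1 * g2 / gn;
    }
    // cap the step to keep exp(eta) in a sane range
    const double dn = std::sqrt(d1 * d1 + d2 * d2);
    if (dn > 2.0) { d1 *= 2.0 / dn; d2 *= 2.0 / dn; }
    double lam = 1.0, hnew = 0.0;
    bool ok = false;
    for (int ls = 0; ls < 12; ++ls) {
      hnew = h_eta(s, tvcl, tvv, e1 + lam * d1, e2 + lam * d2,
                   om2cl, om2v, sig2, work);
      if (hnew <= h0 + 1e-12) { ok = true; break; }
      lam *= 0.5;
    }
    if (!ok) break;
    e1 += lam * d1; e2 += lam * d2;
    if (std::fabs(h0 - hnew) < 1e-10 * (1.0 + std::fabs(h0))) { h0 = hnew; break; }
    h0 = hnew;
  }
  // Hessian of h at the optimum for the Laplace determinant term
  const double hs = 1e-3;
  const double hc = h_eta(s, tvcl, tvv, e1, e2, om2cl, om2v, sig2, work);
  const double hp1 = h_eta(s, tvcl, tvv, e1 + hs, e2, om2cl, om2v, sig2, work);
  const double hm1 = h_eta(s, tvcl, tvv, e1 - hs, e2, om2cl, om2v, sig2, work);
  const double hp2 = h_eta(s, tvcl, tvv, e1, e2 + hs, om2cl, om2v, sig2, work);
  const double hm2 = h_eta(s, tvcl, tvv, e1, e2 - hs, om2cl, om2v, sig2, work);
  const double hpp = h_eta(s, tvcl, tvv, e1 + hs, e2 + hs, om2cl, om2v, sig2, work);
  double h11 = (hp1 - 2 * hc + hm1) / (hs * hs);
  double h22 = (hp2 - 2 * hc + hm2) / (hs * hs);
  double h12 = (hpp - hp1 - hp2 + hc) / (hs * hs);
  double det = (h11 / 2) * (h22 / 2) - (h12 / 2) * (h12 / 2);
  // Non-PD curvature (inner optimum on a flat/saddle region): fall back to
  // the prior-only curvature so degeneracy is never rewarded with a
  // spuriously small determinant.
  const double prior_det = 1.0 / (om2cl * om2v);
  if (!(det > 0.0) || det < prior_det * 1e-6) det = prior_det;
  return hc - 2.0 * std::log(TWOPI) + std::log(det);
}

// [[Rcpp::export]]
List cpp_laplace_nll(NumericVector tvcl, NumericVector tvv,
                     double om2cl, double om2v, double sig2,
                     List y, List t, List dose_t, List dose_amt,
                     List dose_dur, NumericMatrix eta_start) {
  const int n = tvcl.size();
  NumericMatrix eta(n, 2);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    SubjectData s;
    s.y = as<std::vector<double> >(y[i]);
    s.t = as<std::vector<double> >(t[i]);
    s.td = as<std::vector<double> >(dose_t[i]);
    s.amt = as<std::vector<double> >(dose_amt[i]);
    s.dur = as<std::vector<double> >(dose_dur[i]);
    double e1 = eta_start(i, 0), e2 = eta_start(i, 1);
    if (s.y.empty()) { eta(i, 0) = 0.0; eta(i, 1) = 0.0; continue; }
    nll += laplace_subject(s, tvcl[i], tvv[i], om2cl, om2v, sig2, e1, e2);
    eta(i, 0) = e1; eta(i, 1) = e2;
  }
  return List::create(_["nll"] = nll, _["eta"] = eta);
}

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector t, NumericVector dose_t,
                       NumericVector dose_amt, NumericVector dose_dur,
                       double cl, double v) {
  std::vector<double> tt = as<std::vector<double> >(t);
  std::vector<double> out(tt.size());
  conc(tt, as<std::vector<double> >(dose_t),
       as<std::vector<double> >(dose_amt),
       as<std::vector<double> >(dose_dur), cl, v, out);
  return wrap(out);
}
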