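// Compiled kernels for the Monte-Carlo cross-validation loop: a Cox
// partial-likelihood Newton-Raphson solver (Breslow tie handling), the
// IPCW cumulative/dynamic AUC over a vector of time points, and a fused
// screening loop that scores many candidate design matrices on shared
// random splits. A CAFS search performs ~10^5-10^6 fits, so per-split
// work (sorting, tie grouping, censoring KM) is computed once and
// shared across candidates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// tie structure of a time-sorted (descending) sample
struct TieGroups {
  std::vector<arma::uword> start;  // first row of each tie group
  std::vector<int> d;              // events in the group
};

static void make_groups(const arma::vec& ts, const arma::vec& ds,
                        TieGroups& g) {
  const arma::uword n = ts.n_elem;
  g.start.clear();
  g.d.clear();
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    int d = 0;
    while (j < n && ts(j) == ts(i)) {
      if (ds(j) == 1.0) ++d;
      ++j;
    }
    g.start.push_back(i);
    g.d.push_back(d);
    i = j;
  }
  g.start.push_back(n);
}

// Log partial likelihood, gradient and information at beta (Breslow).
// Xt holds one patient per COLUMN (p x n, contiguous covariate vectors)
// with columns sorted by decreasing time; tie groups precomputed.
static double cox_ll(const arma::mat& Xt, const arma::vec& event,
                     const TieGroups& grp, const arma::vec& beta,
                     arma::vec& grad, arma::mat& info) {
  const arma::uword p = Xt.n_rows, n = Xt.n_cols;
  arma::vec eta = Xt.t() * beta;
  double emax = eta.max();
  arma::vec wv = arma::exp(eta - emax);
  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  grad.zeros();
  info.zeros();
  double ll = 0.0;
  for (size_t gi = 0; gi + 1 < grp.start.size(); ++gi) {
    arma::uword i = grp.start[gi], j = grp.start[gi + 1];
    for (arma::uword k = i; k < j; ++k) {
      double w = wv(k);
      S0 += w;
      const double* xk = Xt.colptr(k);
      for (arma::uword a = 0; a < p; ++a) {
        double wxa = w * xk[a];
        S1(a) += wxa;
        double* s2col = S2.colptr(a);
        for (arma::uword b = a; b < p; ++b)
          s2col[b] += wxa * xk[b];
      }
    }
    int d = grp.d[gi];
    if (d > 0) {
      double invS0 = 1.0 / S0;
      double logS0 = std::log(S0) + emax;
      for (arma::uword k = i; k < j; ++k) {
        if (event(k) == 1.0) {
          ll += eta(k) - logS0;
          const double* xk = Xt.colptr(k);
          for (arma::uword a = 0; a < p; ++a) grad(a) += xk[a];
        }
      }
      for (arma::uword a = 0; a < p; ++a) {
        double xbar_a = S1(a) * invS0;
        grad(a) -= d * xbar_a;
        double* icol = info.colptr(a);
        const double* s2col = S2.colptr(a);
        for (arma::uword b = a; b < p; ++b)
          icol[b] += d * (s2col[b] * invS0 - xbar_a * (S1(b) * invS0));
      }
    }
  }
  for (arma::uword a = 0; a < p; ++a)
    for (arma::uword b = a + 1; b < p; ++b) info(a, b) = info(b, a);
  return ll;
}

struct CoxFit {
  arma::vec beta;
  double ll0, ll;
  int iter;
  bool converged, singular;
};

// Newton-Raphson with step halving on pre-sorted, pre-grouped data
static CoxFit cox_newton(const arma::mat& Xt, const arma::vec& ds,
                         const TieGroups& grp,
                         const arma::vec& beta_init, double eps,
                         int iter_max) {
  const arma::uword p = Xt.n_rows;
  CoxFit out;
  out.beta = beta_init;
  arma::vec grad(p);
  arma::mat info(p, p);
  double ll = cox_ll(Xt, ds, grp, out.beta, grad, info);
  out.ll0 = ll;
  out.converged = false;
  out.singular = false;
  int iter = 0;
  for (iter = 0; iter < iter_max; ++iter) {
    arma::vec step;
    bool ok = arma::solve(step, info, grad,
                          arma::solve_opts::no_approx);
    if (!ok || !step.is_finite()) { out.singular = true; break; }
    double halving = 1.0;
    arma::vec beta_new = out.beta + step;
    arma::vec grad_new(p);
    arma::mat info_new(p, p);
    double ll_new = cox_ll(Xt, ds, grp, beta_new, grad_new, info_new);
    int halved = 0;
    while ((!std::isfinite(ll_new) || ll_new < ll) && halved < 30) {
      halving /= 2.0;
      beta_new = out.beta + halving * step;
      ll_new = cox_ll(Xt, ds, grp, beta_new, grad_new, info_new);
      ++halved;
    }
    if (!std::isfinite(ll_new)) { out.singular = true; break; }
    double rel = std::fabs(ll_new - ll) / (std::fabs(ll_new) + 1e-12);
    out.beta = beta_new;
    grad = grad_new;
    info = info_new;
    double prev = ll;
    ll = ll_new;
    if (rel < eps && ll >= prev) { out.converged = true; ++iter; break; }
  }
  out.ll = ll;
  out.iter = iter;
  if (out.singular) out.converged = false;
  return out;
}

// [[Rcpp::export]]
List cpp_coxfit(const arma::mat& X, const arma::vec& time,
                const arma::vec& event, double eps = 1e-9,
                int iter_max = 100) {
  const arma::uword p = X.n_cols;
  arma::uvec ord = arma::sort_index(time, "descend");
  arma::mat Xt = X.t();
  Xt = Xt.cols(ord);
  arma::vec ts = time(ord), ds = event(ord);
  TieGroups grp;
  make_groups(ts, ds, grp);
  CoxFit fit = cox_newton(Xt, ds, grp,
                          arma::vec(p, arma::fill::zeros), eps,
                          iter_max);
  arma::vec se(p, arma::fill::value(NA_REAL));
  bool singular = fit.singular;
  if (!singular) {
    // recompute the information at the optimum for the covariance
    arma::vec grad(p);
    arma::mat info(p, p);
    cox_ll(Xt, ds, grp, fit.beta, grad, info);
    arma::mat vcv;
    if (arma::inv_sympd(vcv, info)) se = arma::sqrt(vcv.diag());
    else singular = true;
  }
  bool converged = fit.converged && !singular;
  return List::create(_["coef"] = fit.beta, _["se"] = se,
                      _["loglik"] = NumericVector::create(fit.ll0,
                                                          fit.ll),
                      _["iter"] = fit.iter, _["converged"] = converged,
                      _["singular"] = singular);
}

// Kaplan-Meier of the censoring distribution G(t) = P(C > t); fills
// gminus(i) = G(T_i-) and, for the exported variant, the
// right-continuous step function.
static void censor_km_gminus(const arma::vec& time,
                             const arma::vec& event,
                             arma::vec& gminus) {
  const arma::uword n = time.n_elem;
  arma::uvec ord = arma::sort_index(time, "ascend");
  gminus.set_size(n);
  double G = 1.0;
  arma::uword i = 0, atrisk = n;
  while (i < n) {
    arma::uword j = i;
    double t = time(ord(i));
    int dcens = 0;
    while (j < n && time(ord(j)) == t) {
      if (event(ord(j)) == 0.0) ++dcens;
      ++j;
    }
    for (arma::uword k = i; k < j; ++k) gminus(ord(k)) = G;
    if (dcens > 0) G *= 1.0 - (double)dcens / (double)atrisk;
    atrisk -= (j - i);
    i = j;
  }
}

// [[Rcpp::export]]
List cpp_censor_km(const arma::vec& time, const arma::vec& event) {
  const arma::uword n = time.n_elem;
  arma::uvec ord = arma::sort_index(time, "ascend");
  std::vector<double> ut, gv;
  ut.reserve(n);
  gv.reserve(n);
  arma::vec gminus(n);
  double G = 1.0;
  arma::uword i = 0, atrisk = n;
  while (i < n) {
    arma::uword j = i;
    double t = time(ord(i));
    int dcens = 0;
    while (j < n && time(ord(j)) == t) {
      if (event(ord(j)) == 0.0) ++dcens;
      ++j;
    }
    for (arma::uword k = i; k < j; ++k) gminus(ord(k)) = G;
    if (dcens > 0) G *= 1.0 - (double)dcens / (double)atrisk;
    ut.push_back(t);
    gv.push_back(G);
    atrisk -= (j - i);
    i = j;
  }
  return List::create(_["gminus"] = gminus, _["utime"] = ut,
                      _["gvals"] = gv);
}

// IPCW cumulative/dynamic AUC at each eval time; rord = ascending risk
// order. Cases weighted 1/G(T-), controls uniform; ties count 1/2.
static void cum_auc(const arma::vec& risk, const arma::vec& time,
                    const arma::vec& event, const arma::uvec& rord,
                    const arma::vec& gminus,
                    const arma::vec& eval_times, arma::vec& out) {
  const arma::uword n = risk.n_elem;
  out.set_size(eval_times.n_elem);
  for (arma::uword e = 0; e < eval_times.n_elem; ++e) {
    double t = eval_times(e);
    double num = 0.0, wsum = 0.0, cum_ctrl = 0.0;
    long nctrl_tot = 0;
    for (arma::uword k = 0; k < n; ++k) if (time(k) > t) ++nctrl_tot;
    bool any_case = false;
    arma::uword i = 0;
    while (i < n) {
      arma::uword j = i;
      double r = risk(rord(i));
      double grp_ctrl = 0.0, grp_case_w = 0.0;
      while (j < n && risk(rord(j)) == r) {
        arma::uword idx = rord(j);
        if (time(idx) > t) grp_ctrl += 1.0;
        else if (event(idx) == 1.0 && gminus(idx) > 0.0) {
          grp_case_w += 1.0 / gminus(idx);
          any_case = true;
        }
        ++j;
      }
      num += grp_case_w * (cum_ctrl + 0.5 * grp_ctrl);
      wsum += grp_case_w;
      cum_ctrl += grp_ctrl;
      i = j;
    }
    out(e) = (!any_case || nctrl_tot == 0 || wsum <= 0.0)
      ? NA_REAL : num / (wsum * (double)nctrl_tot);
  }
}

// [[Rcpp::export]]
NumericVector cpp_cum_auc(const arma::vec& risk, const arma::vec& time,
                          const arma::vec& event,
                          const arma::vec& eval_times) {
  arma::vec gminus;
  censor_km_gminus(time, event, gminus);
  arma::uvec rord = arma::sort_index(risk, "ascend");
  arma::vec out;
  cum_auc(risk, time, event, rord, gminus, eval_times, out);
  return wrap(out);
}

// trapezoid mean over times, dropping undefined points; NA when fewer
// than 2 remain
static double trapz_mean_na(const arma::vec& times,
                            const arma::vec& auc) {
  std::vector<double> x, y;
  for (arma::uword i = 0; i < times.n_elem; ++i) {
    if (arma::is_finite(auc(i))) {
      x.push_back(times(i));
      y.push_back(auc(i));
    }
  }
  if (x.size() < 2) return NA_REAL;
  double s = 0.0;
  for (size_t i = 1; i < x.size(); ++i)
    s += (x[i] - x[i - 1]) * (y[i] + y[i - 1]) / 2.0;
  return s / (x.back() - x.front());
}

// Screen many candidate design matrices on shared Monte-Carlo splits
// with the integrated-AUC criterion. For each column of train_idx
// (1-based row indices) and each candidate matrix: fit the Cox model on
// the training rows (warm-started at beta_init[[c]]), predict risk on
// the complement and integrate the IPCW AUC over eval_times (empty ->
// the split's distinct event times inside [t_lo, t_hi]). Returns a
// reps x candidates matrix of criterion values (NA = failed split).
// [[Rcpp::export]]
NumericMatrix cpp_screen_iauc(const List& X_list, const arma::vec& time,
                              const arma::vec& event,
                              const IntegerMatrix& train_idx,
                              double t_lo, double t_hi,
                              const arma::vec& eval_times,
                              const List& beta_init,
                              double eps = 1e-9, int iter_max = 100) {
  const int nc = X_list.size();
  const arma::uword n = time.n_elem;
  const int reps = train_idx.ncol(), ntr = train_idx.nrow();
  std::vector<arma::mat> Xt(nc);  // p x n, one patient per column
  std::vector<arma::vec> b0(nc);
  for (int c = 0; c < nc; ++c) {
    Xt[c] = as<arma::mat>(X_list[c]).t();
    b0[c] = as<arma::vec>(beta_init[c]);
  }
  NumericMatrix out(reps, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<char> in_train(n);
  for (int r = 0; r < reps; ++r) {
    // per-split artifacts shared by every candidate
    std::fill(in_train.begin(), in_train.end(), 0);
    arma::uvec tr(ntr);
    for (int k = 0; k < ntr; ++k) {
      tr(k) = train_idx(k, r) - 1;
      in_train[tr(k)] = 1;
    }
    arma::uvec te(n - ntr);
    arma::uword cte = 0;
    for (arma::uword k = 0; k < n; ++k) if (!in_train[k]) te(cte++) = k;
    arma::vec t_tr = time(tr), d_tr = event(tr);
    arma::uvec ord = arma::sort_index(t_tr, "descend");
    arma::uvec tr_sorted = tr(ord);
    arma::vec ts = t_tr(ord), ds = d_tr(ord);
    TieGroups grp;
    make_groups(ts, ds, grp);
    arma::vec t_te = time(te), d_te = event(te);
    arma::vec gminus;
    censor_km_gminus(t_te, d_te, gminus);
    arma::vec ev;
    if (eval_times.n_elem > 0) {
      ev = eval_times;
    } else {
      std::vector<double> et;
      for (arma::uword k = 0; k < t_te.n_elem; ++k)
        if (d_te(k) == 1.0 && t_te(k) >= t_lo && t_te(k) <= t_hi)
          et.push_back(t_te(k));
      std::sort(et.begin(), et.end());
      et.erase(std::unique(et.begin(), et.end()), et.end());
      if (et.size() < 2) continue;
      ev = arma::vec(et);
    }
    for (int c = 0; c < nc; ++c) {
      arma::mat Xtr = Xt[c].cols(tr_sorted);
      CoxFit fit = cox_newton(Xtr, ds, grp, b0[c], eps, iter_max);
      if (!fit.converged) continue;
      arma::vec risk = Xt[c].cols(te).t() * fit.beta;
      arma::uvec rord = arma::sort_index(risk, "ascend");
      arma::vec auc;
      cum_auc(risk, t_te, d_te, rord, gminus, ev, auc);
      out(r, c) = trapz_mean_na(ev, auc);
    }
  }
  return out;
}
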