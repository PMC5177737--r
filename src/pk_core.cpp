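// Compiled core: closed-form linear disposition, the joint individual
// -2 log-likelihood (Gaussian residuals + M3 censored terms + log-normal
// eta prior), the inner Newton search for the conditional eta mode, and
// the per-subject Laplace marginal contribution.  Everything here is
// called in tight loops by the R-level estimation code.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Disposition of a unit IV bolus into the central compartment of a 1-, 2-
// or 3-compartment mammillary model: central concentration is
// sum_i A[i] * exp(-lambda[i] * t), with sum(A) = 1/V1.
// params follow the CL/V parameterizations:
//   1-cpt: CL, V ; 2-cpt: CL, V1, Q, V2 ; 3-cpt: CL, V1, Q2, V2, Q3, V3
static void disposition(int ncpt, const arma::vec& p,
                        arma::vec& lambda, arma::vec& A) {
  if (ncpt == 1) {
    lambda.set_size(1); A.set_size(1);
    lambda[0] = p[0] / p[1];
    A[0] = 1.0 / p[1];
    return;
  }
  int n = ncpt;
  double V1 = p[1];
  arma::mat K(n, n, arma::fill::zeros);
  // elimination from central
  K(0, 0) = -p[0] / V1;
  for (int c = 1; c < n; ++c) {
    double Q = p[2 * c];      // Q (2-cpt) or Q2/Q3 (3-cpt)
    double Vp = p[2 * c + 1]; // V2 / V3
    double k1c = Q / V1, kc1 = Q / Vp;
    K(0, 0) -= k1c;
    K(c, 0) = k1c;
    K(0, c) = kc1;
    K(c, c) = -kc1;
  }
  arma::cx_vec eigval;
  arma::cx_mat P;
  arma::eig_gen(eigval, P, K);
  // near-degenerate rate constants: perturb to keep eigenvectors well
  // conditioned (ties are a measure-zero configuration)
  bool tied = false;
  for (int i = 0; i < n && !tied; ++i)
    for (int j = i + 1; j < n; ++j)
      if (std::abs(std::real(eigval[i]) - std::real(eigval[j])) <
          1e-10 * std::abs(std::real(eigval[i]))) { tied = true; break; }
  if (tied) {
    arma::mat K2 = K;
    K2(0, 0) *= (1.0 + 1e-9);
    arma::eig_gen(eigval, P, K2);
  }
  arma::cx_mat Pinv = arma::inv(P);
  lambda.set_size(n); A.set_size(n);
  for (int i = 0; i < n; ++i) {
    lambda[i] = -std::real(eigval[i]);
    A[i] = std::real(P(0, i) * Pinv(i, 0)) / V1;
  }
}

// [[Rcpp::export]]
List cpp_disposition(int ncpt, arma::vec params) {
  arma::vec lambda, A;
  disposition(ncpt, params, lambda, A);
  return List::create(_["lambda"] = lambda, _["A"] = A);
}

// Concentration (IU/L) at arbitrary times under superposed constant-rate
// infusions plus an endogenous baseline and a decaying residual pre-dose
// central amount.
static arma::vec conc_core(const arma::vec& lambda, const arma::vec& A,
                           const arma::vec& rstart, const arma::vec& rdur,
                           const arma::vec& rrate,
                           double baseline, double resid_amt,
                           const arma::vec& times) {
  int nt = times.n_elem, nl = lambda.n_elem, nd = rstart.n_elem;
  arma::vec out(nt);
  for (int t = 0; t < nt; ++t) {
    double tt = times[t];
    double c = baseline;
    if (resid_amt > 0.0)
      for (int i = 0; i < nl; ++i)
        c += resid_amt * A[i] * std::exp(-lambda[i] * tt);
    for (int d = 0; d < nd; ++d) {
      if (tt <= rstart[d] || rrate[d] <= 0.0) continue;
      double tend = rstart[d] + rdur[d];
      for (int i = 0; i < nl; ++i) {
        double k = rrate[d] * A[i] / lambda[i];
        if (tt <= tend)
          c += k * (1.0 - std::exp(-lambda[i] * (tt - rstart[d])));
        else
          c += k * (1.0 - std::exp(-lambda[i] * rdur[d])) *
               std::exp(-lambda[i] * (tt - tend));
      }
    }
    out[t] = c;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_conc(int ncpt, arma::vec params,
                   arma::vec reg_start, arma::vec reg_dur, arma::vec reg_rate,
                   double baseline, double resid_conc, arma::vec times) {
  arma::vec lambda, A;
  disposition(ncpt, params, lambda, A);
  double resid_amt = resid_conc * params[1];
  return conc_core(lambda, A, reg_start, reg_dur, reg_rate,
                   baseline, resid_amt, times);
}

// residual sd g(f); errcode 1=additive 2=proportional 3=exponential(log
// scale) 4=combined; sig = (sd_add, sd_prop) with the exponential form
// using sig[0] as the log-scale sd
static inline double ruv_sd(double f, int errcode, const arma::vec& sig) {
  switch (errcode) {
  case 1: return sig[0];
  case 2: return f * sig[1];
  case 3: return sig[0];
  default: return std::sqrt(f * f * sig[1] * sig[1] + sig[0] * sig[0]);
  }
}

// -2 log joint of (observations, eta) for one subject.  Valid rows give
// Gaussian density terms, BLQ rows give M3 censored terms
// -2 log Phi((LOQ - f)/g), and the eta prior adds
// eta' Omega^-1 eta + log|2 pi Omega|.
static double joint_core(const arma::vec& eta, const arma::vec& typ,
                         const arma::ivec& eta_idx, int ncpt,
                         const arma::vec& rstart, const arma::vec& rdur,
                         const arma::vec& rrate, double baseline,
                         double resid_conc, const arma::vec& t_obs,
                         const arma::vec& dv, const arma::ivec& is_blq,
                         const arma::vec& loq, int errcode,
                         const arma::vec& sig, const arma::mat& Oinv,
                         double logdetO, bool include_prior) {
  arma::vec theta = typ;
  for (arma::uword k = 0; k < eta_idx.n_elem; ++k)
    theta[eta_idx[k]] *= std::exp(eta[k]);
  arma::vec lambda, A;
  disposition(ncpt, theta, lambda, A);
  double resid_amt = resid_conc * theta[1];
  arma::vec f = conc_core(lambda, A, rstart, rdur, rrate,
                          baseline, resid_amt, t_obs);
  double ll2 = 0.0; // accumulates -2 log L
  for (arma::uword r = 0; r < t_obs.n_elem; ++r) {
    double fr = f[r];
    if (fr < 1e-12) fr = 1e-12;
    double g = ruv_sd(fr, errcode, sig);
    if (g <= 0.0) return 1e10;
    if (is_blq[r]) {
      double z = (errcode == 3) ? (std::log(loq[r]) - std::log(fr)) / g
                                : (loq[r] - fr) / g;
      double lp = R::pnorm(z, 0.0, 1.0, 1, 1); // log Phi
      ll2 += -2.0 * lp;
    } else {
      double z = (errcode == 3) ? (std::log(dv[r]) - std::log(fr)) / g
                                : (dv[r] - fr) / g;
      ll2 += z * z + LOG2PI + 2.0 * std::log(g);
    }
  }
  if (include_prior && eta.n_elem > 0) {
    ll2 += arma::as_scalar(eta.t() * Oinv * eta);
    ll2 += logdetO + eta.n_elem * LOG2PI;
  }
  return ll2;
}

struct SubjData {
  arma::vec rstart, rdur, rrate, t_obs, dv, loq;
  arma::ivec is_blq;
  double baseline, resid_conc;
};

static SubjData unpack_subject(const List& sub) {
  SubjData s;
  s.rstart = as<arma::vec>(sub["reg_start"]);
  s.rdur = as<arma::vec>(sub["reg_dur"]);
  s.rrate = as<arma::vec>(sub["reg_rate"]);
  s.t_obs = as<arma::vec>(sub["t_obs"]);
  s.dv = as<arma::vec>(sub["dv"]);
  s.loq = as<arma::vec>(sub["loq"]);
  s.is_blq = as<arma::ivec>(sub["is_blq"]);
  s.baseline = as<double>(sub["baseline"]);
  s.resid_conc = as<double>(sub["resid_conc"]);
  return s;
}

// [[Rcpp::export]]
double cpp_joint_neg2ll(arma::vec eta, arma::vec typ, arma::ivec eta_idx,
                        int ncpt, List sub, int errcode, arma::vec sig,
                        arma::mat Oinv, double logdetO,
                        bool include_prior = true) {
  SubjData s = unpack_subject(sub);
  return joint_core(eta, typ, eta_idx, ncpt, s.rstart, s.rdur, s.rrate,
                    s.baseline, s.resid_conc, s.t_obs, s.dv, s.is_blq,
                    s.loq, errcode, sig, Oinv, logdetO, include_prior);
}

typedef double (*ObjFun)(const arma::vec&, void*);

struct JointCtx {
  const arma::vec* typ; const arma::ivec* eta_idx; int ncpt;
  const SubjData* s; int errcode; const arma::vec* sig;
  const arma::mat* Oinv; double logdetO;
};

static double joint_obj(const arma::vec& eta, void* vctx) {
  JointCtx* c = (JointCtx*)vctx;
  return joint_core(eta, *c->typ, *c->eta_idx, c->ncpt, c->s->rstart,
                    c->s->rdur, c->s->rrate, c->s->baseline,
                    c->s->resid_conc, c->s->t_obs, c->s->dv, c->s->is_blq,
                    c->s->loq, c->errcode, *c->sig, *c->Oinv, c->logdetO,
                    true);
}

static void fd_grad_hess(ObjFun f, void* ctx, const arma::vec& x, double f0,
                         arma::vec& g, arma::mat& H, double h = 1e-4) {
  int q = x.n_elem;
  g.set_size(q); H.set_size(q, q);
  arma::vec fp(q), fm(q);
  for (int i = 0; i < q; ++i) {
    arma::vec xp = x, xm = x;
    xp[i] += h; xm[i] -= h;
    fp[i] = f(xp, ctx); fm[i] = f(xm, ctx);
    g[i] = (fp[i] - fm[i]) / (2.0 * h);
    H(i, i) = (fp[i] - 2.0 * f0 + fm[i]) / (h * h);
  }
  for (int i = 0; i < q; ++i)
    for (int j = i + 1; j < q; ++j) {
      arma::vec xpp = x, xpm = x, xmp = x, xmm = x;
      xpp[i] += h; xpp[j] += h;
      xpm[i] += h; xpm[j] -= h;
      xmp[i] -= h; xmp[j] += h;
      xmm[i] -= h; xmm[j] -= h;
      H(i, j) = H(j, i) =
        (f(xpp, ctx) - f(xpm, ctx) - f(xmp, ctx) + f(xmm, ctx)) /
        (4.0 * h * h);
    }
}

// Newton search with step-halving for the conditional mode of eta,
// started at eta = 0 (deterministic).  Returns the mode, the joint value,
// the finite-difference Hessian of the joint there, and a convergence
// flag (gradient inf-norm below tol).
static List eta_mode_core(JointCtx& ctx, int q, double tol = 1e-6,
                          int maxit = 100) {
  arma::vec eta(q, arma::fill::zeros);
  double f0 = joint_obj(eta, &ctx);
  arma::vec g; arma::mat H;
  bool conv = false;
  double gnorm = NA_REAL;
  for (int it = 0; it < maxit; ++it) {
    fd_grad_hess(joint_obj, &ctx, eta, f0, g, H);
    gnorm = arma::abs(g).max();
    if (gnorm < tol) { conv = true; break; }
    arma::mat Hp = H;
    // ridge until positive definite
    double ridge = 0.0;
    arma::vec step;
    for (int k = 0; k < 12; ++k) {
      bool ok = arma::solve(step, Hp, g, arma::solve_opts::no_approx);
      if (ok && arma::dot(step, g) > 0) break;
      ridge = (ridge == 0.0) ? 1e-4 * std::abs(H.diag().max()) + 1e-8
                             : ridge * 10.0;
      Hp = H + ridge * arma::eye(q, q);
      step.reset();
    }
    if (step.n_elem == 0) step = g; // fall back to gradient
    double alpha = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 40; ++ls) {
      arma::vec cand = eta - alpha * step;
      double fc = joint_obj(cand, &ctx);
      if (fc < f0 - 1e-14) { eta = cand; f0 = fc; improved = true; break; }
      alpha *= 0.5;
    }
    if (!improved) { // local quadratic floor reached
      conv = gnorm < 1e-3;
      break;
    }
  }
  // final curvature at the mode
  fd_grad_hess(joint_obj, &ctx, eta, f0, g, H);
  gnorm = arma::abs(g).max();
  if (gnorm < tol) conv = true;
  return List::create(_["eta"] = eta, _["value"] = f0, _["hessian"] = H,
                      _["grad_norm"] = gnorm, _["converged"] = conv);
}

// [[Rcpp::export]]
List cpp_eta_mode(arma::vec typ, arma::ivec eta_idx, int ncpt, List sub,
                  int errcode, arma::vec sig, arma::mat Oinv,
                  double logdetO, double tol = 1e-6, int maxit = 100) {
  SubjData s = unpack_subject(sub);
  JointCtx ctx{&typ, &eta_idx, ncpt, &s, errcode, &sig, &Oinv, logdetO};
  return eta_mode_core(ctx, eta_idx.n_elem, tol, maxit);
}

// Laplace approximation to the population -2 log marginal likelihood:
// sum_i [ joint_i(eta_hat_i) + log det(H_i / (4 pi)) ], H_i the Hessian
// of the joint in eta at its mode (so H_i/2 is the Hessian of -log joint
// density, giving the usual (2 pi)^{q/2} |H/2|^{-1/2} Laplace factor).
// [[Rcpp::export]]
List cpp_laplace_ofv(arma::mat typ, arma::ivec eta_idx, int ncpt,
                     List subjects, int errcode, arma::vec sig,
                     arma::mat Omega, double tol = 1e-6) {
  int n = subjects.size();
  int q = eta_idx.n_elem;
  arma::mat Oinv;
  double logdetO, sign;
  if (!arma::inv_sympd(Oinv, Omega)) stop("Omega is singular");
  arma::log_det(logdetO, sign, Omega);
  if (sign <= 0) stop("Omega is not positive definite");
  arma::mat eta_hat(n, q, arma::fill::zeros);
  arma::vec ofv_i(n);
  LogicalVector conv(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    List sub = subjects[i];
    SubjData s = unpack_subject(sub);
    arma::vec tv = typ.row(i).t();
    JointCtx ctx{&tv, &eta_idx, ncpt, &s, errcode, &sig, &Oinv, logdetO};
    List m = eta_mode_core(ctx, q, tol);
    arma::vec eh = m["eta"];
    arma::mat H = m["hessian"];
    double val = m["value"];
    // make curvature PD for the log-determinant
    double ridge = 0.0;
    double ld, sgn;
    for (int k = 0; k < 12; ++k) {
      arma::log_det(ld, sgn, H + ridge * arma::eye(q, q));
      if (sgn > 0) break;
      ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
    }
    double o = val + ld - q * std::log(4.0 * arma::datum::pi);
    eta_hat.row(i) = eh.t();
    ofv_i[i] = o;
    conv[i] = as<bool>(m["converged"]);
    total += o;
  }
  return List::create(_["ofv"] = total, _["eta_hat"] = eta_hat,
                      _["ofv_i"] = ofv_i, _["converged"] = conv);
}

// Batch concentration curves for posterior draws: one row of thetas per
// draw, shared regimen/times.
// [[Rcpp::export]]
arma::mat cpp_conc_draws(int ncpt, arma::mat thetas, arma::vec reg_start,
                         arma::vec reg_dur, arma::vec reg_rate,
                         double baseline, double resid_conc,
                         arma::vec times) {
  int nd = thetas.n_rows;
  arma::mat out(nd, times.n_elem);
  for (int d = 0; d < nd; ++d) {
    arma::vec p = thetas.row(d).t();
    arma::vec lambda, A;
    disposition(ncpt, p, lambda, A);
    out.row(d) = conc_core(lambda, A, reg_start, reg_dur, reg_rate,
                           baseline, resid_conc * p[1], times).t();
  }
  return out;
}
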