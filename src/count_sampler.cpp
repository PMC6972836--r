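// Adaptive random-walk Metropolis-within-Gibbs for the count-family
// (Poisson / negative binomial) latent factor model.  Blocks of the same
// kind are conditionally independent given the rest of the state, so each
// sweep walks through them with cached per-cell log-densities.  Uses R's
// RNG so chains are bit-reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct CountLik {
  const NumericMatrix &y;
  bool nb;
  double r;            // NB size = 1/omega
  double lgamma_r;
  std::vector<double> lgamma_yr;   // lgamma(y + r) indexed by integer y
  const std::vector<double> &lgamma_y1;  // lgamma(y + 1), fixed
  int ymax;

  CountLik(const NumericMatrix &y_, bool nb_,
           const std::vector<double> &lgy1, int ymax_)
    : y(y_), nb(nb_), r(0), lgamma_r(0), lgamma_y1(lgy1), ymax(ymax_) {}

  void set_omega(double omega) {
    if (!nb) return;
    r = 1.0 / omega;
    lgamma_r = std::lgamma(r);
    lgamma_yr.resize(ymax + 1);
    for (int v = 0; v <= ymax; ++v) lgamma_yr[v] = std::lgamma(v + r);
  }

  // log density of y(i,j) at linear predictor eta
  double operator()(int i, int j, double eta) const {
    double yv = y(i, j);
    if (!nb) {
      double mu = std::exp(eta);
      if (!std::isfinite(mu)) return R_NegInf;
      return yv * eta - mu - lgamma_y1[(int)yv];
    }
    double mu = std::exp(eta);
    if (!std::isfinite(mu)) return R_NegInf;
    // lgamma(y+r) - lgamma(r) - lgamma(y+1)
    //   + r*log(r/(r+mu)) + y*log(mu/(r+mu))
    double lpy = lgamma_yr[(int)yv] - lgamma_r - lgamma_y1[(int)yv];
    lpy += r * (std::log(r) - std::log(r + mu));
    if (yv > 0) lpy += yv * (eta - std::log(r + mu));
    return lpy;
  }
};

inline double dnorm_log(double x, double m, double v) {
  double d = x - m;
  return -0.5 * d * d / v;   // unnormalised; constants cancel in MH ratios
}

} // namespace

// [[Rcpp::export(name = ".fit_count_cpp")]]
List fit_count_cpp(NumericMatrix y, int q, bool nb, List prior,
                   int n_iter, int burnin, int thin,
                   double init_scale, bool adapt,
                   double tgt_scalar, double tgt_block,
                   List opts) {
  const int n = y.nrow(), p = y.ncol();
  const double mu_a = prior["mu_alpha"], V_a = prior["V_alpha"];
  const double mu_b = prior["mu_beta"], V_b = prior["V_beta"];
  const NumericMatrix Pprior = prior["P_theta"];   // prior precision, q x q
  const double om_scale = prior["omega_scale"];

  const bool up_alpha = opts["alpha"], up_beta = opts["beta"],
             up_Z = opts["Z"], up_Theta = opts["Theta"],
             up_omega = opts["omega"];

  int ymax = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j)
      if (y(i, j) > ymax) ymax = (int)y(i, j);
  std::vector<double> lgy1(ymax + 1);
  for (int v = 0; v <= ymax; ++v) lgy1[v] = std::lgamma(v + 1.0);

  // state (spec initialisation: effects and factors zero, loading
  // diagonal one, omega one)
  std::vector<double> alpha(n, 0.0), beta(p, 0.0);
  NumericMatrix Z(n, q), Theta(p, q);
  for (int j = 0; j < std::min(p, q); ++j) Theta(j, j) = 1.0;
  double omega = 1.0;
  if (opts.containsElementNamed("init")) {
    List ini = opts["init"];
    if (ini.containsElementNamed("alpha")) {
      NumericVector a0 = ini["alpha"];
      for (int i = 0; i < n; ++i) alpha[i] = a0[i];
    }
    if (ini.containsElementNamed("beta")) {
      NumericVector b0 = ini["beta"];
      for (int j = 0; j < p; ++j) beta[j] = b0[j];
    }
    if (ini.containsElementNamed("Z")) Z = as<NumericMatrix>(ini["Z"]);
    if (ini.containsElementNamed("Theta"))
      Theta = as<NumericMatrix>(ini["Theta"]);
    if (ini.containsElementNamed("omega")) omega = as<double>(ini["omega"]);
  }

  CountLik lik(y, nb, lgy1, ymax);
  lik.set_omega(omega);

  NumericMatrix eta(n, p), llC(n, p);
  auto recompute_eta_row = [&](int i) {
    for (int j = 0; j < p; ++j) {
      double e = alpha[i] + beta[j];
      for (int k = 0; k < q; ++k) e += Z(i, k) * Theta(j, k);
      eta(i, j) = e;
    }
  };
  for (int i = 0; i < n; ++i) recompute_eta_row(i);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) llC(i, j) = lik(i, j, eta(i, j));

  std::vector<double> ls_a(n, std::log(init_scale)),
      ls_b(p, std::log(init_scale)), ls_z(n, std::log(init_scale)),
      ls_t(p, std::log(init_scale));
  double ls_o = std::log(init_scale);

  const int m = (n_iter - burnin) / thin;
  NumericMatrix out_alpha(m, n), out_beta(m, p), out_Z(m, n * q),
      out_Theta(m, p * q);
  NumericVector out_omega(nb ? m : 0), out_ll(m);
  double acc_a = 0, acc_b = 0, acc_z = 0, acc_t = 0, acc_o = 0;
  int n_post = 0, keep = 0;

  std::vector<double> prop(q), lrow(p);
  RNGScope scope;

  for (int t = 1; t <= n_iter; ++t) {
    const bool adapting = adapt && t <= burnin;
    const double g = adapting ? std::min(0.25, 2.0 / std::sqrt((double)t))
                              : 0.0;
    double a_it_a = 0, a_it_b = 0, a_it_z = 0, a_it_t = 0, a_it_o = 0;

    if (up_alpha) {
      for (int i = 0; i < n; ++i) {
        double d = std::exp(ls_a[i]) * R::norm_rand();
        double lr = dnorm_log(alpha[i] + d, mu_a, V_a) -
                    dnorm_log(alpha[i], mu_a, V_a);
        for (int j = 0; j < p; ++j) {
          lrow[j] = lik(i, j, eta(i, j) + d);
          lr += lrow[j] - llC(i, j);
        }
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) {
          alpha[i] += d;
          for (int j = 0; j < p; ++j) { eta(i, j) += d; llC(i, j) = lrow[j]; }
        }
        if (adapting) ls_a[i] += g * ((acc ? 1.0 : 0.0) - tgt_scalar);
        a_it_a += acc;
      }
      a_it_a /= n;
    }

    if (up_beta) {
      for (int j = 0; j < p; ++j) {
        double d = std::exp(ls_b[j]) * R::norm_rand();
        double lr = dnorm_log(beta[j] + d, mu_b, V_b) -
                    dnorm_log(beta[j], mu_b, V_b);
        std::vector<double> lcol(n);
        for (int i = 0; i < n; ++i) {
          lcol[i] = lik(i, j, eta(i, j) + d);
          lr += lcol[i] - llC(i, j);
        }
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) {
          beta[j] += d;
          for (int i = 0; i < n; ++i) { eta(i, j) += d; llC(i, j) = lcol[i]; }
        }
        if (adapting) ls_b[j] += g * ((acc ? 1.0 : 0.0) - tgt_scalar);
        a_it_b += acc;
      }
      a_it_b /= p;
    }

    if (up_Z) {
      for (int i = 0; i < n; ++i) {
        double s = std::exp(ls_z[i]);
        double lr = 0;
        for (int k = 0; k < q; ++k) {
          prop[k] = Z(i, k) + s * R::norm_rand();
          lr += -0.5 * (prop[k] * prop[k] - Z(i, k) * Z(i, k));
        }
        for (int j = 0; j < p; ++j) {
          double de = 0;
          for (int k = 0; k < q; ++k)
            de += (prop[k] - Z(i, k)) * Theta(j, k);
          lrow[j] = lik(i, j, eta(i, j) + de);
          lr += lrow[j] - llC(i, j);
        }
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) {
          for (int j = 0; j < p; ++j) {
            double de = 0;
            for (int k = 0; k < q; ++k)
              de += (prop[k] - Z(i, k)) * Theta(j, k);
            eta(i, j) += de; llC(i, j) = lrow[j];
          }
          for (int k = 0; k < q; ++k) Z(i, k) = prop[k];
        }
        if (adapting) ls_z[i] += g * ((acc ? 1.0 : 0.0) - tgt_block);
        a_it_z += acc;
      }
      a_it_z /= n;
    }

    if (up_Theta) {
      for (int j = 0; j < p; ++j) {
        double s = std::exp(ls_t[j]);
        bool bad = false;
        for (int k = 0; k < q; ++k) {
          if (j < q && k > j) { prop[k] = 0.0; continue; }  // structural zero
          prop[k] = Theta(j, k) + s * R::norm_rand();
        }
        if (j < q && prop[j] <= 0) bad = true;   // positive diagonal
        double lr = 0;
        if (!bad) {
          // prior: -0.5 theta' P theta, difference
          for (int k1 = 0; k1 < q; ++k1)
            for (int k2 = 0; k2 < q; ++k2)
              lr += -0.5 * Pprior(k1, k2) *
                    (prop[k1] * prop[k2] - Theta(j, k1) * Theta(j, k2));
          std::vector<double> lcol(n);
          for (int i = 0; i < n; ++i) {
            double de = 0;
            for (int k = 0; k < q; ++k)
              de += Z(i, k) * (prop[k] - Theta(j, k));
            lcol[i] = lik(i, j, eta(i, j) + de);
            lr += lcol[i] - llC(i, j);
          }
          bool acc = std::log(R::unif_rand()) < lr;
          if (acc) {
            for (int i = 0; i < n; ++i) {
              double de = 0;
              for (int k = 0; k < q; ++k)
                de += Z(i, k) * (prop[k] - Theta(j, k));
              eta(i, j) += de; llC(i, j) = lcol[i];
            }
            for (int k = 0; k < q; ++k) Theta(j, k) = prop[k];
          }
          if (adapting) ls_t[j] += g * ((acc ? 1.0 : 0.0) - tgt_block);
          a_it_t += acc;
        } else if (adapting) {
          ls_t[j] += g * (0.0 - tgt_block);  // proposal outside support
        }
      }
      a_it_t /= p;
    }

    if (nb && up_omega) {
      double lom = std::log(omega) + std::exp(ls_o) * R::norm_rand();
      double omP = std::exp(lom);
      CountLik likP(y, true, lgy1, ymax);
      likP.set_omega(omP);
      double lr = (std::log(omP) - std::log1p((omP / om_scale) * (omP / om_scale))) -
                  (std::log(omega) - std::log1p((omega / om_scale) * (omega / om_scale)));
      NumericMatrix llP(n, p);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < p; ++j) {
          llP(i, j) = likP(i, j, eta(i, j));
          lr += llP(i, j) - llC(i, j);
        }
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        omega = omP; llC = llP;
        lik.set_omega(omega);
      }
      if (adapting) ls_o += g * ((acc ? 1.0 : 0.0) - tgt_scalar);
      a_it_o = acc;
    }

    if (t > burnin) {
      acc_a += a_it_a; acc_b += a_it_b; acc_z += a_it_z; acc_t += a_it_t;
      acc_o += a_it_o; ++n_post;
      if ((t - burnin) % thin == 0) {
        for (int i = 0; i < n; ++i) out_alpha(keep, i) = alpha[i];
        for (int j = 0; j < p; ++j) out_beta(keep, j) = beta[j];
        for (int k = 0; k < q; ++k) {
          for (int i = 0; i < n; ++i) out_Z(keep, k * n + i) = Z(i, k);
          for (int j = 0; j < p; ++j) out_Theta(keep, k * p + j) = Theta(j, k);
        }
        if (nb) out_omega[keep] = omega;
        double s = 0;
        // full log-likelihood incl. normalising constants
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < p; ++j) s += llC(i, j);
        out_ll[keep] = s;
        ++keep;
      }
    }
  }

  NumericVector rates = NumericVector::create(
      _["alpha"] = acc_a / std::max(n_post, 1),
      _["beta"] = acc_b / std::max(n_post, 1),
      _["Z"] = acc_z / std::max(n_post, 1),
      _["Theta"] = acc_t / std::max(n_post, 1),
      _["omega"] = acc_o / std::max(n_post, 1));
  return List::create(_["alpha"] = out_alpha, _["beta"] = out_beta,
                      _["Z"] = out_Z, _["Theta"] = out_Theta,
                      _["omega"] = out_omega, _["loglik"] = out_ll,
                      _["accept"] = rates);
}
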