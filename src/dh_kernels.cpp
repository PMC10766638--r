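// Batched forward / backward kernels for DH-SNN training.
//
// The maths mirrors the plain-R reference path (layer_step / dh_backward)
// exactly; a unit test asserts agreement to ~1e-12. States are N x B
// matrices (neurons x batch); trajectories are N x B x T cubes.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct LayerSpec {
  int n, m, d;
  std::vector<arma::mat> W;   // d x (n x m)
  std::vector<arma::mat> U;   // empty if feedforward
  arma::mat alpha;            // d x n, clamped
  arma::vec beta;             // n, clamped
  bool learn_alpha, learn_beta;
  int reset;                  // 0 soft, 1 hard, 2 none
  double u_th, R;
};

LayerSpec parse_layer(const List& l) {
  LayerSpec s;
  s.n = as<int>(l["n"]); s.m = as<int>(l["m"]); s.d = as<int>(l["d"]);
  List W = l["W"];
  for (int d = 0; d < s.d; ++d) s.W.push_back(as<arma::mat>(W[d]));
  if (!Rf_isNull(l["U"])) {
    List U = l["U"];
    for (int d = 0; d < s.d; ++d) s.U.push_back(as<arma::mat>(U[d]));
  }
  s.alpha = as<arma::mat>(l["alpha"]);
  s.beta = as<arma::vec>(l["beta"]);
  s.learn_alpha = as<bool>(l["learn_alpha"]);
  s.learn_beta = as<bool>(l["learn_beta"]);
  s.reset = as<int>(l["reset"]);
  s.u_th = as<double>(l["u_th"]);
  s.R = as<double>(l["R"]);
  return s;
}

inline arma::mat gauss_pdf(const arma::mat& x, double mu, double sd) {
  const double c = 1.0 / (sd * std::sqrt(2.0 * M_PI));
  return c * arma::exp(-0.5 * arma::square((x - mu) / sd));
}

arma::mat surrogate(const arma::mat& u, double u_th,
                    double gamma, double h, double sigma, double s) {
  arma::mat out = gamma * (1.0 + h) * gauss_pdf(u, u_th, sigma);
  if (h > 0 && s > 0) {
    out -= gamma * h * gauss_pdf(u, sigma, s * sigma);
    out -= gamma * h * gauss_pdf(u, -sigma, s * sigma);
  }
  return out;
}

} // namespace

// Run a batch through the network; optionally backpropagate.
//
// x: C x B x T input cube; labels: T x B integer matrix (-1 outside mask);
// mask: length-T 0/1 vector. readout: linear per-step softmax decode.
// Returns loss, per-step class probabilities, gradients (if grad), and the
// per-layer spike rasters (if record).
// [[Rcpp::export]]
List cpp_run_batch(List layers_in, List readout, const arma::cube& x,
                   const arma::imat& labels, const arma::vec& mask,
                   bool grad, List sg, bool record) {
  const int T = x.n_slices, B = x.n_cols;
  const int L = layers_in.size();
  std::vector<LayerSpec> layers;
  for (int l = 0; l < L; ++l) layers.push_back(parse_layer(layers_in[l]));

  const arma::mat Wro = as<arma::mat>(readout["W"]);
  const arma::vec bro = as<arma::vec>(readout["b"]);
  const int K = Wro.n_rows;
  const double g_gamma = as<double>(sg["gamma"]), g_h = as<double>(sg["h"]);
  const double g_sigma = as<double>(sg["sigma"]), g_s = as<double>(sg["s"]);

  // trajectories
  std::vector<arma::cube> Uc(L), Oc(L);
  std::vector<std::vector<arma::cube>> Ic(L), IIc(L);
  for (int l = 0; l < L; ++l) {
    Uc[l].zeros(layers[l].n, B, T);
    Oc[l].zeros(layers[l].n, B, T);
    Ic[l].assign(layers[l].d, arma::cube(layers[l].n, B, T, arma::fill::zeros));
    IIc[l].assign(layers[l].d, arma::cube(layers[l].n, B, T, arma::fill::zeros));
  }

  // ---------- forward ----------
  {
    std::vector<arma::mat> u(L), o(L);
    std::vector<std::vector<arma::mat>> i(L);
    for (int l = 0; l < L; ++l) {
      u[l].zeros(layers[l].n, B);
      o[l].zeros(layers[l].n, B);
      i[l].assign(layers[l].d, arma::mat(layers[l].n, B, arma::fill::zeros));
    }
    for (int t = 0; t < T; ++t) {
      arma::mat inp = x.slice(t);
      for (int l = 0; l < L; ++l) {
        LayerSpec& ly = layers[l];
        arma::mat bsum(ly.n, B, arma::fill::zeros);
        for (int d = 0; d < ly.d; ++d) {
          arma::mat I = ly.W[d] * inp;
          if (!ly.U.empty()) I += ly.U[d] * o[l];
          arma::vec av = ly.alpha.row(d).t();
          i[l][d] = i[l][d].each_col() % av + I.each_col() % (1.0 - av);
          IIc[l][d].slice(t) = I;
          Ic[l][d].slice(t) = i[l][d];
          bsum += i[l][d];
        }
        arma::mat u_new;
        switch (ly.reset) {
        case 0: u_new = u[l].each_col() % ly.beta +
                 (bsum.each_col() % ((1.0 - ly.beta) * ly.R)) - o[l] * ly.u_th;
          break;
        case 1: u_new = arma::mat(u[l] % (1.0 - o[l])).each_col() % ly.beta +
                 (bsum.each_col() % ((1.0 - ly.beta) * ly.R));
          break;
        default: u_new = u[l].each_col() % ly.beta +
                 (bsum.each_col() % ((1.0 - ly.beta) * ly.R));
        }
        arma::mat o_new = arma::conv_to<arma::mat>::from(u_new - ly.u_th >= 0.0);
        u[l] = u_new; o[l] = o_new;
        Uc[l].slice(t) = u_new;
        Oc[l].slice(t) = o_new;
        inp = o_new;
      }
    }
  }

  // ---------- readout forward / loss ----------
  arma::cube probs(K, B, T, arma::fill::zeros);
  double loss = 0.0;
  int n_dec = 0;
  for (int t = 0; t < T; ++t) if (mask[t] > 0) n_dec += B;
  for (int t = 0; t < T; ++t) {
    arma::mat z = Wro * Oc[L - 1].slice(t);
    z.each_col() += bro;
    z.each_row() -= arma::max(z, 0);
    arma::mat e = arma::exp(z);
    arma::mat p = e.each_row() / arma::sum(e, 0);
    probs.slice(t) = p;
    if (mask[t] > 0) {
      for (int b = 0; b < B; ++b) {
        int y = labels(t, b);
        if (y >= 0) loss += -std::log(std::max(p(y, b), 1e-12));
      }
    }
  }
  if (n_dec > 0) loss /= n_dec;

  List out = List::create(_["loss"] = loss, _["probs"] = probs);
  if (record) {
    List rasters(L);
    for (int l = 0; l < L; ++l) rasters[l] = Oc[l];
    out["rasters"] = rasters;
  }
  if (!grad) return out;

  // ---------- backward ----------
  arma::mat gWro(K, Wro.n_cols, arma::fill::zeros);
  arma::vec gbro(K, arma::fill::zeros);
  std::vector<std::vector<arma::mat>> gW(L), gU(L);
  std::vector<arma::mat> gAlpha(L);
  std::vector<arma::vec> gBeta(L);
  for (int l = 0; l < L; ++l) {
    gW[l].assign(layers[l].d,
                 arma::mat(layers[l].n, layers[l].m, arma::fill::zeros));
    if (!layers[l].U.empty())
      gU[l].assign(layers[l].d,
                   arma::mat(layers[l].n, layers[l].n, arma::fill::zeros));
    gAlpha[l].zeros(layers[l].d, layers[l].n);
    gBeta[l].zeros(layers[l].n);
  }

  std::vector<arma::mat> du(L);
  std::vector<std::vector<arma::mat>> di(L);
  for (int l = 0; l < L; ++l) {
    du[l].zeros(layers[l].n, B);
    di[l].assign(layers[l].d, arma::mat(layers[l].n, B, arma::fill::zeros));
  }

  for (int t = T - 1; t >= 0; --t) {
    for (int l = L - 1; l >= 0; --l) {
      LayerSpec& ly = layers[l];
      const arma::mat& u_t = Uc[l].slice(t);
      const arma::mat& o_t = Oc[l].slice(t);
      arma::mat o_prev = (t > 0) ? Oc[l].slice(t - 1)
                                 : arma::mat(ly.n, B, arma::fill::zeros);
      arma::mat u_prev = (t > 0) ? Uc[l].slice(t - 1)
                                 : arma::mat(ly.n, B, arma::fill::zeros);

      arma::mat do_t(ly.n, B, arma::fill::zeros);
      if (l == L - 1 && mask[t] > 0) {
        arma::mat G = probs.slice(t);
        for (int b = 0; b < B; ++b) {
          int y = labels(t, b);
          if (y >= 0) G(y, b) -= 1.0; else G.col(b).zeros();
        }
        G /= (double)n_dec;
        gWro += G * o_t.t();
        gbro += arma::sum(G, 1);
        do_t += Wro.t() * G;
      }
      switch (ly.reset) {
      case 0: do_t -= ly.u_th * du[l]; break;
      case 1: do_t -= arma::mat(du[l] % u_t).each_col() % ly.beta; break;
      default: break;
      }
      if (l < L - 1) {
        LayerSpec& up = layers[l + 1];
        for (int d = 0; d < up.d; ++d) {
          arma::vec av = up.alpha.row(d).t();
          do_t += up.W[d].t() * (di[l + 1][d].each_col() % (1.0 - av));
        }
      }
      if (!ly.U.empty()) {
        for (int d = 0; d < ly.d; ++d) {
          arma::vec av = ly.alpha.row(d).t();
          do_t += ly.U[d].t() * (di[l][d].each_col() % (1.0 - av));
        }
      }

      arma::mat Hp = surrogate(u_t, ly.u_th, g_gamma, g_h, g_sigma, g_s);
      arma::mat du_new;
      if (ly.reset == 1) {
        du_new = arma::mat(du[l] % (1.0 - o_t)).each_col() % ly.beta + Hp % do_t;
      } else {
        du_new = du[l].each_col() % ly.beta + Hp % do_t;
      }

      arma::mat bsum_t(ly.n, B, arma::fill::zeros);
      for (int d = 0; d < ly.d; ++d) bsum_t += Ic[l][d].slice(t);

      arma::mat x_below = (l == 0) ? x.slice(t) : Oc[l - 1].slice(t);
      for (int d = 0; d < ly.d; ++d) {
        arma::vec av = ly.alpha.row(d).t();
        arma::mat di_new = di[l][d].each_col() % av +
          du_new.each_col() % ((1.0 - ly.beta) * ly.R);
        arma::mat w_in = di_new.each_col() % (1.0 - av);
        gW[l][d] += w_in * x_below.t();
        if (!ly.U.empty()) gU[l][d] += w_in * o_prev.t();
        if (ly.learn_alpha) {
          arma::mat i_prev = (t > 0) ? Ic[l][d].slice(t - 1)
                                     : arma::mat(ly.n, B, arma::fill::zeros);
          arma::vec chain = av % (1.0 - av);
          gAlpha[l].row(d) +=
            (chain % arma::sum((i_prev - IIc[l][d].slice(t)) % di_new, 1)).t();
        }
        di[l][d] = di_new;
      }
      if (ly.learn_beta) {
        arma::mat du_dbeta;
        if (ly.reset == 1) {
          du_dbeta = (1.0 - o_prev) % u_prev - ly.R * bsum_t;
        } else {
          du_dbeta = u_prev - ly.R * bsum_t;
        }
        gBeta[l] += (ly.beta % (1.0 - ly.beta)) %
          arma::sum(du_dbeta % du_new, 1);
      }
      du[l] = du_new;
    }
  }

  List glayers(L);
  for (int l = 0; l < L; ++l) {
    List Wg(layers[l].d);
    for (int d = 0; d < layers[l].d; ++d) Wg[d] = gW[l][d];
    List lg = List::create(_["W"] = Wg, _["alpha_raw"] = gAlpha[l],
                           _["beta_raw"] = gBeta[l]);
    if (!layers[l].U.empty()) {
      List Ug(layers[l].d);
      for (int d = 0; d < layers[l].d; ++d) Ug[d] = gU[l][d];
      lg["U"] = Ug;
    } else {
      lg["U"] = R_NilValue;
    }
    glayers[l] = lg;
  }
  out["grads"] = List::create(
    _["layers"] = glayers,
    _["readout"] = List::create(_["W"] = gWro, _["b"] = gbro));
  return out;
}
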