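// Fixed-step RK4 integrators for networks of two-population (E/I) neural
// masses.  Two entry points:
//   sim_network_cpp   - generic N-node, M-input simulator with optional
//                       synaptic adaptation on W^EE and covariance-driven
//                       short-term plasticity on masked (W^EE, W^EI) pairs.
//   scan_twonode_cpp  - specialised two-node kernel that integrates many
//                       inter-node weight settings in one call and returns
//                       only the per-window maxima of m_2^E needed by the
//                       response categorizer.
//
// State per node: (v_e, u_e) pairs for the EPSP and IPSP of both
// populations, i.e. 8 first-order variables; v^E = v^E_e - v^E_i,
// m^E = S(v^E) and likewise for the inhibitory population.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigm(double v, double two_e0, double r, double v0) {
  return two_e0 / (1.0 + std::exp(r * (v0 - v)));
}

struct NetPar {
  int N, M;
  arma::mat WEE, WIE, WEI, WII, WEX, WIX;
  arma::vec He, taue, Hi, taui, B;
  double two_e0, r, v0;
};

struct NetState {
  // columns of a (N x 8) layout kept as separate vectors for clarity
  arma::vec vEe, uEe, vEi, uEi, vIe, uIe, vIi, uIi;
  arma::mat a;      // adaptation efficacy, N x N (unused unless adapt)
};

static NetState zero_state(int N) {
  NetState s;
  s.vEe.zeros(N); s.uEe.zeros(N); s.vEi.zeros(N); s.uEi.zeros(N);
  s.vIe.zeros(N); s.uIe.zeros(N); s.vIi.zeros(N); s.uIi.zeros(N);
  s.a.ones(N, N);
  return s;
}

// RHS of Eqs. of motion.  x: external input sample (length M).  If adapt,
// da/dt is filled and the E->E coupling uses a % WEE.
static void rhs(const NetPar &p, const NetState &s, const arma::vec &x,
                bool adapt, double tau_a, double kappa, const arma::umat &amask,
                NetState &d, arma::vec &mE, arma::vec &mI) {
  const int N = p.N;
  arma::vec vE = s.vEe - s.vEi;
  arma::vec vI = s.vIe - s.vIi;
  for (int j = 0; j < N; ++j) {
    mE[j] = sigm(vE[j], p.two_e0, p.r, p.v0);
    mI[j] = sigm(vI[j], p.two_e0, p.r, p.v0);
  }
  arma::vec excE;          // input rate to E population, excitatory synapses
  if (adapt) excE = (s.a % p.WEE) * mE; else excE = p.WEE * mE;
  excE += p.WEX * x + p.B;
  arma::vec inhE = p.WEI * mI;
  arma::vec excI = p.WIE * mE + p.WIX * x;
  arma::vec inhI = p.WII * mI;
  for (int j = 0; j < N; ++j) {
    double te = p.taue[j], ti = p.taui[j];
    double ge = p.He[j] / te, gi = p.Hi[j] / ti;
    d.vEe[j] = s.uEe[j];
    d.uEe[j] = ge * excE[j] - 2.0 / te * s.uEe[j] - s.vEe[j] / (te * te);
    d.vEi[j] = s.uEi[j];
    d.uEi[j] = gi * inhE[j] - 2.0 / ti * s.uEi[j] - s.vEi[j] / (ti * ti);
    d.vIe[j] = s.uIe[j];
    d.uIe[j] = ge * excI[j] - 2.0 / te * s.uIe[j] - s.vIe[j] / (te * te);
    d.vIi[j] = s.uIi[j];
    d.uIi[j] = gi * inhI[j] - 2.0 / ti * s.uIi[j] - s.vIi[j] / (ti * ti);
  }
  if (adapt) {
    for (int k = 0; k < N; ++k)
      for (int j = 0; j < N; ++j)
        d.a(j, k) = amask(j, k)
          ? (1.0 - s.a(j, k)) / tau_a - kappa * s.a(j, k) * mE[k]
          : 0.0;
  }
}

static inline void axpy(NetState &y, const NetState &x, double h, bool adapt) {
  y.vEe += h * x.vEe; y.uEe += h * x.uEe; y.vEi += h * x.vEi; y.uEi += h * x.uEi;
  y.vIe += h * x.vIe; y.uIe += h * x.uIe; y.vIi += h * x.vIi; y.uIi += h * x.uIi;
  if (adapt) y.a += h * x.a;
}

// [[Rcpp::export]]
List sim_network_cpp(const arma::mat &WEE, const arma::mat &WIE,
                     const arma::mat &WEI, const arma::mat &WII,
                     const arma::mat &WEX, const arma::mat &WIX,
                     const arma::vec &B,
                     const arma::vec &He, const arma::vec &taue,
                     const arma::vec &Hi, const arma::vec &taui,
                     double e0, double r, double v0,
                     const arma::mat &X,        // M x (2*n_total+1), half-step samples
                     double dt, int n_settle, int n_out,
                     bool adapt, double tau_a, double kappa,
                     const arma::umat &adapt_mask,
                     bool stp, double stp_eta, double stp_gain, double stp_tau,
                     int stp_win, const arma::mat &stp_alpha,
                     const arma::mat &stp_beta, const arma::umat &stp_mask,
                     bool keep_settle, bool keep_components) {
  NetPar p;
  p.N = WEE.n_rows; p.M = WEX.n_cols;
  p.WEE = WEE; p.WIE = WIE; p.WEI = WEI; p.WII = WII; p.WEX = WEX; p.WIX = WIX;
  p.He = He; p.taue = taue; p.Hi = Hi; p.taui = taui; p.B = B;
  p.two_e0 = 2.0 * e0; p.r = r; p.v0 = v0;
  const int N = p.N;
  const int n_total = n_settle + n_out;
  const int rec0 = keep_settle ? 0 : n_settle;
  const int n_rec = n_total - rec0 + 1;

  NetState s = zero_state(N);
  NetState k1 = zero_state(N), k2 = zero_state(N), k3 = zero_state(N),
           k4 = zero_state(N), tmp = zero_state(N);
  arma::vec mE(N), mI(N), mEd(N), mId(N);

  arma::mat out_mE(n_rec, N), out_mI(n_rec, N), out_vE(n_rec, N), out_vI(n_rec, N);
  arma::mat out_sink(n_rec, N), out_source(n_rec, N);
  arma::mat out_vEe, out_vEi, out_vIe, out_vIi;
  if (keep_components) {
    out_vEe.set_size(n_rec, N); out_vEi.set_size(n_rec, N);
    out_vIe.set_size(n_rec, N); out_vIi.set_size(n_rec, N);
  }
  arma::vec out_wee_mean(n_rec, arma::fill::zeros),
            out_wei_mean(n_rec, arma::fill::zeros);
  arma::mat out_a_min(n_rec, N);   // per presynaptic node: min efficacy

  // trailing-window covariance bookkeeping (solver grid, incl. settle)
  arma::mat hist;  arma::vec hsum(N, arma::fill::zeros);
  arma::mat hprod(N, N, arma::fill::zeros);
  int hcount = 0, hpos = 0;
  double n_stp_pairs = stp ? (double)arma::accu(stp_mask) : 1.0;
  if (stp) hist.zeros(N, stp_win);

  auto record = [&](int step) {
    int i = step - rec0;
    arma::vec vE = s.vEe - s.vEi, vI = s.vIe - s.vIi;
    for (int j = 0; j < N; ++j) {
      mE[j] = sigm(vE[j], p.two_e0, p.r, p.v0);
      mI[j] = sigm(vI[j], p.two_e0, p.r, p.v0);
    }
    out_vE.row(i) = vE.t(); out_vI.row(i) = vI.t();
    out_mE.row(i) = mE.t(); out_mI.row(i) = mI.t();
    arma::vec sink = adapt ? arma::vec((s.a % p.WEE) * mE) : arma::vec(p.WEE * mE);
    out_sink.row(i) = sink.t();
    out_source.row(i) = arma::vec(p.WEI * mI).t();
    if (keep_components) {
      out_vEe.row(i) = s.vEe.t(); out_vEi.row(i) = s.vEi.t();
      out_vIe.row(i) = s.vIe.t(); out_vIi.row(i) = s.vIi.t();
    }
    if (stp) {
      double see = 0, sei = 0;
      for (int k = 0; k < N; ++k) for (int j = 0; j < N; ++j)
        if (stp_mask(j, k)) { see += p.WEE(j, k); sei += p.WEI(j, k); }
      out_wee_mean[i] = see / n_stp_pairs;
      out_wei_mean[i] = sei / n_stp_pairs;
    }
    if (adapt) out_a_min.row(i) = arma::min(s.a, 0);
  };

  if (rec0 == 0) record(0);

  for (int step = 0; step < n_total; ++step) {
    arma::vec x0 = X.col(2 * step), xh = X.col(2 * step + 1), x1 = X.col(2 * step + 2);
    rhs(p, s, x0, adapt, tau_a, kappa, adapt_mask, k1, mE, mI);
    tmp = s; axpy(tmp, k1, dt / 2.0, adapt);
    rhs(p, tmp, xh, adapt, tau_a, kappa, adapt_mask, k2, mEd, mId);
    tmp = s; axpy(tmp, k2, dt / 2.0, adapt);
    rhs(p, tmp, xh, adapt, tau_a, kappa, adapt_mask, k3, mEd, mId);
    tmp = s; axpy(tmp, k3, dt, adapt);
    rhs(p, tmp, x1, adapt, tau_a, kappa, adapt_mask, k4, mEd, mId);
    axpy(s, k1, dt / 6.0, adapt); axpy(s, k2, dt / 3.0, adapt);
    axpy(s, k3, dt / 3.0, adapt); axpy(s, k4, dt / 6.0, adapt);
    if (adapt) s.a = arma::clamp(s.a, 0.0, 1.0);

    // firing rates at the new time point (for STP history / updates)
    arma::vec vE = s.vEe - s.vEi;
    for (int j = 0; j < N; ++j) mE[j] = sigm(vE[j], p.two_e0, p.r, p.v0);
    if (!vE.is_finite() || !s.vIe.is_finite()) {
      arma::uvec bad = arma::find_nonfinite(vE);
      int nodebad = bad.n_elem ? (int)bad[0] : 0;
      stop("non-finite state at node %d (excitatory population), step %d (t = %g s)",
           nodebad + 1, step + 1, (step + 1 - n_settle) * dt);
    }

    if (stp) {
      // update trailing-window sums with the new sample
      if (hcount == stp_win) {
        arma::vec old = hist.col(hpos);
        hsum -= old; hprod -= old * old.t();
      } else {
        ++hcount;
      }
      hist.col(hpos) = mE;
      hsum += mE; hprod += mE * mE.t();
      hpos = (hpos + 1) % stp_win;
      if (hcount == stp_win) {
        double nw = (double)stp_win;
        for (int k = 0; k < N; ++k) {
          for (int j = 0; j < N; ++j) {
            if (!stp_mask(j, k)) continue;
            double cov = (hprod(j, k) - hsum[j] * hsum[k] / nw) / (nw - 1.0);
            double wee = p.WEE(j, k), wei = p.WEI(j, k);
            double tgt_ee = cov > 0 ? stp_gain * stp_eta * stp_alpha(j, k) * cov : 0.0;
            double tgt_ei = cov < 0 ? stp_gain * stp_eta * stp_beta(j, k) * (-cov) : 0.0;
            p.WEE(j, k) = wee + dt / stp_tau * (-wee + tgt_ee);
            p.WEI(j, k) = wei + dt / stp_tau * (-wei + tgt_ei);
          }
        }
      }
    }
    if (step + 1 >= rec0) record(step + 1);
  }

  List out = List::create(
    _["mE"] = out_mE, _["mI"] = out_mI, _["vE"] = out_vE, _["vI"] = out_vI,
    _["sink"] = out_sink, _["source"] = out_source,
    _["stp_wee_mean"] = out_wee_mean, _["stp_wei_mean"] = out_wei_mean,
    _["a_min"] = out_a_min,
    _["WEE_final"] = p.WEE, _["WEI_final"] = p.WEI, _["a_final"] = s.a);
  if (keep_components) {
    out["vEe"] = out_vEe; out["vEi"] = out_vEi;
    out["vIe"] = out_vIe; out["vIi"] = out_vIi;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Two-node scan kernel.  grid: n x 8 absolute gains in column order
// (w21_EE, w21_IE, w21_EI, w21_II, w12_EE, w12_IE, w12_EI, w12_II), where
// w21 couples node 1 -> node 2 (the change detector).  Node 1 receives the
// stimulus channel; node 2 has no external input.  Returns the five window
// maxima of m_2^E plus a divergence flag per grid point.
// [[Rcpp::export]]
List scan_twonode_cpp(const arma::mat &grid,
                      double wEE, double wIE, double wEI, double wII,  // intra
                      double wEX1, double wIX1, double B,
                      double He, double taue, double Hi, double taui,
                      double e0, double r, double v0,
                      const arma::vec &x,        // half-step samples, length 2*n_total+1
                      double dt, int n_settle, int n_out,
                      const arma::imat &win,     // 5 x 2 (first/last output index, 0-based)
                      bool adapt, double tau_a, double kappa) {
  const int npts = grid.n_rows;
  const int n_total = n_settle + n_out;
  const double two_e0 = 2.0 * e0;
  const double ge = He / taue, gi = Hi / taui;
  const double ite = 1.0 / (taue * taue), iti = 1.0 / (taui * taui);
  const double de = 2.0 / taue, di = 2.0 / taui;

  arma::mat maxima(npts, 5);
  arma::ivec diverged(npts, arma::fill::zeros);

  for (int pidx = 0; pidx < npts; ++pidx) {
    const double w21EE = grid(pidx, 0), w21IE = grid(pidx, 1),
                 w21EI = grid(pidx, 2), w21II = grid(pidx, 3),
                 w12EE = grid(pidx, 4), w12IE = grid(pidx, 5),
                 w12EI = grid(pidx, 6), w12II = grid(pidx, 7);
    // state: 16 vars (8 per node) + 4 adaptation efficacies
    double y[20] = {0};
    if (adapt) { y[16] = y[17] = y[18] = y[19] = 1.0; }
    double wmax[5] = { -1e300, -1e300, -1e300, -1e300, -1e300 };
    bool bad = false;

    auto deriv = [&](const double *s, double xs, double *d) {
      // node potentials and rates
      double vE1 = s[0] - s[2], vI1 = s[4] - s[6];
      double vE2 = s[8] - s[10], vI2 = s[12] - s[14];
      double mE1 = sigm(vE1, two_e0, r, v0), mI1 = sigm(vI1, two_e0, r, v0);
      double mE2 = sigm(vE2, two_e0, r, v0), mI2 = sigm(vI2, two_e0, r, v0);
      double a11 = 1, a12 = 1, a21 = 1, a22 = 1;
      if (adapt) { a11 = s[16]; a12 = s[17]; a21 = s[18]; a22 = s[19]; }
      // node 1
      double excE1 = a11 * wEE * mE1 + a12 * w12EE * mE2 + wEX1 * xs + B;
      double inhE1 = wEI * mI1 + w12EI * mI2;
      double excI1 = wIE * mE1 + w12IE * mE2 + wIX1 * xs;
      double inhI1 = wII * mI1 + w12II * mI2;
      // node 2
      double excE2 = a21 * w21EE * mE1 + a22 * wEE * mE2 + B;
      double inhE2 = w21EI * mI1 + wEI * mI2;
      double excI2 = w21IE * mE1 + wIE * mE2;
      double inhI2 = w21II * mI1 + wII * mI2;
      d[0] = s[1];  d[1] = ge * excE1 - de * s[1] - ite * s[0];
      d[2] = s[3];  d[3] = gi * inhE1 - di * s[3] - iti * s[2];
      d[4] = s[5];  d[5] = ge * excI1 - de * s[5] - ite * s[4];
      d[6] = s[7];  d[7] = gi * inhI1 - di * s[7] - iti * s[6];
      d[8] = s[9];  d[9] = ge * excE2 - de * s[9] - ite * s[8];
      d[10] = s[11]; d[11] = gi * inhE2 - di * s[11] - iti * s[10];
      d[12] = s[13]; d[13] = ge * excI2 - de * s[13] - ite * s[12];
      d[14] = s[15]; d[15] = gi * inhI2 - di * s[15] - iti * s[14];
      if (adapt) {
        d[16] = (1.0 - a11) / tau_a - kappa * a11 * mE1;
        d[17] = (1.0 - a12) / tau_a - kappa * a12 * mE2;
        d[18] = (1.0 - a21) / tau_a - kappa * a21 * mE1;
        d[19] = (1.0 - a22) / tau_a - kappa * a22 * mE2;
      }
    };

    const int nv = adapt ? 20 : 16;
    double k1[20], k2[20], k3[20], k4[20], tmp[20];
    for (int step = 0; step < n_total && !bad; ++step) {
      double x0 = x[2 * step], xh = x[2 * step + 1], x1 = x[2 * step + 2];
      deriv(y, x0, k1);
      for (int i = 0; i < nv; ++i) tmp[i] = y[i] + dt / 2.0 * k1[i];
      deriv(tmp, xh, k2);
      for (int i = 0; i < nv; ++i) tmp[i] = y[i] + dt / 2.0 * k2[i];
      deriv(tmp, xh, k3);
      for (int i = 0; i < nv; ++i) tmp[i] = y[i] + dt * k3[i];
      deriv(tmp, x1, k4);
      for (int i = 0; i < nv; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (adapt)
        for (int i = 16; i < 20; ++i)
          y[i] = y[i] < 0 ? 0 : (y[i] > 1 ? 1 : y[i]);
      int oidx = step + 1 - n_settle;          // output sample index
      if (oidx >= 0) {
        double vE2 = y[8] - y[10];
        if (!std::isfinite(vE2)) { bad = true; break; }
        double mE2 = sigm(vE2, two_e0, r, v0);
        for (int w = 0; w < 5; ++w)
          if (oidx >= win(w, 0) && oidx <= win(w, 1) && mE2 > wmax[w])
            wmax[w] = mE2;
      }
    }
    diverged[pidx] = bad ? 1 : 0;
    for (int w = 0; w < 5; ++w) maxima(pidx, w) = wmax[w];
    if (pidx % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["maxima"] = maxima, _["diverged"] = diverged);
}
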