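// Multi-state MASH trajectory kernel.
//
// All quantities arrive in internal "angular" units: energies/frequencies in
// rad/fs (hbar = 1), time in fs, mass-scaled nuclear coordinates.  The
// potential matrix in the site basis is
//   V_nn(q) = eps_n + sum_k kappa_k q_nk,   V_nm = J_nm  (n != m)
// with the state-independent bath potential sum_nk omega_k^2 q_nk^2 / 2
// tracked separately for energy bookkeeping.
//
// The local eigenbasis is refreshed every step by rotating V into the
// previous step's eigenbasis and polishing with Jacobi sweeps; along a
// trajectory the basis changes slowly, so this costs one or two sweeps and
// keeps eigenvector columns continuous (no resorting between steps).  All
// workspace is preallocated; the inner loops avoid heap traffic.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::uword;

namespace {

// SplitMix64: decorrelates (seed, trajectory index) pairs into stream seeds.
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Model {
  vec eps;      // site energies, rad/fs
  mat J;        // couplings, rad/fs
  vec omega;    // mode frequencies, rad/fs (shared across sites)
  vec kappa;    // linear coupling coefficients
  vec omega2;   // omega^2
  uword N, M;
};

struct Workspace {
  mat V, A, T, U;              // potential, rotation workspace, eigenvectors
  vec E;                       // eigenvalues (unsorted, column-continuous)
  mat q, p, F, qmid, d;        // nuclear arrays (N x M)
  vec cr, ci, ar, ai, ar2, ai2, br, bi, P, cph, sph, ph;
  bool fresh;
  explicit Workspace(uword N, uword M)
      : V(N, N), A(N, N), T(N, N), U(N, N), E(N), q(N, M), p(N, M), F(N, M),
        qmid(N, M), d(N, M), cr(N), ci(N), ar(N), ai(N), ar2(N), ai2(N),
        br(N), bi(N), P(N), cph(N), sph(N), ph(N), fresh(true) {}
};

// Diagonalize symmetric V into ws.U/ws.E, warm-starting from the previous
// basis.  First call (ws.fresh) uses LAPACK; later calls rotate and polish.
void eig_refresh(const mat& V, Workspace& ws) {
  const uword n = V.n_rows;
  if (ws.fresh) {
    arma::eig_sym(ws.E, ws.U, V);
    ws.fresh = false;
    return;
  }
  ws.T = V * ws.U;
  ws.A = ws.U.t() * ws.T;  // nearly diagonal
  mat& A = ws.A;
  double amax = 0.0;
  for (uword i = 0; i < n; ++i) amax = std::max(amax, std::abs(A(i, i)));
  const double tol = 1e-13 * (1.0 + amax);
  for (int sweep = 0; sweep < 60; ++sweep) {
    double off = 0.0;
    for (uword p_ = 0; p_ + 1 < n; ++p_)
      for (uword q_ = p_ + 1; q_ < n; ++q_)
        off = std::max(off, std::abs(A(p_, q_)));
    if (off <= tol) break;
    for (uword p_ = 0; p_ + 1 < n; ++p_) {
      for (uword q_ = p_ + 1; q_ < n; ++q_) {
        const double apq = A(p_, q_);
        if (std::abs(apq) <= tol) continue;
        const double app = A(p_, p_), aqq = A(q_, q_);
        const double theta = (aqq - app) / (2.0 * apq);
        const double t = (theta >= 0 ? 1.0 : -1.0) /
                         (std::abs(theta) + std::sqrt(theta * theta + 1.0));
        const double c = 1.0 / std::sqrt(t * t + 1.0);
        const double s = t * c;
        for (uword k = 0; k < n; ++k) {
          if (k == p_ || k == q_) continue;
          const double akp = A(k, p_), akq = A(k, q_);
          A(k, p_) = A(p_, k) = c * akp - s * akq;
          A(k, q_) = A(q_, k) = s * akp + c * akq;
        }
        A(p_, p_) = app - t * apq;
        A(q_, q_) = aqq + t * apq;
        A(p_, q_) = A(q_, p_) = 0.0;
        double* up = ws.U.colptr(p_);
        double* uq = ws.U.colptr(q_);
        for (uword k = 0; k < n; ++k) {
          const double ukp = up[k], ukq = uq[k];
          up[k] = c * ukp - s * ukq;
          uq[k] = s * ukp + c * ukq;
        }
      }
    }
  }
  for (uword i = 0; i < n; ++i) ws.E(i) = A(i, i);
}

inline void build_V(const Model& mdl, const mat& q, mat& V) {
  V = mdl.J;
  for (uword n = 0; n < mdl.N; ++n) {
    double dsum = mdl.eps(n);
    const double* kap = mdl.kappa.memptr();
    for (uword k = 0; k < mdl.M; ++k) dsum += kap[k] * q(n, k);
    V(n, n) = dsum;
  }
}

// force F = -omega^2 q - kappa * U_{n,act}^2 (the second term is the
// excitonic back-action; absent in the no-back-action baseline)
inline void build_force(const Model& mdl, const mat& q, const mat& U,
                        int act, bool backaction, mat& F) {
  const double* w2 = mdl.omega2.memptr();
  const double* kap = mdl.kappa.memptr();
  for (uword k = 0; k < mdl.M; ++k) {
    const double* qc = q.colptr(k);
    double* fc = F.colptr(k);
    for (uword n = 0; n < mdl.N; ++n) fc[n] = -w2[k] * qc[n];
  }
  if (backaction) {
    for (uword n = 0; n < mdl.N; ++n) {
      const double wn = U(n, (uword)act) * U(n, (uword)act);
      for (uword k = 0; k < mdl.M; ++k) F(n, k) -= kap[k] * wn;
    }
  }
}

struct TrajConfig {
  double dt;
  int nsteps, stride;
  int init_site;      // 0-based
  int sampling;       // 0 classical Boltzmann, 1 Wigner
  bool backaction;    // true: MASH; false: no-back-action baseline
  double kT;          // rad/fs
};

struct HopEvent { int step, from, to, accepted; double dE; };

// Run one trajectory; accumulate |c_n|^2 into pops (N x nout).  Returns
// false if the trajectory went non-finite.
bool run_traj(const Model& mdl, const TrajConfig& cfg, std::mt19937_64& rng,
              Workspace& ws, mat& pops, vec* energy_out, vec* norm_out,
              std::vector<HopEvent>* hops) {
  const uword N = mdl.N, M = mdl.M;
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 2.0 * M_PI);
  ws.fresh = true;

  // nuclear initial conditions: thermal distribution centered at q = 0
  // (vertical excitation) or, for sampling == 2, at the displaced minimum
  // of the initially excited site (relaxed start; used for equilibrium
  // checks, where the vertical start's extra reorganization energy would
  // heat the finite microcanonical bath above the target temperature)
  for (uword k = 0; k < M; ++k) {
    double sq, sp;
    const double w = mdl.omega(k);
    if (cfg.sampling == 1) {          // Wigner (thermal harmonic oscillator)
      const double cth = 1.0 / std::tanh(w / (2.0 * cfg.kT));
      sq = std::sqrt(cth / (2.0 * w));
      sp = std::sqrt(w * cth / 2.0);
    } else {                          // classical Boltzmann
      sq = std::sqrt(cfg.kT) / w;
      sp = std::sqrt(cfg.kT);
    }
    const double qc = (cfg.sampling == 2) ? -mdl.kappa(k) / (w * w) : 0.0;
    for (uword n = 0; n < N; ++n) {
      ws.q(n, k) = sq * gauss(rng) +
                   (((int)n == cfg.init_site) ? qc : 0.0);
      ws.p(n, k) = sp * gauss(rng);
    }
  }

  // focused excitonic initial condition
  double HN = 0.0;
  for (uword n = 1; n <= N; ++n) HN += 1.0 / n;
  const double alpha = (N - 1.0) / (HN - 1.0);
  const double ri = std::sqrt((N - 1.0 + alpha) / (N * alpha));
  const double ro = std::sqrt((alpha - 1.0) / (N * alpha));
  for (uword n = 0; n < N; ++n) {
    const double r = ((int)n == cfg.init_site) ? ri : ro;
    const double phi = unif(rng);
    ws.cr(n) = r * std::cos(phi);
    ws.ci(n) = r * std::sin(phi);
  }

  build_V(mdl, ws.q, ws.V);
  eig_refresh(ws.V, ws);
  ws.br = ws.U.t() * ws.cr;
  ws.bi = ws.U.t() * ws.ci;
  ws.P = ws.br % ws.br + ws.bi % ws.bi;
  int act = (int)ws.P.index_max();

  int iout = 0;
  auto record = [&](int slot) {
    double* pc = pops.colptr(slot);
    // populations are normalized at readout so the estimator sum rule
    // holds exactly despite ~1e-10 norm drift from the eigenbasis refresh
    double nrm2 = 0.0;
    for (uword n = 0; n < N; ++n)
      nrm2 += ws.cr(n) * ws.cr(n) + ws.ci(n) * ws.ci(n);
    for (uword n = 0; n < N; ++n)
      pc[n] += (ws.cr(n) * ws.cr(n) + ws.ci(n) * ws.ci(n)) / nrm2;
    if (energy_out) {
      double e = ws.E((uword)act);
      for (uword k = 0; k < M; ++k)
        for (uword n = 0; n < N; ++n)
          e += 0.5 * ws.p(n, k) * ws.p(n, k) +
               0.5 * mdl.omega2(k) * ws.q(n, k) * ws.q(n, k);
      (*energy_out)(slot) = e;
    }
    if (norm_out)
      (*norm_out)(slot) = arma::accu(ws.cr % ws.cr + ws.ci % ws.ci);
  };
  record(iout++);

  // unitary half-step exp(-i V dt/2) applied to c in the current eigenbasis
  auto half_propagate = [&](double dt) {
    ws.ar = ws.U.t() * ws.cr;
    ws.ai = ws.U.t() * ws.ci;
    for (uword n = 0; n < N; ++n) {
      const double phn = ws.E(n) * (0.5 * dt);
      const double cn = std::cos(phn), sn = std::sin(phn);
      ws.ar2(n) = ws.ar(n) * cn + ws.ai(n) * sn;
      ws.ai2(n) = ws.ai(n) * cn - ws.ar(n) * sn;
    }
    ws.cr = ws.U * ws.ar2;
    ws.ci = ws.U * ws.ai2;
  };

  const double dt = cfg.dt;
  for (int step = 1; step <= cfg.nsteps; ++step) {
    build_force(mdl, ws.q, ws.U, act, cfg.backaction, ws.F);
    ws.p += (0.5 * dt) * ws.F;

    // Strang-split coefficient propagation: exp(-i V(q_new) dt/2)
    // exp(-i V(q_old) dt/2), symmetric and unitary by construction, with
    // both factors exact in their instantaneous eigenbases.  The first
    // half-step reuses the eigendecomposition already in hand at q_old.
    half_propagate(dt);
    ws.q += dt * ws.p;
    build_V(mdl, ws.q, ws.V);
    eig_refresh(ws.V, ws);
    half_propagate(dt);

    build_force(mdl, ws.q, ws.U, act, cfg.backaction, ws.F);
    ws.p += (0.5 * dt) * ws.F;

    if (cfg.backaction) {
      ws.br = ws.U.t() * ws.cr;
      ws.bi = ws.U.t() * ws.ci;
      ws.P = ws.br % ws.br + ws.bi % ws.bi;
      int amax = (int)ws.P.index_max();
      if (amax != act && ws.P((uword)amax) > ws.P((uword)act)) {
        const double dE = ws.E((uword)amax) - ws.E((uword)act);
        if (std::abs(dE) < 1e-14) {
          if (hops) hops->push_back({step, act, amax, 1, dE});
          act = amax;  // degenerate surfaces: free switch
        } else {
          // hop direction along the projected nonadiabatic coupling
          double dn2 = 0.0;
          for (uword n = 0; n < N; ++n) {
            const double un = ws.U(n, (uword)act) * ws.U(n, (uword)amax);
            for (uword k = 0; k < M; ++k) {
              const double v = mdl.kappa(k) * un;
              ws.d(n, k) = v;
              dn2 += v * v;
            }
          }
          if (dn2 < 1e-300) {
            // degenerate direction: fall back to uniform momentum rescaling
            const double ke = 0.5 * arma::accu(ws.p % ws.p);
            if (ke > dE) {
              if (hops) hops->push_back({step, act, amax, 2, dE});
              ws.p *= std::sqrt((ke - dE) / ke);
              act = amax;
            }
          } else {
            const double dn = std::sqrt(dn2);
            double pd = 0.0;
            for (uword k = 0; k < M; ++k)
              for (uword n = 0; n < N; ++n) pd += ws.p(n, k) * ws.d(n, k);
            pd /= dn;
            const double disc = pd * pd - 2.0 * dE;
            if (disc >= 0.0) {
              const double gam = (pd >= 0.0) ? (-pd + std::sqrt(disc))
                                             : (-pd - std::sqrt(disc));
              ws.p += (gam / dn) * ws.d;
              if (hops) hops->push_back({step, act, amax, 1, dE});
              act = amax;
            } else {
              ws.p -= (2.0 * pd / dn) * ws.d;  // frustrated: reflect
              if (hops) hops->push_back({step, act, amax, 0, dE});
            }
          }
        }
      }
    }

    if (step % cfg.stride == 0) {
      if (!ws.cr.is_finite() || !ws.ci.is_finite() || !ws.q.is_finite())
        return false;
      record(iout++);
    }
  }
  return true;
}

Model make_model(const vec& eps, const mat& J, const vec& omega, const vec& kappa) {
  Model mdl;
  mdl.eps = eps;
  mdl.J = J;
  mdl.omega = omega;
  mdl.kappa = kappa;
  mdl.omega2 = omega % omega;
  mdl.N = eps.n_elem;
  mdl.M = omega.n_elem;
  return mdl;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List mash_ensemble_cpp(const arma::vec& eps, const arma::mat& J,
                             const arma::vec& omega, const arma::vec& kappa,
                             double kT, double dt, int nsteps, int stride,
                             int ntraj, int nbatch, double seed, int init_site,
                             int sampling, bool backaction) {
  const Model mdl = make_model(eps, J, omega, kappa);
  TrajConfig cfg{dt, nsteps, stride, init_site, sampling, backaction, kT};
  const int nout = nsteps / stride + 1;
  arma::cube csum(mdl.N, nout, nbatch, arma::fill::zeros);
  arma::ivec counts(nbatch, arma::fill::zeros);
  arma::ivec discards(nbatch, arma::fill::zeros);
  mat pops(mdl.N, nout);
  Workspace ws(mdl.N, mdl.M);
  const uint64_t seed0 = (uint64_t)seed;
  for (int j = 0; j < ntraj; ++j) {
    const int b = j % nbatch;
    std::mt19937_64 rng(splitmix64(seed0 ^ splitmix64((uint64_t)j + 1)));
    pops.zeros();
    if (run_traj(mdl, cfg, rng, ws, pops, nullptr, nullptr, nullptr)) {
      csum.slice(b) += pops;
      counts(b) += 1;
    } else {
      discards(b) += 1;
    }
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("csum") = csum,
      Rcpp::Named("counts") = counts,
      Rcpp::Named("discards") = discards);
}

// [[Rcpp::export]]
Rcpp::List mash_trajectory_cpp(const arma::vec& eps, const arma::mat& J,
                               const arma::vec& omega, const arma::vec& kappa,
                               double kT, double dt, int nsteps, int stride,
                               double seed, int traj_index, int init_site,
                               int sampling, bool backaction) {
  const Model mdl = make_model(eps, J, omega, kappa);
  TrajConfig cfg{dt, nsteps, stride, init_site, sampling, backaction, kT};
  const int nout = nsteps / stride + 1;
  mat pops(mdl.N, nout, arma::fill::zeros);
  vec energy(nout), nrm(nout);
  std::vector<HopEvent> hops;
  Workspace ws(mdl.N, mdl.M);
  std::mt19937_64 rng(
      splitmix64((uint64_t)seed ^ splitmix64((uint64_t)traj_index + 1)));
  const bool ok = run_traj(mdl, cfg, rng, ws, pops, &energy, &nrm, &hops);
  arma::imat hoplog(hops.size(), 4);
  vec hopde(hops.size());
  for (size_t i = 0; i < hops.size(); ++i) {
    hoplog(i, 0) = hops[i].step;
    hoplog(i, 1) = hops[i].from + 1;
    hoplog(i, 2) = hops[i].to + 1;
    hoplog(i, 3) = hops[i].accepted;
    hopde(i) = hops[i].dE;
  }
  return Rcpp::List::create(
      Rcpp::Named("pops") = pops, Rcpp::Named("energy") = energy,
      Rcpp::Named("norm") = nrm, Rcpp::Named("hops") = hoplog,
      Rcpp::Named("hop_dE") = hopde, Rcpp::Named("ok") = ok);
}
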