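// Core numerics: forward-Euler integration of the coupled Hindmarsh-Rose
// brain dynamical network and tangent-space (Benettin / Gram-Schmidt)
// estimation of the two largest Lyapunov exponents.  Kept in C++ because
// network evolution needs O(10^2) Lyapunov runs per call.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct HRPar {
  double a, b, c, d, s, p0, Iext, r;
};
struct SynPar {
  double theta, lambda, Vsyn, gn, gl;
};

inline HRPar hr_from_list(const Rcpp::List& l) {
  HRPar h;
  h.a = l["a"]; h.b = l["b"]; h.c = l["c"]; h.d = l["d"];
  h.s = l["s"]; h.p0 = l["p0"]; h.Iext = l["I_ext"]; h.r = l["r"];
  return h;
}
inline SynPar syn_from_list(const Rcpp::List& l) {
  SynPar s;
  s.theta = l["theta_syn"]; s.lambda = l["lambda_sig"]; s.Vsyn = l["V_syn"];
  s.gn = l["g_n"]; s.gl = l["g_l"];
  return s;
}

// Orthonormalize two stacked tangent vectors in place; returns the two
// stretch factors (norms before normalization).  A degenerate vector is
// reinitialized to a canonical basis direction.
inline void gram_schmidt2(vec& u1, vec& u2, double& n1, double& n2,
                          bool& degenerate) {
  degenerate = false;
  n1 = norm(u1);
  if (n1 <= 0.0 || !std::isfinite(n1)) {
    u1.zeros(); u1(0) = 1.0; n1 = 1.0; degenerate = true;
  } else {
    u1 /= n1;
  }
  u2 -= dot(u2, u1) * u1;
  n2 = norm(u2);
  if (n2 <= 0.0 || !std::isfinite(n2)) {
    u2.zeros();
    u2(u2.n_elem > 1 ? 1 : 0) = 1.0;
    u2 -= dot(u2, u1) * u1;
    double nn = norm(u2);
    if (nn > 0) u2 /= nn;
    n2 = 1.0; degenerate = true;
  } else {
    u2 /= n2;
  }
}

} // namespace

// Integrate the coupled HR network (Euler, step dt) and optionally evolve two
// tangent vectors in the 3*N (p,q,n) space under the analytic Jacobian.
//
// A: electrical adjacency (symmetric binary); B: chemical adjacency.
// state0: vector c(p, q, n, phi) of length 4N.
// n_steps: total Euler steps; n_trans: steps belonging to the transient
// (statistics and Lyapunov accumulation start after n_trans).
// stride: record every `stride`-th sample into the returned trajectory
// (0 = record nothing). renorm_interval: Gram-Schmidt cadence in steps.
// want_lyap: evolve tangent vectors and accumulate exponents.
// [[Rcpp::export]]
Rcpp::List hr_run_cpp(const arma::mat& A, const arma::mat& B,
                      const arma::vec& state0,
                      const Rcpp::List& hr_par, const Rcpp::List& syn_par,
                      double dt, int n_steps, int n_trans,
                      int stride, bool want_lyap, int renorm_interval,
                      int history_max = 2000) {
  const HRPar hp = hr_from_list(hr_par);
  const SynPar sp = syn_from_list(syn_par);
  const uword N = A.n_rows;
  if (B.n_rows != N || state0.n_elem != 4 * N)
    Rcpp::stop("inconsistent network/state dimensions");

  vec p = state0.subvec(0, N - 1);
  vec q = state0.subvec(N, 2 * N - 1);
  vec n = state0.subvec(2 * N, 3 * N - 1);
  vec phi = state0.subvec(3 * N, 4 * N - 1);
  const vec kA = sum(A, 1);  // electrical degrees (Laplacian diagonal)

  // trajectory storage
  const int n_rec = (stride > 0) ? (n_steps / stride + 1) : 0;
  mat P, Q, Nn, PHI;
  vec rec_t;
  if (n_rec > 0) {
    P.set_size(n_rec, N); Q.set_size(n_rec, N);
    Nn.set_size(n_rec, N); PHI.set_size(n_rec, N);
    rec_t.set_size(n_rec);
  }
  int i_rec = 0;

  // tangent vectors (3N-dim, phi excluded: it never feeds back), stored as
  // N x 2 blocks so both vectors share each matrix product
  mat Up, Uq, Un, dUp, dUq, dUn, Utmp;
  double sum_log1 = 0.0, sum_log2 = 0.0, t_accum = 0.0, t_accum_start = 0.0;
  bool accum_started = false;
  int n_degenerate = 0;
  std::vector<double> hist_t, hist_l1, hist_l2;
  if (want_lyap) {
    Up.zeros(N, 2); Uq.zeros(N, 2); Un.zeros(N, 2);
    dUp.set_size(N, 2); dUq.set_size(N, 2); dUn.set_size(N, 2);
    Utmp.set_size(N, 2);
    // first two columns of the identity in (p, q, n) layout
    Up(0, 0) = 1.0;
    if (N > 1) Up(1, 1) = 1.0; else Uq(0, 1) = 1.0;
    hist_t.reserve(history_max); hist_l1.reserve(history_max);
    hist_l2.reserve(history_max);
  }
  const int hist_stride = std::max(
      1, (n_steps - n_trans) / std::max(renorm_interval, 1) / history_max + 1);
  int n_renorms_post = 0;

  // post-transient accumulators
  double rho_sum = 0.0;
  long rho_count = 0;
  double max_abs_p = 0.0;

  vec Sp(N), Bs(N), dp(N), dq(N), dn(N), dphi(N), p2(N);
  vec Sderiv(N), diagJ(N), coefn(N);

  auto record = [&](double t) {
    if (n_rec == 0 || i_rec >= n_rec) return;
    P.row(i_rec) = p.t(); Q.row(i_rec) = q.t();
    Nn.row(i_rec) = n.t(); PHI.row(i_rec) = phi.t();
    rec_t(i_rec) = t;
    ++i_rec;
  };
  record(0.0);

  for (int step = 0; step < n_steps; ++step) {
    // vector field
    p2 = p % p;
    Sp = 1.0 / (1.0 + exp(-sp.lambda * (p - sp.theta)));
    Bs = B * Sp;
    dp = q - hp.a * p2 % p + hp.b * p2 - n + hp.Iext
         - sp.gn * (p - sp.Vsyn) % Bs
         - sp.gl * (kA % p - A * p);
    dq = hp.c - hp.d * p2 - q;
    dn = hp.r * (hp.s * (p - hp.p0) - n);
    {
      vec denom = p % p + q % q;
      dphi = (dq % p - dp % q);
      for (uword i = 0; i < N; ++i)
        dphi(i) = denom(i) > 0.0 ? dphi(i) / denom(i) : 0.0;
    }

    if (want_lyap) {
      // analytic Jacobian applied to both tangent vectors at once
      Sderiv = sp.lambda * Sp % (1.0 - Sp);
      diagJ = -3.0 * hp.a * p2 + 2.0 * hp.b * p - sp.gn * Bs - sp.gl * kA;
      coefn = -sp.gn * (p - sp.Vsyn);
      Utmp = Up;
      Utmp.each_col() %= Sderiv;
      dUp = B * Utmp;
      dUp.each_col() %= coefn;
      dUp += sp.gl * (A * Up) + Uq - Un;
      Utmp = Up;
      Utmp.each_col() %= diagJ;
      dUp += Utmp;
      dUq = Up;
      dUq.each_col() %= (-2.0 * hp.d) * p;
      dUq -= Uq;
      dUn = (hp.r * hp.s) * Up - hp.r * Un;
      Up += dt * dUp;
      Uq += dt * dUq;
      Un += dt * dUn;
    }

    // Euler update
    p += dt * dp; q += dt * dq; n += dt * dn; phi += dt * dphi;
    const int step1 = step + 1;
    const double t = step1 * dt;
    const bool post = step1 > n_trans;

    if (want_lyap && (step1 % renorm_interval == 0 || step1 == n_steps)) {
      double n1, n2; bool degen;
      vec u1 = join_cols(Up.col(0), Uq.col(0), Un.col(0));
      vec u2 = join_cols(Up.col(1), Uq.col(1), Un.col(1));
      gram_schmidt2(u1, u2, n1, n2, degen);
      Up.col(0) = u1.subvec(0, N - 1);
      Uq.col(0) = u1.subvec(N, 2 * N - 1);
      Un.col(0) = u1.subvec(2 * N, 3 * N - 1);
      Up.col(1) = u2.subvec(0, N - 1);
      Uq.col(1) = u2.subvec(N, 2 * N - 1);
      Un.col(1) = u2.subvec(2 * N, 3 * N - 1);
      if (degen) ++n_degenerate;
      if (post) {
        if (!accum_started) {
          // discard the interval straddling the transient cutoff
          accum_started = true;
          t_accum_start = t;
        } else {
          sum_log1 += std::log(n1);
          sum_log2 += std::log(n2);
          t_accum = t - t_accum_start;
          ++n_renorms_post;
          if (t_accum > 0 && (n_renorms_post % hist_stride == 0)) {
            const double r1 = sum_log1 / t_accum, r2 = sum_log2 / t_accum;
            hist_t.push_back(t);
            hist_l1.push_back(std::max(r1, r2));
            hist_l2.push_back(std::min(r1, r2));
          }
        }
      }
    }

    if (post) {
      double mc = 0.0, ms = 0.0;
      for (uword i = 0; i < N; ++i) { mc += std::cos(phi(i)); ms += std::sin(phi(i)); }
      mc /= N; ms /= N;
      rho_sum += std::sqrt(mc * mc + ms * ms);
      ++rho_count;
      double mp = abs(p).max();
      if (mp > max_abs_p) max_abs_p = mp;
    }

    if (stride > 0 && step1 % stride == 0) record(t);

    if (step1 % 50 == 0 || step1 == n_steps) {
      if (!p.is_finite())
        Rcpp::stop("numerical overflow near step %d (t = %.2f), neuron %d",
                   step1, t, (int)(abs(p).index_max() + 1));
      Rcpp::checkUserInterrupt();
    }
  }

  double l1 = NA_REAL, l2 = NA_REAL;
  if (want_lyap && t_accum > 0) {
    l1 = sum_log1 / t_accum;
    l2 = sum_log2 / t_accum;
    if (l2 > l1) std::swap(l1, l2);  // sorted accumulation guarantee
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("lambda1") = l1, Rcpp::Named("lambda2") = l2,
      Rcpp::Named("rho") = rho_count > 0 ? rho_sum / rho_count : NA_REAL,
      Rcpp::Named("max_abs_p") = max_abs_p,
      Rcpp::Named("n_degenerate") = n_degenerate,
      Rcpp::Named("final_state") = join_cols(p, q, n, phi));
  if (want_lyap) {
    out["history"] = Rcpp::DataFrame::create(
        Rcpp::Named("time") = hist_t, Rcpp::Named("lambda1") = hist_l1,
        Rcpp::Named("lambda2") = hist_l2);
  }
  if (n_rec > 0) {
    out["times"] = rec_t.head(i_rec);
    out["p"] = P.head_rows(i_rec); out["q"] = Q.head_rows(i_rec);
    out["n_slow"] = Nn.head_rows(i_rec); out["phi"] = PHI.head_rows(i_rec);
  }
  return out;
}

// Benettin exponents of the linear system x' = M x (same machinery:
// Euler tangent steps + periodic Gram-Schmidt).  Used to validate the
// method against systems with known eigenvalue real parts.
// [[Rcpp::export]]
Rcpp::List lyap_linear_cpp(const arma::mat& M, double dt, int n_steps,
                           int n_trans, int renorm_interval) {
  const uword m = M.n_rows;
  if (m < 2) Rcpp::stop("need dimension >= 2");
  vec u1(m, fill::zeros), u2(m, fill::zeros);
  u1(0) = 1.0; u2(1) = 1.0;
  double s1 = 0.0, s2 = 0.0, t0 = 0.0, t_acc = 0.0;
  bool started = false;
  int n_degenerate = 0;
  for (int step = 1; step <= n_steps; ++step) {
    u1 += dt * (M * u1);
    u2 += dt * (M * u2);
    if (step % renorm_interval == 0 || step == n_steps) {
      double n1, n2; bool degen;
      gram_schmidt2(u1, u2, n1, n2, degen);
      if (degen) ++n_degenerate;
      if (step > n_trans) {
        if (!started) {  // discard the interval straddling the cutoff
          started = true;
          t0 = step * dt;
        } else {
          s1 += std::log(n1); s2 += std::log(n2);
          t_acc = step * dt - t0;
        }
      }
    }
  }
  if (t_acc <= 0) Rcpp::stop("no post-transient accumulation interval");
  double l1 = s1 / t_acc, l2 = s2 / t_acc;
  if (l2 > l1) std::swap(l1, l2);
  return Rcpp::List::create(Rcpp::Named("lambda1") = l1,
                            Rcpp::Named("lambda2") = l2,
                            Rcpp::Named("n_degenerate") = n_degenerate);
}
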