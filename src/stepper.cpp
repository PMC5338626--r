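// Explicit Runge-Kutta (orders 2 and 4) time integration of the
// finite-volume semi-discretization of the coupled analyte/peroxide radial
// reaction-diffusion equations.
//
// State: analyte A on the full radial grid (zero flux at the core face,
// Dirichlet A_outer at the outer face) and peroxide H on the prefix of the
// grid inside the H boundary (Dirichlet zero at both end faces).  Cell
// balances use precomputed face conductances g (already including the
// cylindrical face radius and the distance-weighted alpha*theta*D
// transmission), free-volume-weighted cell volumes, and linear reaction
// terms: dA source alpha*V*v*(target - A), dH source alpha*V*v_b*A in the
// enzyme layer.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Problem {
  int nA, nH;
  std::vector<double> gA, gH;       // nA+1, nH+1 face conductances
  std::vector<double> volA, volH;   // alpha * cell volume
  std::vector<double> vA, targA;    // reaction rate and relaxation target
  std::vector<double> prodH;        // alpha * v_b per H cell (0 outside enzyme)
  double A_outer;

  void rhs(const std::vector<double>& A, const std::vector<double>& H,
           std::vector<double>& dA, std::vector<double>& dH) const {
    for (int i = 0; i < nA; ++i) {
      double flux = 0.0;
      if (i > 0) flux += gA[i] * (A[i - 1] - A[i]);
      // core face (i == 0) has zero analyte flux
      if (i < nA - 1) {
        flux += gA[i + 1] * (A[i + 1] - A[i]);
      } else {
        flux += gA[nA] * (A_outer - A[i]);
      }
      dA[i] = (flux + volA[i] * vA[i] * (targA[i] - A[i])) / volA[i];
    }
    for (int i = 0; i < nH; ++i) {
      double flux = 0.0;
      flux += (i > 0) ? gH[i] * (H[i - 1] - H[i]) : gH[0] * (0.0 - H[i]);
      flux += (i < nH - 1) ? gH[i + 1] * (H[i + 1] - H[i])
                           : gH[nH] * (0.0 - H[i]);
      dH[i] = (flux + volH[i] * prodH[i] * A[i]) / volH[i];
    }
  }
};

inline void axpy(std::vector<double>& out, const std::vector<double>& x,
                 const std::vector<double>& d, double a) {
  for (size_t i = 0; i < x.size(); ++i) out[i] = x[i] + a * d[i];
}

} // namespace

// [[Rcpp::export]]
List rk_integrate_cpp(NumericVector A0, NumericVector H0,
                      NumericVector gA, NumericVector gH,
                      NumericVector volA, NumericVector volH,
                      NumericVector vA, NumericVector targA,
                      NumericVector prodH,
                      double A_outer, double dt, int n_steps, int order,
                      int record_every, IntegerVector snap_steps,
                      double current_scale) {
  Problem pb;
  pb.nA = A0.size();
  pb.nH = H0.size();
  pb.gA = as<std::vector<double>>(gA);
  pb.gH = as<std::vector<double>>(gH);
  pb.volA = as<std::vector<double>>(volA);
  pb.volH = as<std::vector<double>>(volH);
  pb.vA = as<std::vector<double>>(vA);
  pb.targA = as<std::vector<double>>(targA);
  pb.prodH = as<std::vector<double>>(prodH);
  pb.A_outer = A_outer;

  std::vector<double> A = as<std::vector<double>>(A0);
  std::vector<double> H = as<std::vector<double>>(H0);
  std::vector<double> kA1(pb.nA), kA2(pb.nA), kA3(pb.nA), kA4(pb.nA), At(pb.nA);
  std::vector<double> kH1(pb.nH), kH2(pb.nH), kH3(pb.nH), kH4(pb.nH), Ht(pb.nH);

  std::vector<double> rec_t, rec_I;
  rec_t.reserve(n_steps / std::max(record_every, 1) + 2);
  rec_I.reserve(rec_t.capacity());
  List snaps;

  double current = current_scale * pb.gH[0] * (pb.nH > 0 ? H[0] : 0.0);
  rec_t.push_back(0.0);
  rec_I.push_back(current);

  int snap_i = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (order == 4) {
      pb.rhs(A, H, kA1, kH1);
      axpy(At, A, kA1, dt / 2); axpy(Ht, H, kH1, dt / 2);
      pb.rhs(At, Ht, kA2, kH2);
      axpy(At, A, kA2, dt / 2); axpy(Ht, H, kH2, dt / 2);
      pb.rhs(At, Ht, kA3, kH3);
      axpy(At, A, kA3, dt); axpy(Ht, H, kH3, dt);
      pb.rhs(At, Ht, kA4, kH4);
      for (int i = 0; i < pb.nA; ++i)
        A[i] += dt / 6 * (kA1[i] + 2 * kA2[i] + 2 * kA3[i] + kA4[i]);
      for (int i = 0; i < pb.nH; ++i)
        H[i] += dt / 6 * (kH1[i] + 2 * kH2[i] + 2 * kH3[i] + kH4[i]);
    } else { // order 2 (midpoint)
      pb.rhs(A, H, kA1, kH1);
      axpy(At, A, kA1, dt / 2); axpy(Ht, H, kH1, dt / 2);
      pb.rhs(At, Ht, kA2, kH2);
      for (int i = 0; i < pb.nA; ++i) A[i] += dt * kA2[i];
      for (int i = 0; i < pb.nH; ++i) H[i] += dt * kH2[i];
    }

    if (step % record_every == 0 || step == n_steps) {
      current = current_scale * pb.gH[0] * (pb.nH > 0 ? H[0] : 0.0);
      rec_t.push_back(step * dt);
      rec_I.push_back(current);
    }
    if (snap_i < snap_steps.size() && step == snap_steps[snap_i]) {
      snaps.push_back(List::create(_["step"] = step,
                                   _["time"] = step * dt,
                                   _["A"] = NumericVector(A.begin(), A.end()),
                                   _["H"] = NumericVector(H.begin(), H.end())));
      ++snap_i;
    }
  }

  return List::create(_["times"] = NumericVector(rec_t.begin(), rec_t.end()),
                      _["current"] = NumericVector(rec_I.begin(), rec_I.end()),
                      _["A"] = NumericVector(A.begin(), A.end()),
                      _["H"] = NumericVector(H.begin(), H.end()),
                      _["snapshots"] = snaps);
}
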