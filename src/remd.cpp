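#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis Monte Carlo propagation of the reduced three-dihedral model,
// with optional Hamiltonian replica exchange over a ladder of torsion
// force constants. Angles are handled in radians internally; the one-fold
// trans-destabilizing bias and the smooth state-coupling term are present
// in every replica. Randomness comes from R's RNG (seeded from R).

static const double TWOPI = 2.0 * M_PI;

static inline double wrap_rad(double w) {
  // canonical interval [-pi, pi)
  return w - TWOPI * std::floor((w + M_PI) / TWOPI);
}

// physical torsion profile per unit force constant:
// 4 * (1 + cos(2w - pi)) = 4 * (1 - cos 2w)
static inline double torsion_shape(double w) {
  return 4.0 * (1.0 - std::cos(2.0 * w));
}

struct Coupling {
  double off[8];
  bool trans[8][3];  // is residue j trans in state s
  bool active;
};

// smooth coupling energy given the three cis weights wc = (1+cos w)/2
static inline double coupling_energy(const Coupling &cp, const double *wc) {
  if (!cp.active) return 0.0;
  double u = 0.0;
  for (int s = 0; s < 8; ++s) {
    if (cp.off[s] == 0.0) continue;
    double prod = cp.off[s];
    for (int j = 0; j < 3; ++j) {
      prod *= cp.trans[s][j] ? (1.0 - wc[j]) : wc[j];
    }
    u += prod;
  }
  return u;
}

// full potential energy of one configuration at ladder level V
static double total_energy(const double *w, double V, double biasV,
                           const Coupling &cp) {
  double u = 0.0, wc[3];
  for (int j = 0; j < 3; ++j) {
    u += V * torsion_shape(w[j]);
    u += biasV * (1.0 - std::cos(w[j]));  // bias: V(1 + cos(w - pi))
    wc[j] = 0.5 * (1.0 + std::cos(w[j]));
  }
  return u + coupling_energy(cp, wc);
}

// [[Rcpp::export(.run_remd_cpp)]]
List run_remd_cpp(NumericVector force_constants, NumericVector offsets,
                  LogicalMatrix state_trans, double bias_force_constant,
                  double temperature, int n_sweeps, int n_burn,
                  int exchange_every, int save_stride, double step_sigma_deg,
                  NumericMatrix start) {
  const int R = force_constants.size();
  if (R < 1) stop("need at least one replica");
  if (start.nrow() != R || start.ncol() != 3) {
    stop("`start` must be an n_replicas x 3 matrix");
  }
  const double beta = 1.0 / (0.0019872 * temperature);
  const double sigma = step_sigma_deg * M_PI / 180.0;

  Coupling cp;
  cp.active = false;
  for (int s = 0; s < 8; ++s) {
    cp.off[s] = offsets[s];
    if (offsets[s] != 0.0) cp.active = true;
    for (int j = 0; j < 3; ++j) cp.trans[s][j] = state_trans(s, j);
  }

  // configuration per replica (radians)
  std::vector<std::array<double, 3>> conf(R);
  for (int r = 0; r < R; ++r)
    for (int j = 0; j < 3; ++j)
      conf[r][j] = wrap_rad(start(r, j) * M_PI / 180.0);

  const int n_saved = (save_stride > 0) ? n_sweeps / save_stride : 0;
  // frames stored replica-major: list of n_saved x 3 matrices
  std::vector<NumericMatrix> frames;
  for (int r = 0; r < R; ++r) frames.push_back(NumericMatrix(n_saved, 3));
  IntegerVector saved_step(n_saved);

  const int n_pairs = (R > 1) ? R - 1 : 0;
  IntegerVector attempts(n_pairs), accepts(n_pairs);

  int n_attempt_rounds = 0;
  int isave = 0;
  const int total_sweeps = n_burn + n_sweeps;

  for (int sweep = 1; sweep <= total_sweeps; ++sweep) {
    for (int r = 0; r < R; ++r) {
      const double V = force_constants[r];
      double wc[3];
      for (int j = 0; j < 3; ++j)
        wc[j] = 0.5 * (1.0 + std::cos(conf[r][j]));
      for (int j = 0; j < 3; ++j) {
        const double w_old = conf[r][j];
        const double w_new = wrap_rad(w_old + sigma * R::norm_rand());
        const double wc_new = 0.5 * (1.0 + std::cos(w_new));
        double dU = V * (torsion_shape(w_new) - torsion_shape(w_old)) +
                    bias_force_constant * (std::cos(w_old) - std::cos(w_new));
        if (cp.active) {
          const double wc_old = wc[j];
          double u_old = coupling_energy(cp, wc);
          wc[j] = wc_new;
          double u_new = coupling_energy(cp, wc);
          dU += u_new - u_old;
          if (dU <= 0.0 || R::unif_rand() < std::exp(-beta * dU)) {
            conf[r][j] = w_new;
          } else {
            wc[j] = wc_old;  // reject: restore cached weight
          }
        } else {
          if (dU <= 0.0 || R::unif_rand() < std::exp(-beta * dU)) {
            conf[r][j] = w_new;
            wc[j] = wc_new;
          }
        }
      }
    }

    // neighbor exchanges, alternating even/odd pairs
    if (exchange_every > 0 && n_pairs > 0 && sweep % exchange_every == 0) {
      const int parity = n_attempt_rounds % 2;
      ++n_attempt_rounds;
      for (int p = parity; p < n_pairs; p += 2) {
        const int a = p, b = p + 1;
        const double uaa = total_energy(conf[a].data(), force_constants[a],
                                        bias_force_constant, cp);
        const double ubb = total_energy(conf[b].data(), force_constants[b],
                                        bias_force_constant, cp);
        const double uab = total_energy(conf[b].data(), force_constants[a],
                                        bias_force_constant, cp);
        const double uba = total_energy(conf[a].data(), force_constants[b],
                                        bias_force_constant, cp);
        const double delta = beta * (uab + uba - uaa - ubb);
        ++attempts[p];
        if (delta <= 0.0 || R::unif_rand() < std::exp(-delta)) {
          std::swap(conf[a], conf[b]);  // swap configurations, not Hamiltonians
          ++accepts[p];
        }
      }
    }

    if (sweep > n_burn && save_stride > 0 &&
        (sweep - n_burn) % save_stride == 0 && isave < n_saved) {
      for (int r = 0; r < R; ++r)
        for (int j = 0; j < 3; ++j)
          frames[r](isave, j) = conf[r][j] * 180.0 / M_PI;
      saved_step[isave] = sweep - n_burn;
      ++isave;
    }
  }

  List frame_list(R);
  for (int r = 0; r < R; ++r) frame_list[r] = frames[r];
  return List::create(
    _["frames"] = frame_list,
    _["step"] = saved_step,
    _["attempts"] = attempts,
    _["accepts"] = accepts
  );
}
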