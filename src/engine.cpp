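// Fixed-time-step lattice Monte Carlo engine for integrin clustering.
//
// States: 0 INACTIVE, 1 ACTIVE, 2 BOUND, 3 ASSOCIATED. Transitions move
// along adjacent rungs of the ladder only. Each step (duration dt) visits
// every integrin in a freshly shuffled order and propagates its reaction
// ladder through the full step by first-reaction kinetics: competing
// Poisson channels, exponential waiting times, sub-stepping until the step
// budget dt is exhausted. This is exact for the single-integrin channels at
// any dt (the inactivation rate alone has k*dt ~ 2 with the default
// constants, so single-event-per-step schemes distort the stationary
// occupancies). Neighbour context is re-read at every sub-event; positions
// only change in the diffusion phase.
//
// An integrin that fired no reaction during its step and is not associated
// attempts one diffusion hop to a uniformly chosen 4-neighbour, rejected if
// the target site is occupied. After all integrins have been visited,
// associated integrins left without an associated 4-neighbour are demoted
// to BOUND (iterated to the unique fixpoint), so the associated set is
// always a union of lattice-connected clusters of size >= 2.
//
// All randomness comes from R's RNG, so set.seed() in R gives bit-identical
// trajectories.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const int INACTIVE = 0, ACTIVE = 1, BOUND = 2, ASSOC = 3;

inline int wrap(int x, int n) { return (x % n + n) % n; }

struct Grid {
  int nr, nc;
  inline int site(int r, int c) const { return r * nc + c; }
  inline void neighbors(int r, int c, int* nb) const {
    nb[0] = site(wrap(r - 1, nr), c);
    nb[1] = site(wrap(r + 1, nr), c);
    nb[2] = site(r, wrap(c - 1, nc));
    nb[3] = site(r, wrap(c + 1, nc));
  }
};

inline int rand_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

inline double rand_exp() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0);
  return -std::log(u);
}

// demote associated integrins without an associated 4-neighbour; iterated
// to the fixpoint (the maximal associated set whose members all keep a
// partner), which is order-independent
void orphan_cleanup(const Grid& g, IntegerVector& state,
                    const IntegerVector& row, const IntegerVector& col,
                    const IntegerVector& occ) {
  int n = state.size();
  int nb[4];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < n; ++i) {
      if (state[i] != ASSOC) continue;
      g.neighbors(row[i], col[i], nb);
      bool partner = false;
      for (int d = 0; d < 4; ++d) {
        int j = occ[nb[d]];
        if (j > 0 && state[j - 1] == ASSOC) { partner = true; break; }
      }
      if (!partner) { state[i] = BOUND; changed = true; }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(IntegerVector occ_in, IntegerVector row_in, IntegerVector col_in,
                IntegerVector state_in, int nr, int nc,
                double k_aplus, double k_aminus, double k_bplus,
                NumericVector k_bminus, double k_cplus, NumericVector k_cminus,
                double dt, double hop_prob, int n_steps,
                int checkpoint_every) {
  Grid g{nr, nc};
  IntegerVector occ = clone(occ_in);     // 0 = empty, else integrin id (1-based)
  IntegerVector row = clone(row_in);     // 0-based
  IntegerVector col = clone(col_in);
  IntegerVector state = clone(state_in);
  const int n = state.size();

  if (dt <= 0) stop("time step dt must be positive (got %g s)", dt);
  if (k_aplus < 0 || k_aminus < 0 || k_bplus < 0 || k_cplus < 0)
    stop("reaction rates must be non-negative");
  for (int s = 0; s < k_bminus.size(); ++s)
    if (k_bminus[s] < 0 || k_cminus[s] < 0)
      stop("per-site reverse rates must be non-negative");

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  int n_checkpoints = (checkpoint_every > 0) ? (n_steps / checkpoint_every) : 0;
  IntegerMatrix chk(n_checkpoints, 5); // step, nI, nA, nB, nAs
  int chk_row = 0;
  int nb[4];

  for (int step = 1; step <= n_steps; ++step) {
    // Fisher-Yates shuffle of the visiting order
    for (int i = n - 1; i > 0; --i) {
      int j = rand_int(i + 1);
      std::swap(order[i], order[j]);
    }

    for (int k = 0; k < n; ++k) {
      int i = order[k];
      int s = g.site(row[i], col[i]);
      bool fired = false;

      // first-reaction kinetics through the step budget dt
      double t_rem = dt;
      for (;;) {
        double rate[3];   // up to three competing channels
        int target[3];    // state after the channel fires
        int n_ch = 0;
        bool ch_assoc = false;
        int st = state[i];
        if (st == INACTIVE) {
          rate[n_ch] = k_aplus; target[n_ch++] = ACTIVE;
        } else if (st == ACTIVE) {
          rate[n_ch] = k_aminus; target[n_ch++] = INACTIVE;
          rate[n_ch] = k_bplus; target[n_ch++] = BOUND;
        } else if (st == BOUND) {
          rate[n_ch] = k_bminus[s]; target[n_ch++] = ACTIVE;
          // association requires a bound or associated 4-neighbour
          g.neighbors(row[i], col[i], nb);
          bool eligible = false;
          for (int d = 0; d < 4; ++d) {
            int j = occ[nb[d]];
            if (j > 0 && state[j - 1] >= BOUND) { eligible = true; break; }
          }
          if (eligible) {
            rate[n_ch] = k_cplus; target[n_ch] = ASSOC; ch_assoc = true;
            ++n_ch;
          }
        } else { // ASSOC
          rate[n_ch] = k_cminus[s]; target[n_ch++] = BOUND;
        }

        double total = 0.0;
        for (int c = 0; c < n_ch; ++c) total += rate[c];
        if (total <= 0.0) break;
        double tau = rand_exp() / total;
        if (tau > t_rem) break;
        t_rem -= tau;
        // pick the firing channel proportional to its rate
        int c = 0;
        if (n_ch > 1) {
          double u = unif_rand() * total, acc = 0.0;
          for (; c < n_ch - 1; ++c) {
            acc += rate[c];
            if (u < acc) break;
          }
        }
        state[i] = target[c];
        fired = true;
        if (target[c] == ASSOC && ch_assoc) {
          // pairwise nucleation: if no cluster is already adjacent, recruit
          // one uniformly chosen bound neighbour
          g.neighbors(row[i], col[i], nb);
          bool has_assoc_nb = false;
          int n_bound_nb = 0, bound_nb[4];
          for (int d = 0; d < 4; ++d) {
            int j = occ[nb[d]];
            if (j > 0 && j - 1 != i) {
              if (state[j - 1] == ASSOC) has_assoc_nb = true;
              else if (state[j - 1] == BOUND) bound_nb[n_bound_nb++] = j - 1;
            }
          }
          if (!has_assoc_nb) {
            if (n_bound_nb > 0) {
              int pick = bound_nb[n_bound_nb == 1 ? 0 : rand_int(n_bound_nb)];
              state[pick] = ASSOC;
            } else {
              // eligibility vanished between scans cannot happen (positions
              // are frozen during reactions), but stay safe
              state[i] = BOUND;
              fired = true;
            }
          }
        }
      }

      // diffusion attempt (associated integrins are immobilised)
      if (!fired && state[i] != ASSOC) {
        if (hop_prob >= 1.0 || unif_rand() < hop_prob) {
          g.neighbors(row[i], col[i], nb);
          int t = nb[rand_int(4)];
          if (occ[t] == 0) {
            occ[s] = 0;
            occ[t] = i + 1;
            row[i] = t / nc;
            col[i] = t % nc;
          }
        }
      }
    }

    orphan_cleanup(g, state, row, col, occ);

    if (checkpoint_every > 0 && step % checkpoint_every == 0) {
      int cnt[4] = {0, 0, 0, 0};
      for (int i = 0; i < n; ++i) ++cnt[state[i]];
      chk(chk_row, 0) = step;
      chk(chk_row, 1) = cnt[0];
      chk(chk_row, 2) = cnt[1];
      chk(chk_row, 3) = cnt[2];
      chk(chk_row, 4) = cnt[3];
      ++chk_row;
    }
  }

  return List::create(_["occ"] = occ, _["row"] = row, _["col"] = col,
                      _["state"] = state, _["checkpoints"] = chk);
}
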