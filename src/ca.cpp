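#include <Rcpp.h>
using namespace Rcpp;

// Stochastic cellular automaton of surface colonization under laminar flow.
// Site states: 0 = empty, 1 = blue, 2 = red. Grids are R matrices with the
// row index as the transverse coordinate and the column index as the flow
// axis (flow runs left -> right, i.e. towards increasing column). Both axes
// are periodic. All randomness is drawn from R's RNG so that set.seed() in
// R makes every run exactly reproducible.

static inline int rand_int(int n) {
  // uniform integer on {0, ..., n-1}
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Event codes shared with the R wrappers (see R/lattice.R):
//  0 no event; 1 birth into empty neighbour; 2 shove, resident displaced and
//  relocated; 3 shove, resident displaced and removed; 4 shove, newborn
//  placed next to resident; 5 shove, newborn removed; and for detachment:
//  1 drafting-eligible but no detachment, 2 detached and landed, 3 detached
//  and removed (landing site occupied).

struct CAState {
  IntegerMatrix grid;
  int ny, nx;
  std::vector<int> occ;  // linear (column-major) indices of occupied sites
  std::vector<int> pos;  // pos[idx] = index into occ, -1 when empty

  explicit CAState(IntegerMatrix g) : grid(g), ny(g.nrow()), nx(g.ncol()) {
    pos.assign((size_t)ny * nx, -1);
    for (int c = 0; c < nx; ++c)
      for (int r = 0; r < ny; ++r) {
        int idx = r + c * ny;
        if (grid[idx] != 0) {
          pos[idx] = (int)occ.size();
          occ.push_back(idx);
        }
      }
  }

  int n_occ() const { return (int)occ.size(); }

  void occupy(int idx, int color) {
    grid[idx] = color;
    pos[idx] = (int)occ.size();
    occ.push_back(idx);
  }

  void vacate(int idx) {
    int p = pos[idx];
    int last = occ.back();
    occ[p] = last;
    pos[last] = p;
    occ.pop_back();
    pos[idx] = -1;
    grid[idx] = 0;
  }

  // the 8 Moore neighbours of idx, periodic wrap
  void moore(int idx, int out[8]) const {
    int r = idx % ny, c = idx / ny;
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int rr = (r + dr + ny) % ny;
        int cc = (c + dc + nx) % nx;
        out[k++] = rr + cc * ny;
      }
  }

  int upstream(int idx) const {
    int r = idx % ny, c = idx / ny;
    return r + ((c - 1 + nx) % nx) * ny;
  }
};

// One birth attempt: with probability p_b a uniformly chosen occupied cell
// divides; the newborn goes to a random empty Moore neighbour, or failing
// that a single shove against a random resident neighbour is resolved with
// displacement probability p_s = (1 - sigma)/2. The losing cell moves to a
// random empty Moore neighbour of the resident's original site or is removed
// with the outflow. Shoves never cascade.
static int birth_attempt(CAState &st, double p_b, double p_s) {
  if (unif_rand() >= p_b) return 0;
  if (st.n_occ() == 0) return 0;
  int parent = st.occ[rand_int(st.n_occ())];
  int color = st.grid[parent];
  int nb[8], empt[8], ne = 0;
  st.moore(parent, nb);
  for (int k = 0; k < 8; ++k)
    if (st.grid[nb[k]] == 0) empt[ne++] = nb[k];
  if (ne > 0) {
    st.occupy(empt[rand_int(ne)], color);
    return 1;
  }
  // no empty neighbour: shove a random resident
  int resident = nb[rand_int(8)];
  int res_color = st.grid[resident];
  int rnb[8], rempt[8], rne = 0;
  st.moore(resident, rnb);
  for (int k = 0; k < 8; ++k)
    if (st.grid[rnb[k]] == 0) rempt[rne++] = rnb[k];
  bool resident_loses = unif_rand() < p_s;
  if (resident_loses) {
    st.grid[resident] = color;  // newborn takes the resident's site
    if (rne > 0) {
      st.occupy(rempt[rand_int(rne)], res_color);
      return 2;
    }
    return 3;  // resident removed with the outflow
  }
  if (rne > 0) {
    st.occupy(rempt[rand_int(rne)], color);
    return 4;
  }
  return 5;  // newborn removed with the outflow
}

// One detachment attempt: a uniformly chosen occupied cell detaches with
// probability p_d = f (1 - sigma) only if its directly upstream site is
// empty (drafting protection). A detached cell is relocated downstream by
// dx ~ U{0,...,floor(f L)}, dy ~ U{-dx,...,dx} (origin vacated first, so a
// dx = dy = 0 draw self-lands); an occupied landing site means loss with
// the outflow.
static int detach_attempt(CAState &st, double p_d, double f) {
  if (st.n_occ() == 0) return 0;
  int cell = st.occ[rand_int(st.n_occ())];
  if (st.grid[st.upstream(cell)] != 0) return 0;  // drafting protection
  if (unif_rand() >= p_d) return 1;
  int color = st.grid[cell];
  int r = cell % st.ny, c = cell / st.ny;
  int dxmax = (int)std::floor(f * st.nx);
  int dx = rand_int(dxmax + 1);
  int dy = rand_int(2 * dx + 1) - dx;
  st.vacate(cell);
  int land = ((r + dy) % st.ny + st.ny) % st.ny +
             (((c + dx) % st.nx) * st.ny);
  if (st.grid[land] == 0) {
    st.occupy(land, color);
    return 2;  // landed
  }
  return 3;  // landing site occupied: removed with the outflow
}

// [[Rcpp::export]]
List ca_birth_cpp(IntegerMatrix grid, double sigma, double p_b) {
  CAState st(clone(grid));
  double p_s = (1.0 - sigma) / 2.0;
  int ev = birth_attempt(st, p_b, p_s);
  return List::create(_["grid"] = st.grid, _["event"] = ev);
}

// [[Rcpp::export]]
List ca_detach_cpp(IntegerMatrix grid, double sigma, double f) {
  CAState st(clone(grid));
  double p_d = f * (1.0 - sigma);
  int ev = detach_attempt(st, p_d, f);
  return List::create(_["grid"] = st.grid, _["event"] = ev);
}

// [[Rcpp::export]]
List ca_step_cpp(IntegerMatrix grid, double sigma, double f, double p_b) {
  CAState st(clone(grid));
  double p_s = (1.0 - sigma) / 2.0;
  double p_d = f * (1.0 - sigma);
  int bev = birth_attempt(st, p_b, p_s);
  int dev = st.n_occ() > 0 ? detach_attempt(st, p_d, f) : 0;
  return List::create(_["grid"] = st.grid, _["birth_event"] = bev,
                      _["detach_event"] = dev);
}

// [[Rcpp::export]]
List ca_run_cpp(IntegerMatrix grid, double sigma, double f, double p_b,
                double threshold, double max_steps) {
  CAState st(clone(grid));
  double p_s = (1.0 - sigma) / 2.0;
  double p_d = f * (1.0 - sigma);
  long long nsites = (long long)st.ny * st.nx;
  long long target =
      (long long)std::ceil(threshold * (double)nsites - 1e-9);
  long long steps = 0;
  long long births = 0, shove_removals = 0, detachments = 0,
            reloc_removals = 0;
  std::string terminated = "THRESHOLD";
  while (st.n_occ() < target) {
    if (st.n_occ() == 0) {
      terminated = "EXTINCT";
      break;
    }
    if ((double)steps >= max_steps) {
      terminated = "MAX_STEPS";
      break;
    }
    int bev = birth_attempt(st, p_b, p_s);
    if (bev >= 1 && bev != 5) ++births;
    if (bev == 3 || bev == 5) ++shove_removals;
    if (st.n_occ() > 0) {
      int dev = detach_attempt(st, p_d, f);
      if (dev >= 2) ++detachments;
      if (dev == 3) ++reloc_removals;
    }
    ++steps;
  }
  return List::create(
      _["grid"] = st.grid, _["steps"] = (double)steps,
      _["births"] = (double)births,
      _["shove_removals"] = (double)shove_removals,
      _["detachments"] = (double)detachments,
      _["relocation_removals"] = (double)reloc_removals,
      _["terminated"] = terminated,
      _["final_fraction"] = (double)st.n_occ() / (double)nsites);
}
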