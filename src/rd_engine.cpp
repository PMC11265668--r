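// Particle-based reaction-diffusion engine.
//
// One call runs a full simulation: per timestep the fixed sub-step order is
//   (1) Brownian displacement + reflection into the disc
//   (2) RNA decay            (R -> 0, prob p_rd each)
//   (3) RNA production       (0 -> R at the nucleation-point position, prob p_rp)
//   (4) complex formation    (E + R -> C, prob p_cp per matched pair)
//   (5) complex decay        (C -> E, prob p_cd each)
//   (6) methylation sweep    (synchronous, against the pre-sweep lattice)
//   (7) demethylation sweep
//   (8) nucleation-point re-assertion
// All randomness comes from R's RNG so a set.seed() call in R makes the whole
// trajectory reproducible bit-for-bit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int SP_E = 0, SP_R = 1, SP_C = 2;

// Uniform cell grid over the bounding box of the disc; used for proximity
// queries (nearest free enzyme, complexes near a nucleosome).
struct CellGrid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<int> head;  // ncells, -1 terminated chains
  std::vector<int> nxt;   // per particle

  void init(double radius, double d_prox, int cap) {
    cell = d_prox;
    double min_cell = (2.0 * radius) / 256.0;
    if (cell < min_cell) cell = min_cell;
    x0 = -radius - cell;
    y0 = -radius - cell;
    nx = (int)std::ceil((2.0 * (radius + cell)) / cell) + 1;
    ny = nx;
    head.assign((size_t)nx * ny, -1);
    nxt.assign(cap, -1);
  }
  inline int cx(double x) const {
    int c = (int)std::floor((x - x0) / cell);
    if (c < 0) c = 0; if (c >= nx) c = nx - 1; return c;
  }
  inline int cy(double y) const {
    int c = (int)std::floor((y - y0) / cell);
    if (c < 0) c = 0; if (c >= ny) c = ny - 1; return c;
  }
  // fill with particles of one species
  void build(const std::vector<double>& px, const std::vector<double>& py,
             const std::vector<int>& sp, int species) {
    std::fill(head.begin(), head.end(), -1);
    if (nxt.size() < px.size()) nxt.resize(px.size() * 2, -1);
    for (int i = 0; i < (int)px.size(); ++i) {
      if (sp[i] != species) continue;
      int c = cy(py[i]) * nx + cx(px[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// radial mirror: |p| -> 2r - |p|, folded until inside; angle preserved
static inline double reflect_particle(double& x, double& y, double radius) {
  double rr = std::sqrt(x * x + y * y);
  if (rr <= radius || rr == 0.0) return rr;
  double rn = rr;
  int guard = 0;
  while (rn > radius && guard++ < 64) {
    rn = 2.0 * radius - rn;
    if (rn < 0.0) rn = -rn;
  }
  if (rn > radius) rn = radius;  // pathological step length
  double s = rn / rr;
  x *= s; y *= s;
  return rn;
}

// [[Rcpp::export]]
List cpp_rd_engine(NumericVector site_x, NumericVector site_y, List nbrs,
                   int np_site, bool nucleation, double radius, int n_enzymes,
                   double d_tilde, double p_rp, double p_rd, double p_cp,
                   double p_cd, double p_w, double p_m, double p_dm,
                   double d_prox, int n_steps, int burn_in, int sample_interval,
                   double shell_dr, double particle_cap) {
  const int n_sites = site_x.size();
  std::vector<std::vector<int>> nbr(n_sites);
  for (int i = 0; i < n_sites; ++i) {
    IntegerVector v = nbrs[i];
    nbr[i].assign(v.begin(), v.end());
  }

  // particle store (stable insertion order; removals compact in order)
  std::vector<double> px, py;
  std::vector<int> sp;
  px.reserve(n_enzymes + 64); py.reserve(n_enzymes + 64);
  sp.reserve(n_enzymes + 64);

  // enzymes uniform on the disc
  for (int i = 0; i < n_enzymes; ++i) {
    double u = unif_rand();
    double th = 2.0 * M_PI * unif_rand();
    double rr = radius * std::sqrt(u);
    px.push_back(rr * std::cos(th));
    py.push_back(rr * std::sin(th));
    sp.push_back(SP_E);
  }
  int n_e = n_enzymes, n_r = 0, n_c = 0;

  std::vector<int> lattice(n_sites, 0);  // 0 = U, 1 = M
  if (nucleation) lattice[np_site] = 1;
  const double np_x = site_x[np_site], np_y = site_y[np_site];

  const int n_samples = (sample_interval > 0 && n_steps > burn_in)
                            ? (n_steps - burn_in) / sample_interval
                            : 0;
  IntegerMatrix samples(n_samples, n_sites);
  IntegerMatrix counts(n_samples, 3);
  std::vector<double> m_count(n_sites, 0.0), cprox_sum(n_sites, 0.0);
  const int n_shells = (int)std::ceil(radius / shell_dr);
  std::vector<double> shell_sum(n_shells, 0.0);

  CellGrid grid;
  grid.init(radius, d_prox, n_enzymes + 256);
  const double d2 = d_prox * d_prox;
  const double step_sd = std::sqrt(2.0 * d_tilde);

  bool conservation_ok = true, cap_hit = false;
  double max_radius = 0.0;
  int sample_row = 0;
  std::vector<char> removed;
  std::vector<int> new_state(n_sites);

  for (int step = 1; step <= n_steps; ++step) {
    const int n_part = (int)px.size();

    // (1) diffusion + reflection
    if (step_sd > 0.0) {
      for (int i = 0; i < n_part; ++i) {
        px[i] += step_sd * norm_rand();
        py[i] += step_sd * norm_rand();
        double rr = reflect_particle(px[i], py[i], radius);
        if (rr > max_radius) max_radius = rr;
      }
    }

    // (2) RNA decay
    if (n_r > 0 && p_rd > 0.0) {
      removed.assign(px.size(), 0);
      bool any = false;
      for (int i = 0; i < (int)px.size(); ++i) {
        if (sp[i] == SP_R && unif_rand() < p_rd) {
          removed[i] = 1; any = true; --n_r;
        }
      }
      if (any) {
        int w = 0;
        for (int i = 0; i < (int)px.size(); ++i) {
          if (!removed[i]) { px[w] = px[i]; py[w] = py[i]; sp[w] = sp[i]; ++w; }
        }
        px.resize(w); py.resize(w); sp.resize(w);
      }
    }

    // (3) RNA production at the nucleation-point position
    if (p_rp > 0.0 && unif_rand() < p_rp) {
      px.push_back(np_x); py.push_back(np_y); sp.push_back(SP_R);
      ++n_r;
    }

    // (4) complex formation: R particles in index order, each takes its
    //     nearest free E within d_prox (ties -> lower index)
    if (n_r > 0 && n_e > 0 && p_cp > 0.0) {
      grid.build(px, py, sp, SP_E);
      removed.assign(px.size(), 0);
      bool any = false;
      for (int i = 0; i < (int)px.size(); ++i) {
        if (sp[i] != SP_R) continue;
        int best = -1; double bestd = d2 + 1.0;
        int cx = grid.cx(px[i]), cy = grid.cy(py[i]);
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = cy + dy; if (yy < 0 || yy >= grid.ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx; if (xx < 0 || xx >= grid.nx) continue;
            for (int j = grid.head[yy * grid.nx + xx]; j >= 0; j = grid.nxt[j]) {
              if (sp[j] != SP_E) continue;  // consumed earlier this sweep
              double ddx = px[j] - px[i], ddy = py[j] - py[i];
              double dd = ddx * ddx + ddy * ddy;
              if (dd <= d2 && (dd < bestd || (dd == bestd && j < best))) {
                bestd = dd; best = j;
              }
            }
          }
        }
        if (best >= 0 && unif_rand() < p_cp) {
          sp[best] = SP_C;       // C inherits the enzyme's position
          removed[i] = 1; any = true;
          --n_e; --n_r; ++n_c;
        }
      }
      if (any) {
        int w = 0;
        for (int i = 0; i < (int)px.size(); ++i) {
          if (!removed[i]) { px[w] = px[i]; py[w] = py[i]; sp[w] = sp[i]; ++w; }
        }
        px.resize(w); py.resize(w); sp.resize(w);
      }
    }

    // (5) complex decay C -> E (in place, RNA component destroyed)
    if (n_c > 0 && p_cd > 0.0) {
      for (int i = 0; i < (int)px.size(); ++i) {
        if (sp[i] == SP_C && unif_rand() < p_cd) {
          sp[i] = SP_E; --n_c; ++n_e;
        }
      }
    }

    // (6) methylation sweep (synchronous: neighbour states read pre-sweep)
    grid.build(px, py, sp, SP_C);
    for (int s = 0; s < n_sites; ++s) new_state[s] = lattice[s];
    if (n_c > 0) {
      for (int s = 0; s < n_sites; ++s) {
        if (lattice[s] == 1) continue;
        // any C within d_prox of the site position?
        bool covered = false;
        int cx = grid.cx(site_x[s]), cy = grid.cy(site_y[s]);
        for (int dy = -1; dy <= 1 && !covered; ++dy) {
          int yy = cy + dy; if (yy < 0 || yy >= grid.ny) continue;
          for (int dx = -1; dx <= 1 && !covered; ++dx) {
            int xx = cx + dx; if (xx < 0 || xx >= grid.nx) continue;
            for (int j = grid.head[yy * grid.nx + xx]; j >= 0; j = grid.nxt[j]) {
              double ddx = px[j] - site_x[s], ddy = py[j] - site_y[s];
              if (ddx * ddx + ddy * ddy <= d2) { covered = true; break; }
            }
          }
        }
        if (!covered) continue;
        bool nbr_m = false;
        for (int k : nbr[s]) if (lattice[k] == 1) { nbr_m = true; break; }
        double peff = p_w + (nbr_m ? p_m : 0.0);
        if (peff > 1.0) peff = 1.0;
        if (peff > 0.0 && unif_rand() < peff) new_state[s] = 1;
      }
    }

    for (int s = 0; s < n_sites; ++s) lattice[s] = new_state[s];

    // (7) demethylation sweep (NP exempt while nucleation is on)
    if (p_dm > 0.0) {
      for (int s = 0; s < n_sites; ++s) {
        if (lattice[s] != 1) continue;
        if (nucleation && s == np_site) continue;
        if (unif_rand() < p_dm) lattice[s] = 0;
      }
    }

    // (8) nucleation-point re-assertion
    if (nucleation) lattice[np_site] = 1;

    if (n_e + n_c != n_enzymes) conservation_ok = false;
    if ((double)px.size() > particle_cap) cap_hit = true;

    // sampling
    if (step > burn_in && sample_interval > 0 &&
        (step - burn_in) % sample_interval == 0 && sample_row < n_samples) {
      for (int s = 0; s < n_sites; ++s) {
        samples(sample_row, s) = lattice[s];
        m_count[s] += lattice[s];
      }
      counts(sample_row, 0) = n_e;
      counts(sample_row, 1) = n_r;
      counts(sample_row, 2) = n_c;
      // complex-proximity counts per site (grid still holds the C particles)
      if (n_c > 0) {
        for (int s = 0; s < n_sites; ++s) {
          int cnt = 0;
          int cx = grid.cx(site_x[s]), cy = grid.cy(site_y[s]);
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = cy + dy; if (yy < 0 || yy >= grid.ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = cx + dx; if (xx < 0 || xx >= grid.nx) continue;
              for (int j = grid.head[yy * grid.nx + xx]; j >= 0;
                   j = grid.nxt[j]) {
                double ddx = px[j] - site_x[s], ddy = py[j] - site_y[s];
                if (ddx * ddx + ddy * ddy <= d2) ++cnt;
              }
            }
          }
          cprox_sum[s] += cnt;
        }
      }
      // RNA radial shell counts
      for (int i = 0; i < (int)px.size(); ++i) {
        if (sp[i] != SP_R) continue;
        double rr = std::sqrt(px[i] * px[i] + py[i] * py[i]);
        int b = (int)std::floor(rr / shell_dr);
        if (b >= n_shells) b = n_shells - 1;
        shell_sum[b] += 1.0;
      }
      ++sample_row;
    }

    if (step % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["m_count"] = NumericVector(m_count.begin(), m_count.end()),
      _["samples"] = samples, _["counts"] = counts,
      _["cprox_sum"] = NumericVector(cprox_sum.begin(), cprox_sum.end()),
      _["shell_sum"] = NumericVector(shell_sum.begin(), shell_sum.end()),
      _["n_samples"] = sample_row, _["conservation_ok"] = conservation_ok,
      _["max_radius"] = max_radius, _["cap_hit"] = cap_hit,
      _["final_x"] = NumericVector(px.begin(), px.end()),
      _["final_y"] = NumericVector(py.begin(), py.end()),
      _["final_species"] = IntegerVector(sp.begin(), sp.end()));
}
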