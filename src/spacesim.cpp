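// Continuous-space Wright-Fisher core: Gaussian mate-choice and competition
// kernels, fitness-weighted mother sampling, recombination + finite-site
// mutation, and local/long-range dispersal with reflecting boundaries.
// All randomness goes through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// spatial hash over the unit square for neighbour queries
struct Grid {
  double cell;
  int nc;
  std::vector<std::vector<int>> buckets;
  Grid(const std::vector<double>& x, const std::vector<double>& y,
       double cell_) : cell(cell_) {
    nc = std::max(1, (int)std::floor(1.0 / cell));
    buckets.assign(nc * nc, {});
    for (int i = 0; i < (int)x.size(); ++i)
      buckets[idx(x[i], y[i])].push_back(i);
  }
  int clampc(double v) const {
    int c = (int)std::floor(v / cell);
    if (c < 0) c = 0;
    if (c >= nc) c = nc - 1;
    return c;
  }
  int idx(double x, double y) const { return clampc(x) * nc + clampc(y); }
  template <typename F>
  void neighbours(double x, double y, double radius, F&& fn) const {
    int r = (int)std::ceil(radius / cell);
    int cx = clampc(x), cy = clampc(y);
    for (int dx = -r; dx <= r; ++dx) {
      int ix = cx + dx;
      if (ix < 0 || ix >= nc) continue;
      for (int dy = -r; dy <= r; ++dy) {
        int iy = cy + dy;
        if (iy < 0 || iy >= nc) continue;
        for (int j : buckets[ix * nc + iy]) fn(j);
      }
    }
  }
};

static inline double reflect01(double v) {
  // reflect into [0,1]; period 2 (avoid fmod: keeps old-glibc symbols)
  v -= 2.0 * std::floor(v / 2.0);
  return v > 1.0 ? 2.0 - v : v;
}

// competition_i = sum_{j != i, d <= maxd} maxs * exp(-d^2 / (2 sigma^2))
static std::vector<double> competition_sums(
    const std::vector<double>& x, const std::vector<double>& y,
    double maxd, double maxs, double sigma) {
  int n = x.size();
  std::vector<double> comp(n, 0.0);
  Grid grid(x, y, std::max(0.05, maxd / 3.0));
  double inv2s2 = 1.0 / (2.0 * sigma * sigma), maxd2 = maxd * maxd;
  for (int i = 0; i < n; ++i) {
    double ci = 0.0;
    grid.neighbours(x[i], y[i], maxd, [&](int j) {
      if (j == i) return;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 <= maxd2) ci += maxs * std::exp(-d2 * inv2s2);
    });
    comp[i] = ci;
  }
  return comp;
}

// [[Rcpp::export(name = "cpp_competition")]]
NumericVector cpp_competition(NumericMatrix pos, double maxd, double maxs,
                              double sigma) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  return wrap(competition_sums(x, y, maxd, maxs, sigma));
}

// draw offspring displacement; long-range draws are rejected until the
// displacement exceeds r99 (radial 99% quantile of the base kernel)
static void draw_displacement(bool longrange, double sigma_disp,
                              double sigma_lr, double r99,
                              double& dx, double& dy) {
  if (!longrange) {
    dx = norm_rand() * sigma_disp;
    dy = norm_rand() * sigma_disp;
    return;
  }
  for (int it = 0; it < 10000; ++it) {
    dx = norm_rand() * sigma_lr;
    dy = norm_rand() * sigma_lr;
    if (dx * dx + dy * dy > r99 * r99) return;
  }
  stop("long-range dispersal rejection cap hit; sigma_lr too small");
}

// [[Rcpp::export(name = "cpp_disperse")]]
NumericMatrix cpp_disperse(NumericMatrix mother_pos, double sigma_disp,
                           double p_lr, double sigma_lr, double r99) {
  int n = mother_pos.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double dx, dy;
    bool lr = p_lr > 0 && unif_rand() < p_lr;
    draw_displacement(lr, sigma_disp, sigma_lr, r99, dx, dy);
    out(i, 0) = reflect01(mother_pos(i, 0) + dx);
    out(i, 1) = reflect01(mother_pos(i, 1) + dy);
  }
  return out;
}

// recombine the two parental haplotypes into gamete
static void make_gamete(const unsigned char* h0, const unsigned char* h1,
                        unsigned char* gam, int L,
                        const std::vector<int>& site_bp, double genome_bp,
                        double exp_crossovers, double mu_per_site) {
  int ncross = (int)R::rpois(exp_crossovers);
  int cur = unif_rand() < 0.5 ? 0 : 1;
  if (ncross == 0) {
    std::copy(cur == 0 ? h0 : h1, (cur == 0 ? h0 : h1) + L, gam);
  } else {
    std::vector<double> cuts(ncross);
    for (int c = 0; c < ncross; ++c) cuts[c] = unif_rand() * genome_bp;
    std::sort(cuts.begin(), cuts.end());
    int s = 0;
    for (int c = 0; c <= ncross; ++c) {
      double hi = (c == ncross) ? genome_bp + 1 : cuts[c];
      int s0 = s;
      while (s < L && site_bp[s] < hi) ++s;
      const unsigned char* src = (cur == 0) ? h0 : h1;
      std::copy(src + s0, src + s, gam + s0);
      cur = 1 - cur;
    }
  }
  int nmut = (int)R::rbinom((double)L, mu_per_site);
  for (int m = 0; m < nmut; ++m) {
    int s = (int)(unif_rand() * L);
    if (s >= L) s = L - 1;
    gam[s] ^= 1;
  }
}

// Run n_gens non-overlapping Wright-Fisher generations.
// genomes: raw vector, haplotype-major: individual i, haplotype h, site s
// at (2*i + h) * L + s.  Returns list(positions, genomes).
// [[Rcpp::export(name = "cpp_step_generations")]]
List cpp_step_generations(NumericMatrix pos, RawVector genomes, int L,
                          List params, int n_gens) {
  int N = pos.nrow();
  if ((int)genomes.size() != 2 * N * L)
    stop("genomes length does not match 2 * N * L");
  double mate_maxd = params["mate_maxd"], mate_sigma = params["mate_sigma"];
  double comp_maxd = params["comp_maxd"], comp_maxs = params["comp_maxs"],
         comp_sigma = params["comp_sigma"];
  double sigma_disp = params["sigma_disp"], p_lr = params["p_lr"],
         sigma_lr = params["sigma_lr"], r99 = params["r99"];
  double genome_bp = params["genome_length_bp"];
  double mu = params["mu_per_site"], r_bp = params["r_per_bp"];
  double exp_cross = r_bp * genome_bp;
  IntegerVector site_bp_in = params["site_bp"];
  std::vector<int> site_bp(site_bp_in.begin(), site_bp_in.end());
  double mate_inv2s2 = 1.0 / (2.0 * mate_sigma * mate_sigma);
  double mate_maxd2 = mate_maxd * mate_maxd;

  std::vector<double> x(N), y(N);
  for (int i = 0; i < N; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  std::vector<unsigned char> gen(genomes.begin(), genomes.end());
  std::vector<unsigned char> next(2 * (size_t)N * L);
  std::vector<double> nx(N), ny(N);

  for (int g = 0; g < n_gens; ++g) {
    std::vector<double> comp =
      competition_sums(x, y, comp_maxd, comp_maxs, comp_sigma);
    std::vector<double> cumfit(N);
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double f = 1.1 - comp[i] / N;
      if (f < 0) f = 0;
      tot += f;
      cumfit[i] = tot;
    }
    if (tot <= 0) stop("all fitness zero: pathological configuration");
    Grid grid(x, y, std::max(0.05, mate_maxd));
    std::vector<int> cand;
    std::vector<double> w;
    for (int k = 0; k < N; ++k) {
      int mother = -1, father = -1;
      for (int attempt = 0; attempt < 1000; ++attempt) {
        double u = unif_rand() * tot;
        mother = (int)(std::lower_bound(cumfit.begin(), cumfit.end(), u) -
                       cumfit.begin());
        if (mother >= N) mother = N - 1;
        cand.clear(); w.clear();
        double wtot = 0.0;
        grid.neighbours(x[mother], y[mother], mate_maxd, [&](int j) {
          if (j == mother) return;
          double dx = x[mother] - x[j], dy = y[mother] - y[j];
          double d2 = dx * dx + dy * dy;
          if (d2 <= mate_maxd2) {
            double wt = std::exp(-d2 * mate_inv2s2); // maxStrength cancels
            cand.push_back(j);
            w.push_back(wt);
            wtot += wt;
          }
        });
        if (wtot > 0) {
          double v = unif_rand() * wtot, acc = 0.0;
          father = cand.back();
          for (size_t c = 0; c < cand.size(); ++c) {
            acc += w[c];
            if (v <= acc) { father = cand[c]; break; }
          }
          break;
        }
      }
      if (father < 0)
        stop("no mate found within max_distance after 1000 mother redraws");
      unsigned char* childbase = next.data() + (size_t)(2 * k) * L;
      make_gamete(gen.data() + (size_t)(2 * mother) * L,
                  gen.data() + (size_t)(2 * mother + 1) * L,
                  childbase, L, site_bp, genome_bp, exp_cross, mu);
      make_gamete(gen.data() + (size_t)(2 * father) * L,
                  gen.data() + (size_t)(2 * father + 1) * L,
                  childbase + L, L, site_bp, genome_bp, exp_cross, mu);
      double dx, dy;
      bool lr = p_lr > 0 && unif_rand() < p_lr;
      draw_displacement(lr, sigma_disp, sigma_lr, r99, dx, dy);
      nx[k] = reflect01(x[mother] + dx);
      ny[k] = reflect01(y[mother] + dy);
    }
    gen.swap(next);
    x = nx;
    y = ny;
  }

  NumericMatrix outpos(N, 2);
  for (int i = 0; i < N; ++i) { outpos(i, 0) = x[i]; outpos(i, 1) = y[i]; }
  RawVector outgen(2 * (size_t)N * L);
  std::copy(gen.begin(), gen.end(), outgen.begin());
  return List::create(_["positions"] = outpos, _["genomes"] = outgen);
}

// initial haplotypes: per site s, each haplotype carries the derived allele
// with probability freqs[s] independently (no spatial structure)
// [[Rcpp::export(name = "cpp_init_genomes")]]
RawVector cpp_init_genomes(NumericVector freqs, int n_hap) {
  int L = freqs.size();
  RawVector out((size_t)n_hap * L);
  for (int h = 0; h < n_hap; ++h) {
    size_t base = (size_t)h * L;
    for (int s = 0; s < L; ++s)
      out[base + s] = unif_rand() < freqs[s] ? 1 : 0;
  }
  return out;
}

// per-cell derived-allele counts: genomes haplotype-major (2N x L bits),
// cell: 1-based cell index per individual, ncell: number of cells.
// Returns L x ncell integer matrix.
// [[Rcpp::export(name = "cpp_cell_counts")]]
IntegerMatrix cpp_cell_counts(RawVector genomes, int L, IntegerVector cell,
                              int ncell) {
  int N = cell.size();
  if ((int)genomes.size() != 2 * N * L) stop("genome size mismatch");
  IntegerMatrix out(L, ncell);
  for (int i = 0; i < N; ++i) {
    int c = cell[i] - 1;
    if (c < 0 || c >= ncell) stop("cell index out of range");
    const Rbyte* h0 = &genomes[(size_t)(2 * i) * L];
    const Rbyte* h1 = &genomes[(size_t)(2 * i + 1) * L];
    int* col = &out(0, c);
    for (int s = 0; s < L; ++s) col[s] += h0[s] + h1[s];
  }
  return out;
}

// dosage matrix (L x N) from bit haplotypes, for genotype export
// [[Rcpp::export(name = "cpp_dosages")]]
IntegerMatrix cpp_dosages(RawVector genomes, int L) {
  int N = genomes.size() / (2 * L);
  IntegerMatrix out(L, N);
  for (int i = 0; i < N; ++i) {
    const Rbyte* h0 = &genomes[(size_t)(2 * i) * L];
    const Rbyte* h1 = &genomes[(size_t)(2 * i + 1) * L];
    for (int s = 0; s < L; ++s) out(s, i) = h0[s] + h1[s];
  }
  return out;
}
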