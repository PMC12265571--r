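// Forward-time Wright-Fisher simulator on a linear region.
//
// Haplotypes are sparse sorted lists of mutation positions (continuous
// coordinates in [0, L), i.e. infinite-sites). Each generation, offspring
// haplotypes are gametes of fitness-weighted diploid parents with Poisson
// crossovers and Poisson new mutations. The beneficial allele is tracked as
// a per-haplotype flag so that recombination moves it between backgrounds
// exactly; after fixation it is monomorphic and never appears in the sample.
//
// All randomness goes through R's RNG so set.seed() in R fully determines
// the output.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <climits>
#include <cstdlib>
using namespace Rcpp;

typedef std::vector<double> Hap;

struct Pop {
  std::vector<Hap> haps;   // 2N haplotypes; individual i owns 2i, 2i+1
  std::vector<char> sel;   // beneficial-allele carrier flags
  int n_dip() const { return (int)haps.size() / 2; }
};

static inline int rpois_int(double lambda) {
  return (int) R::rpois(lambda);
}

// diploid population size at time t generations before present;
// epochs: col0 = start time (most recent first, first row 0), col1 = N
static int size_at(const NumericMatrix &demog, double t) {
  int k = 0;
  for (int i = 0; i < demog.nrow(); ++i)
    if (t >= demog(i, 0)) k = i;
  return (int) demog(k, 1);
}

// one gamete from diploid parent (h1,h2): mosaic with Poisson(rec*L)
// crossovers plus Poisson(mu*L) new mutations; records whether the segment
// covering sweep_pos came from a carrier haplotype.
static void make_gamete(const Hap &h1, const Hap &h2, char s1, char s2,
                        double mu, double rec, double L, double sweep_pos,
                        Hap &out, char &out_sel) {
  out.clear();
  int nx = rpois_int(rec * L);
  if (nx == 0) {
    bool first = (R::unif_rand() < 0.5);
    out = first ? h1 : h2;
    out_sel = first ? s1 : s2;
  } else {
    std::vector<double> bp(nx);
    for (int i = 0; i < nx; ++i) bp[i] = R::unif_rand() * L;
    std::sort(bp.begin(), bp.end());
    bp.push_back(L);
    bool cur = (R::unif_rand() < 0.5);
    out_sel = 0;
    double lo = 0.0;
    for (size_t seg = 0; seg < bp.size(); ++seg) {
      double hi = bp[seg];
      const Hap &src = cur ? h1 : h2;
      char ssel = cur ? s1 : s2;
      Hap::const_iterator a = std::lower_bound(src.begin(), src.end(), lo);
      Hap::const_iterator b = std::lower_bound(src.begin(), src.end(), hi);
      out.insert(out.end(), a, b);
      if (sweep_pos >= lo && sweep_pos < hi) out_sel = ssel;
      lo = hi;
      cur = !cur;
    }
  }
  int nm = rpois_int(mu * L);
  if (nm > 0) {
    for (int i = 0; i < nm; ++i) {
      double pos = R::unif_rand() * L;
      Hap::iterator it = std::lower_bound(out.begin(), out.end(), pos);
      out.insert(it, pos);
    }
  }
}

// advance one generation; offspring population has n_next diploids
static void next_generation(Pop &pop, Pop &nxt, int n_next,
                            double mu, double rec, double L,
                            double s, double sweep_pos) {
  int n_par = pop.n_dip();
  std::vector<double> cumw;
  bool selected = (s != 0.0);
  if (selected) {
    cumw.resize(n_par);
    double acc = 0.0;
    for (int i = 0; i < n_par; ++i) {
      int nc = pop.sel[2 * i] + pop.sel[2 * i + 1];
      acc += 1.0 + 0.5 * s * nc;   // 1, 1+s/2, 1+s
      cumw[i] = acc;
    }
  }
  nxt.haps.resize(2 * (size_t)n_next);
  nxt.sel.assign(2 * (size_t)n_next, 0);
  for (int i = 0; i < n_next; ++i) {
    for (int g = 0; g < 2; ++g) {
      int par;
      if (selected) {
        double u = R::unif_rand() * cumw[n_par - 1];
        par = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
      } else {
        par = (int)(R::unif_rand() * n_par);
        if (par >= n_par) par = n_par - 1;
      }
      char osel = 0;
      make_gamete(pop.haps[2 * par], pop.haps[2 * par + 1],
                  pop.sel[2 * par], pop.sel[2 * par + 1],
                  mu, rec, L, sweep_pos, nxt.haps[2 * i + g], osel);
      nxt.sel[2 * i + g] = osel;
    }
  }
  std::swap(pop.haps, nxt.haps);
  std::swap(pop.sel, nxt.sel);
}

static int count_sel(const Pop &pop) {
  int c = 0;
  for (size_t i = 0; i < pop.sel.size(); ++i) c += pop.sel[i];
  return c;
}

// drop mutations fixed in the whole population (bookkeeping only)
static void strip_fixed(Pop &pop) {
  size_t n = pop.haps.size();
  if (n == 0 || pop.haps[0].empty()) return;
  std::unordered_map<double, size_t> cnt;
  cnt.reserve(pop.haps[0].size() * 4);
  for (size_t i = 0; i < n; ++i)
    for (size_t j = 0; j < pop.haps[i].size(); ++j) cnt[pop.haps[i][j]]++;
  bool any = false;
  for (std::unordered_map<double, size_t>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second == n) { any = true; break; }
  if (!any) return;
  for (size_t i = 0; i < n; ++i) {
    Hap keep;
    keep.reserve(pop.haps[i].size());
    for (size_t j = 0; j < pop.haps[i].size(); ++j)
      if (cnt[pop.haps[i][j]] < n) keep.push_back(pop.haps[i][j]);
    pop.haps[i].swap(keep);
  }
}

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
List wf_simulate_cpp(double region_length, double mu, double rec, double s,
                     double tau, double f0, double sweep_pos, int sweep_mode,
                     NumericMatrix demog, int n_sample_dip,
                     double burnin_factor, int max_attempts,
                     double soft_search_tol) {
  // sweep_mode: 0 neutral, 1 hard (single de novo copy), 2 soft (standing
  // variant at frequency f0)
  const double L = region_length;
  int N0 = (int) demog(0, 1);
  int N_anc = (int) demog(demog.nrow() - 1, 1);
  double T_old = demog(demog.nrow() - 1, 0);
  int t_fix = (sweep_mode == 0) ? 0 : (int) std::floor(tau * 4.0 * N0 + 0.5);

  Pop pop, buf;
  pop.haps.assign(2 * (size_t)N_anc, Hap());
  pop.sel.assign(2 * (size_t)N_anc, 0);

  int burnin = (int)(burnin_factor * N_anc + 0.5);
  for (int g = 0; g < burnin; ++g) {
    next_generation(pop, buf, N_anc, mu, rec, L, 0.0, sweep_pos);
    if ((g & 63) == 63) strip_fixed(pop);
  }

  // neutral epoch walk from the oldest epoch start down to t_stop
  int t_stop = t_fix;
  for (int t = (int) T_old; t > t_stop; --t) {
    int n_next = size_at(demog, t - 1.0);
    next_generation(pop, buf, n_next, mu, rec, L, 0.0, sweep_pos);
    if ((t & 63) == 63) strip_fixed(pop);
  }

  int attempts = 0, sweep_gens = 0;
  if (sweep_mode != 0) {
    strip_fixed(pop);
    Pop saved = pop;   // state at the sweep insertion point
    int N_sweep = size_at(demog, (double) t_fix);
    int twoN = 2 * pop.n_dip();
    int gen_cap = 1000 + (int)(40.0 * std::log((double) twoN) / std::max(s, 1e-6));
    bool done = false;
    while (!done) {
      if (attempts >= max_attempts)
        stop("fixation rejection budget exhausted (s=%g, f0=%g, mode=%d)",
             s, f0, sweep_mode);
      ++attempts;
      pop = saved;
      // introduce the beneficial allele
      if (sweep_mode == 1) {
        int h = (int)(R::unif_rand() * twoN);
        if (h >= twoN) h = twoN - 1;
        pop.sel[h] = 1;
      } else {
        int k0 = (int) std::floor(f0 * twoN + 0.5);
        if (k0 < 1) stop("population too small for f0 (f0*2N < 1)");
        // prefer an existing standing neutral variant in the focal
        // subwindow with carrier count near k0
        double sw = L / 11.0; // search span: the subwindow holding sweep_pos
        double lo = std::floor(sweep_pos / sw) * sw, hi = lo + sw;
        std::unordered_map<double, int> cnt;
        for (int i = 0; i < twoN; ++i) {
          Hap::const_iterator a = std::lower_bound(pop.haps[i].begin(),
                                                   pop.haps[i].end(), lo);
          Hap::const_iterator b = std::lower_bound(pop.haps[i].begin(),
                                                   pop.haps[i].end(), hi);
          for (; a != b; ++a) cnt[*a]++;
        }
        double best_pos = -1.0;
        int best_diff = INT_MAX;
        int tol = soft_search_tol <= 0 ? -1
          : std::max(1, (int)(soft_search_tol * k0 + 0.5));
        for (std::unordered_map<double, int>::iterator it = cnt.begin();
             it != cnt.end(); ++it) {
          int d = std::abs(it->second - k0);
          if (d <= tol && d < best_diff && it->second < twoN) {
            best_diff = d;
            best_pos = it->first;
          }
        }
        if (best_pos >= 0.0) {
          // select on that variant: transfer it from the lists to the flag
          sweep_pos = best_pos;
          for (int i = 0; i < twoN; ++i) {
            Hap &h = pop.haps[i];
            Hap::iterator a = std::lower_bound(h.begin(), h.end(), best_pos);
            if (a != h.end() && *a == best_pos) {
              pop.sel[i] = 1;
              h.erase(a);
            }
          }
        } else {
          // inject a new variant at frequency f0 on random backgrounds
          std::vector<int> idx(twoN);
          for (int i = 0; i < twoN; ++i) idx[i] = i;
          for (int i = 0; i < k0; ++i) {
            int j = i + (int)(R::unif_rand() * (twoN - i));
            if (j >= twoN) j = twoN - 1;
            std::swap(idx[i], idx[j]);
            pop.sel[idx[i]] = 1;
          }
        }
      }
      // selection phase until fixation or loss
      sweep_gens = 0;
      while (true) {
        next_generation(pop, buf, N_sweep, mu, rec, L, s, sweep_pos);
        ++sweep_gens;
        int c = count_sel(pop);
        if (c == 2 * pop.n_dip()) { done = true; break; }
        if (c == 0) break;
        if (sweep_gens > gen_cap) break;
        if ((sweep_gens & 63) == 63) strip_fixed(pop);
      }
    }
    // post-fixation neutral phase: t_fix generations to the present
    for (int t = t_fix; t > 0; --t) {
      int n_next = size_at(demog, t - 1.0);
      next_generation(pop, buf, n_next, mu, rec, L, 0.0, sweep_pos);
      if ((t & 63) == 63) strip_fixed(pop);
    }
  }

  // sample 2*n_sample_dip haplotypes without replacement, pair consecutively
  int twoN = 2 * pop.n_dip();
  int ns = 2 * n_sample_dip;
  if (ns > twoN) stop("sample size exceeds population size");
  std::vector<int> idx(twoN);
  for (int i = 0; i < twoN; ++i) idx[i] = i;
  for (int i = 0; i < ns; ++i) {
    int j = i + (int)(R::unif_rand() * (twoN - i));
    if (j >= twoN) j = twoN - 1;
    std::swap(idx[i], idx[j]);
  }

  // segregating sites in the sample
  std::unordered_map<double, int> cnt;
  for (int i = 0; i < ns; ++i) {
    const Hap &h = pop.haps[idx[i]];
    for (size_t j = 0; j < h.size(); ++j) cnt[h[j]]++;
  }
  std::vector<double> segpos;
  segpos.reserve(cnt.size());
  for (std::unordered_map<double, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second > 0 && it->second < ns) segpos.push_back(it->first);
  std::sort(segpos.begin(), segpos.end());

  int S = (int) segpos.size();
  IntegerMatrix dos(n_sample_dip, S);
  for (int i = 0; i < n_sample_dip; ++i) {
    const Hap &h1 = pop.haps[idx[2 * i]];
    const Hap &h2 = pop.haps[idx[2 * i + 1]];
    for (int sIdx = 0; sIdx < S; ++sIdx) {
      double p = segpos[sIdx];
      int d = 0;
      if (std::binary_search(h1.begin(), h1.end(), p)) ++d;
      if (std::binary_search(h2.begin(), h2.end(), p)) ++d;
      dos(i, sIdx) = d;
    }
  }

  int n_sel_sample = 0;
  for (int i = 0; i < ns; ++i) n_sel_sample += pop.sel[idx[i]];

  return List::create(
    _["positions"] = NumericVector(segpos.begin(), segpos.end()),
    _["dosages"] = dos,
    _["attempts"] = attempts,
    _["sweep_generations"] = sweep_gens,
    _["sweep_position"] = sweep_pos,
    _["n_beneficial_sampled"] = n_sel_sample);
}
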