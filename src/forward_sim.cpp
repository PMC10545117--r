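// Individual-based Wright-Fisher forward simulator for a 1-D serial-founder
// range expansion. Haplotypes are sorted vectors of mutated positions
// (infinite-sites over a fixed coding map); fitness is multiplicative across
// sites with genotype scheme 1 / 1-h*s / 1-s (s < 0 = beneficial).
// RNG is a self-contained mt19937_64 so a single integer seed fixes the run.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Individual {
  std::vector<uint32_t> hap[2];
  double w;
};

typedef std::vector<Individual> Deme;

struct SiteInfo {
  uint8_t active;      // currently segregating (or recently counted)
  uint8_t fixed;       // fixed in the focal species during the run
  uint8_t derived;     // target base code 0..3
  uint8_t cls;         // 0 syn, 1 missense, 2 lof
  double s;
};

struct Sim {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  double runif() { return unif(rng); }
  int rint(int n) { return (int)(runif() * n) % n; }
};

// merge the two haplotypes of an individual and compute fitness
double genotype_fitness(const std::vector<uint32_t>& a,
                        const std::vector<uint32_t>& b,
                        const std::vector<SiteInfo>& sites,
                        double h_del, double h_ben) {
  double w = 1.0;
  size_t i = 0, j = 0;
  while (i < a.size() || j < b.size()) {
    uint32_t pa = i < a.size() ? a[i] : UINT32_MAX;
    uint32_t pb = j < b.size() ? b[j] : UINT32_MAX;
    if (pa == pb) {
      const double s = sites[pa].s;
      if (s != 0.0) w *= (1.0 - s);
      ++i; ++j;
    } else if (pa < pb) {
      const double s = sites[pa].s;
      if (s != 0.0) w *= (1.0 - (s > 0 ? h_del : h_ben) * s);
      ++i;
    } else {
      const double s = sites[pb].s;
      if (s != 0.0) w *= (1.0 - (s > 0 ? h_del : h_ben) * s);
      ++j;
    }
  }
  return w > 1e-12 ? w : 1e-12;
}

// recombinant gamete: phase chosen per gene, crossover at gene boundaries
void make_gamete(const Individual& par, std::vector<uint32_t>& out,
                 const std::vector<int>& gene_of_pos,
                 const NumericVector& xover, std::vector<uint8_t>& phase_buf,
                 Sim& sim) {
  const int n_genes = (int)phase_buf.size();
  uint8_t ph = sim.runif() < 0.5 ? 0 : 1;
  phase_buf[0] = ph;
  for (int g = 1; g < n_genes; ++g) {
    const double r = xover[g - 1];
    if (r >= 0.5) { if (sim.runif() < 0.5) ph ^= 1; }
    else if (r > 0.0 && sim.runif() < r) ph ^= 1;
    phase_buf[g] = ph;
  }
  const std::vector<uint32_t>& a = par.hap[0];
  const std::vector<uint32_t>& b = par.hap[1];
  out.clear();
  size_t i = 0, j = 0;
  while (i < a.size() || j < b.size()) {
    uint32_t pa = i < a.size() ? a[i] : UINT32_MAX;
    uint32_t pb = j < b.size() ? b[j] : UINT32_MAX;
    if (pa == pb) { out.push_back(pa); ++i; ++j; }
    else if (pa < pb) {
      if (phase_buf[gene_of_pos[pa]] == 0) out.push_back(pa);
      ++i;
    } else {
      if (phase_buf[gene_of_pos[pb]] == 1) out.push_back(pb);
      ++j;
    }
  }
}

int weighted_draw(const std::vector<double>& cumw, Sim& sim) {
  const double u = sim.runif() * cumw.back();
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".wf_simulate")]]
List wf_simulate(int n_demes, IntegerVector capacity, int K, int T_found,
                 double m, double growth, int burnin, int post_gens,
                 IntegerVector gene_of_pos_r, NumericVector xover,
                 IntegerMatrix alt_targets, LogicalMatrix alt_is_syn,
                 double gamma_shape, double gamma_mean, double p_b,
                 double mean_sb, double h_del, double h_ben,
                 double lof_thr, double s_max, double mu,
                 int n_sample, int purge_every, int seed, bool neutral) {
  const int L = gene_of_pos_r.size();
  const int n_genes = xover.size() + 1;
  std::vector<int> gene_of_pos(gene_of_pos_r.begin(), gene_of_pos_r.end());

  Sim sim;
  sim.rng.seed((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);
  std::gamma_distribution<double> rgamma_s(gamma_shape, gamma_mean / gamma_shape);
  std::exponential_distribution<double> rexp_sb(1.0 / std::max(mean_sb, 1e-12));

  std::vector<SiteInfo> sites(L);
  for (int p = 0; p < L; ++p) sites[p] = SiteInfo{0, 0, 0, 0, 0.0};
  std::vector<std::pair<uint32_t, int> > fixed_log; // position, generation

  std::vector<Deme> pop(n_demes), next(n_demes);
  std::vector<int> founded_at(n_demes, -1);
  founded_at[0] = 0;
  const int N0 = capacity[0];
  pop[0].resize(N0);
  for (int i = 0; i < N0; ++i) pop[0][i].w = 1.0;

  const int total_gens = burnin + (n_demes - 1) * T_found + post_gens;
  std::vector<uint8_t> phase_buf(n_genes);
  std::vector<double> cumw;
  std::vector<uint32_t> cnt(L, 0);

  for (int gen = 1; gen <= total_gens; ++gen) {
    // serial founding: deme d is founded from deme d-1 every T_found gens
    if (gen > burnin) {
      int j = (gen - burnin - 1) / T_found + 1;
      if (j < n_demes && founded_at[j] < 0 && (gen - burnin - 1) % T_found == 0) {
        Deme& src = pop[j - 1];
        std::vector<int> idx(src.size());
        for (size_t i = 0; i < src.size(); ++i) idx[i] = (int)i;
        for (int i = 0; i < K; ++i) {
          int pick = i + sim.rint((int)src.size() - i);
          std::swap(idx[i], idx[pick]);
          pop[j].push_back(src[idx[i]]);
        }
        founded_at[j] = gen;
      }
    }

    // reproduction, deme by deme
    int total_haps = 0;
    for (int d = 0; d < n_demes; ++d) {
      if (founded_at[d] < 0) continue;
      Deme& par = pop[d];
      cumw.resize(par.size());
      double acc = 0.0;
      for (size_t i = 0; i < par.size(); ++i) { acc += par[i].w; cumw[i] = acc; }
      // founded demes grow toward carrying capacity at rate `growth`
      int target = d == 0 ? capacity[0]
        : std::min(capacity[d],
                   std::max(K, (int)std::ceil(par.size() * growth)));
      Deme& chd = next[d];
      chd.resize(target);
      for (int i = 0; i < target; ++i) {
        const Individual& p1 = par[weighted_draw(cumw, sim)];
        const Individual& p2 = par[weighted_draw(cumw, sim)];
        make_gamete(p1, chd[i].hap[0], gene_of_pos, xover, phase_buf, sim);
        make_gamete(p2, chd[i].hap[1], gene_of_pos, xover, phase_buf, sim);
        chd[i].w = genotype_fitness(chd[i].hap[0], chd[i].hap[1], sites,
                                    h_del, h_ben);
      }
      total_haps += 2 * target;
    }
    for (int d = 0; d < n_demes; ++d)
      if (founded_at[d] >= 0) pop[d].swap(next[d]);

    // new mutations in the offspring generation
    std::poisson_distribution<int> rpois((double)total_haps * L * mu);
    int n_mut = rpois(sim.rng);
    for (int k = 0; k < n_mut; ++k) {
      int hap_idx = sim.rint(total_haps);
      int d = 0;
      while (true) {
        if (founded_at[d] >= 0) {
          int nh = 2 * (int)pop[d].size();
          if (hap_idx < nh) break;
          hap_idx -= nh;
        }
        ++d;
      }
      Individual& ind = pop[d][hap_idx / 2];
      std::vector<uint32_t>& hp = ind.hap[hap_idx % 2];
      uint32_t pos = (uint32_t)sim.rint(L);
      SiteInfo& si = sites[pos];
      if (si.fixed) continue; // ignore back-mutation on substituted sites
      if (!si.active) {
        // activate: pick a target base among the allowed (non-stop) changes
        int n_ok = 0, pick = -1;
        for (int t = 0; t < 3; ++t)
          if (alt_targets(pos, t) >= 0) ++n_ok;
        if (n_ok == 0) continue;
        int want = sim.rint(n_ok);
        for (int t = 0; t < 3; ++t) {
          if (alt_targets(pos, t) >= 0 && want-- == 0) { pick = t; break; }
        }
        si.derived = (uint8_t)alt_targets(pos, pick);
        if (alt_is_syn(pos, pick)) { si.cls = 0; si.s = 0.0; }
        else if (neutral) { si.cls = 1; si.s = 0.0; }
        else if (sim.runif() < p_b) { si.cls = 1; si.s = -rexp_sb(sim.rng); }
        else {
          double s = rgamma_s(sim.rng);
          if (s > s_max) s = s_max;
          si.s = s;
          si.cls = s >= lof_thr ? 2 : 1;
        }
        si.active = 1;
      }
      std::vector<uint32_t>::iterator it =
        std::lower_bound(hp.begin(), hp.end(), pos);
      if (it != hp.end() && *it == pos) continue; // already carries it
      hp.insert(it, pos);
      if (si.s != 0.0) { // update fitness incrementally
        const std::vector<uint32_t>& other = ind.hap[1 - hap_idx % 2];
        bool hom = std::binary_search(other.begin(), other.end(), pos);
        double hh = si.s > 0 ? h_del : h_ben;
        double f = hom ? (1.0 - si.s) / (1.0 - hh * si.s) : (1.0 - hh * si.s);
        ind.w = std::max(ind.w * f, 1e-12);
      }
    }

    // symmetric nearest-neighbour migration between founded demes
    if (m > 0.0) {
      for (int d = 0; d + 1 < n_demes; ++d) {
        if (founded_at[d] < 0 || founded_at[d + 1] < 0) continue;
        int nmin = (int)std::min(pop[d].size(), pop[d + 1].size());
        std::poisson_distribution<int> rmig(m * nmin);
        int nm = std::min(rmig(sim.rng), nmin / 4);
        for (int k = 0; k < nm; ++k) {
          int i = sim.rint((int)pop[d].size());
          int j = sim.rint((int)pop[d + 1].size());
          std::swap(pop[d][i], pop[d + 1][j]);
        }
      }
    }

    // purge fixed and lost mutations
    if (gen % purge_every == 0 || gen == total_gens) {
      std::fill(cnt.begin(), cnt.end(), 0u);
      int nh = 0;
      for (int d = 0; d < n_demes; ++d) {
        if (founded_at[d] < 0) continue;
        for (size_t i = 0; i < pop[d].size(); ++i)
          for (int hidx = 0; hidx < 2; ++hidx) {
            ++nh;
            const std::vector<uint32_t>& hp = pop[d][i].hap[hidx];
            for (size_t q = 0; q < hp.size(); ++q) ++cnt[hp[q]];
          }
      }
      std::vector<uint8_t> drop(L, 0);
      bool any_drop = false;
      for (int p = 0; p < L; ++p) {
        if (!sites[p].active) continue;
        if ((int)cnt[p] == nh) {
          sites[p].active = 0; sites[p].fixed = 1;
          fixed_log.push_back(std::make_pair((uint32_t)p, gen));
          drop[p] = 1; any_drop = true;
        } else if (cnt[p] == 0) {
          sites[p].active = 0;
        }
      }
      if (any_drop) {
        for (int d = 0; d < n_demes; ++d) {
          if (founded_at[d] < 0) continue;
          for (size_t i = 0; i < pop[d].size(); ++i)
            for (int hidx = 0; hidx < 2; ++hidx) {
              std::vector<uint32_t>& hp = pop[d][i].hap[hidx];
              hp.erase(std::remove_if(hp.begin(), hp.end(),
                         [&](uint32_t p) { return drop[p] != 0; }),
                       hp.end());
            }
        }
      }
    }
  }

  // final census frequencies and segregating-site list
  std::fill(cnt.begin(), cnt.end(), 0u);
  std::vector<std::vector<uint32_t> > deme_cnt(n_demes,
                                               std::vector<uint32_t>(L, 0));
  for (int d = 0; d < n_demes; ++d)
    for (size_t i = 0; i < pop[d].size(); ++i)
      for (int hidx = 0; hidx < 2; ++hidx) {
        const std::vector<uint32_t>& hp = pop[d][i].hap[hidx];
        for (size_t q = 0; q < hp.size(); ++q) {
          ++cnt[hp[q]]; ++deme_cnt[d][hp[q]];
        }
      }
  std::vector<int> seg;
  for (int p = 0; p < L; ++p)
    if (sites[p].active && cnt[p] > 0) seg.push_back(p);
  const int S = (int)seg.size();

  // sample individuals per deme
  IntegerMatrix haps(2 * n_sample * n_demes, S);
  IntegerVector samp_deme(n_sample * n_demes);
  for (int d = 0; d < n_demes; ++d) {
    std::vector<int> idx((int)pop[d].size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
    for (int i = 0; i < n_sample; ++i) {
      int pick = i + sim.rint((int)idx.size() - i);
      std::swap(idx[i], idx[pick]);
      samp_deme[d * n_sample + i] = d;
      for (int hidx = 0; hidx < 2; ++hidx) {
        const std::vector<uint32_t>& hp = pop[d][idx[i]].hap[hidx];
        int row = 2 * (d * n_sample + i) + hidx;
        size_t q = 0;
        for (int c = 0; c < S; ++c) {
          while (q < hp.size() && hp[q] < (uint32_t)seg[c]) ++q;
          haps(row, c) = (q < hp.size() && hp[q] == (uint32_t)seg[c]) ? 1 : 0;
        }
      }
    }
  }

  NumericMatrix freq(n_demes, S);
  for (int d = 0; d < n_demes; ++d)
    for (int c = 0; c < S; ++c)
      freq(d, c) = deme_cnt[d][seg[c]] / (2.0 * pop[d].size());

  IntegerVector seg_pos(S), seg_base(S), seg_cls(S);
  NumericVector seg_s(S);
  for (int c = 0; c < S; ++c) {
    seg_pos[c] = seg[c] + 1; // 1-based within the coding map
    seg_base[c] = sites[seg[c]].derived;
    seg_cls[c] = sites[seg[c]].cls;
    seg_s[c] = sites[seg[c]].s;
  }
  const int F = (int)fixed_log.size();
  IntegerVector fx_pos(F), fx_base(F), fx_cls(F), fx_gen(F);
  NumericVector fx_s(F);
  for (int c = 0; c < F; ++c) {
    uint32_t p = fixed_log[c].first;
    fx_pos[c] = (int)p + 1;
    fx_base[c] = sites[p].derived;
    fx_cls[c] = sites[p].cls;
    fx_s[c] = sites[p].s;
    fx_gen[c] = fixed_log[c].second;
  }
  return List::create(
    _["pos"] = seg_pos, _["derived_base"] = seg_base, _["cls"] = seg_cls,
    _["s"] = seg_s, _["haps"] = haps, _["freq"] = freq,
    _["sample_deme"] = samp_deme,
    _["fixed"] = List::create(_["pos"] = fx_pos, _["derived_base"] = fx_base,
                              _["cls"] = fx_cls, _["s"] = fx_s,
                              _["gen"] = fx_gen),
    _["total_gens"] = total_gens);
}

//' @noRd
// [[Rcpp::export(name = ".wf_fixation_trials")]]
IntegerVector wf_fixation_trials(int N, double s, double h, int n_trials,
                                 int seed) {
  // single-locus Wright-Fisher trials from one copy; returns fixation count
  Sim sim;
  sim.rng.seed((uint64_t)seed * 2862933555777941757ULL + 97531ULL);
  int fixed = 0;
  const int n2 = 2 * N;
  for (int t = 0; t < n_trials; ++t) {
    int k = 1;
    while (k > 0 && k < n2) {
      double x = (double)k / n2;
      // marginal fitness of the mutant vs wild-type allele under HWE
      double wA = x * (1.0 - s) + (1.0 - x) * (1.0 - h * s);
      double wa = x * (1.0 - h * s) + (1.0 - x) * 1.0;
      double xp = x * wA / (x * wA + (1.0 - x) * wa);
      std::binomial_distribution<int> rb(n2, std::min(std::max(xp, 0.0), 1.0));
      k = rb(sim.rng);
    }
    if (k == n2) ++fixed;
  }
  return IntegerVector::create(fixed, n_trials);
}
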