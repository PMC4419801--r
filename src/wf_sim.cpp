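// Forward-in-time Wright-Fisher simulator with recombination and an
// optional single beneficial mutation (hard sweep).  Haplotypes are sparse
// sorted vectors of mutation positions on a continuous chromosome (infinite
// sites: every mutation is new, the derived allele is always "1" and the
// founding allele is the known ancestral state).  Uses R's RNG so that
// set.seed() on the R side gives bit-identical runs.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>

using namespace Rcpp;

typedef std::vector<double> Hap;
typedef std::vector<Hap> Pop;

static inline bool carries(const Hap &h, double pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// recombinant gamete from the two haplotypes of one diploid parent
static Hap make_gamete(const Hap &a, const Hap &b, double rec_total, double L) {
  int k = (int) R::rpois(rec_total);
  int start = (unif_rand() < 0.5) ? 0 : 1;
  if (k == 0) return start == 0 ? a : b;
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  Hap out;
  out.reserve(a.size() + b.size());
  // walk both sorted lists; a position belongs to segment = #breakpoints <= pos
  // segments alternate between the two parental haplotypes
  size_t ia = 0, ib = 0, seg_a, seg_b;
  while (ia < a.size() || ib < b.size()) {
    bool take_a;
    if (ia >= a.size()) take_a = false;
    else if (ib >= b.size()) take_a = true;
    else take_a = a[ia] <= b[ib];
    if (take_a) {
      seg_a = std::upper_bound(bp.begin(), bp.end(), a[ia]) - bp.begin();
      if ((int)((seg_a + start) % 2) == 0) out.push_back(a[ia]);
      ++ia;
    } else {
      seg_b = std::upper_bound(bp.begin(), bp.end(), b[ib]) - bp.begin();
      if ((int)((seg_b + start) % 2) == 1) out.push_back(b[ib]);
      ++ib;
    }
  }
  return out;
}

static void mutate(Hap &h, double mu_total, double L) {
  int m = (int) R::rpois(mu_total);
  for (int i = 0; i < m; ++i) {
    double p = unif_rand() * L;
    h.insert(std::lower_bound(h.begin(), h.end(), p), p);
  }
}

static int count_allele(const Pop &pop, double pos) {
  int c = 0;
  for (size_t i = 0; i < pop.size(); ++i)
    if (carries(pop[i], pos)) ++c;
  return c;
}

// remove mutations fixed in the whole population (invisible in any sample)
static void purge_fixed(Pop &pop, double keep_pos) {
  std::unordered_map<double, int> tally;
  for (size_t i = 0; i < pop.size(); ++i)
    for (size_t j = 0; j < pop[i].size(); ++j) tally[pop[i][j]]++;
  std::vector<double> fixed;
  int n = (int) pop.size();
  for (std::unordered_map<double, int>::iterator it = tally.begin();
       it != tally.end(); ++it)
    if (it->second == n && it->first != keep_pos) fixed.push_back(it->first);
  if (fixed.empty()) return;
  std::sort(fixed.begin(), fixed.end());
  for (size_t i = 0; i < pop.size(); ++i) {
    Hap &h = pop[i];
    Hap kept;
    kept.reserve(h.size());
    for (size_t j = 0; j < h.size(); ++j)
      if (!std::binary_search(fixed.begin(), fixed.end(), h[j]))
        kept.push_back(h[j]);
    h.swap(kept);
  }
}

// one Wright-Fisher generation; ben_pos < 0 disables selection
static void step(Pop &pop, Pop &next, double mu_total, double rec_total,
                 double L, double ben_pos, double s) {
  int n2 = (int) pop.size();
  int N = n2 / 2;
  std::vector<double> cum(N);
  double tot = 0.0;
  if (ben_pos >= 0 && s > 0) {
    for (int i = 0; i < N; ++i) {
      int copies = (carries(pop[2 * i], ben_pos) ? 1 : 0) +
                   (carries(pop[2 * i + 1], ben_pos) ? 1 : 0);
      tot += std::pow(1.0 + s, copies);
      cum[i] = tot;
    }
  } else {
    for (int i = 0; i < N; ++i) { tot += 1.0; cum[i] = tot; }
  }
  next.resize(n2);
  for (int j = 0; j < N; ++j) {
    for (int g = 0; g < 2; ++g) {
      double u = unif_rand() * tot;
      int par = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (par >= N) par = N - 1;
      next[2 * j + g] = make_gamete(pop[2 * par], pop[2 * par + 1],
                                    rec_total, L);
      mutate(next[2 * j + g], mu_total, L);
    }
  }
  pop.swap(next);
}

static std::vector<int> sample_indices(int n2, int n_sample) {
  // simple random sample without replacement
  std::vector<int> idx(n2);
  for (int i = 0; i < n2; ++i) idx[i] = i;
  for (int i = 0; i < n_sample; ++i) {
    int j = i + (int)(unif_rand() * (n2 - i));
    if (j >= n2) j = n2 - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(n_sample);
  return idx;
}

static IntegerMatrix build_matrix(const Pop &pop, const std::vector<int> &idx,
                                  const std::vector<double> &sites) {
  IntegerMatrix m((int) idx.size(), (int) sites.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    const Hap &h = pop[idx[i]];
    for (size_t j = 0; j < sites.size(); ++j)
      m((int) i, (int) j) = carries(h, sites[j]) ? 1 : 0;
  }
  return m;
}

// [[Rcpp::export]]
List wf_simulate_cpp(int n_sample, double L, double mu, double rec,
                     int N, int burnin_gens, int era_gens,
                     double ben_pos, double s, double start_freq,
                     int max_retries, bool sample_ref,
                     double fix_sample_freq) {
  int n2 = 2 * N;
  if (n_sample > n2) stop("sample size exceeds 2N haplotypes");
  double mu_total = mu * L, rec_total = rec * L;
  Pop pop(n2), scratch;
  for (int g = 0; g < burnin_gens; ++g) {
    step(pop, scratch, mu_total, rec_total, L, -1.0, 0.0);
    if (g % 32 == 31) purge_fixed(pop, -1.0);
  }
  purge_fixed(pop, -1.0);

  // reference sample drawn before the sweep era
  std::vector<int> ref_idx;
  Pop ref_pop;
  if (sample_ref) {
    ref_idx = sample_indices(n2, n_sample);
    ref_pop.resize(n_sample);
    for (int i = 0; i < n_sample; ++i) ref_pop[i] = pop[ref_idx[i]];
  }

  bool sweep = ben_pos >= 0;
  int retries = 0;
  bool fixed = false, lost_final = false;
  int gens_run = 0;
  if (sweep) {
    Pop saved = pop;  // conditioning on establishment: restart from here
    for (;;) {
      // inject the beneficial mutation at its starting frequency
      int k0 = (int) std::max(1.0, std::floor(start_freq * n2 + 0.5));
      std::vector<int> car = sample_indices(n2, k0);
      for (int i = 0; i < k0; ++i) {
        Hap &h = pop[car[i]];
        h.insert(std::lower_bound(h.begin(), h.end(), ben_pos), ben_pos);
      }
      bool lost = false;
      gens_run = 0;
      for (int g = 0; g < era_gens; ++g) {
        step(pop, scratch, mu_total, rec_total, L, ben_pos, s);
        ++gens_run;
        int cnt = count_allele(pop, ben_pos);
        if (cnt == 0) { lost = true; break; }
        if (cnt >= (int) std::ceil(fix_sample_freq * n2)) {
          fixed = (cnt == n2);
          break;
        }
        if (g % 32 == 31) purge_fixed(pop, ben_pos);
      }
      if (!lost) break;
      if (++retries > max_retries) { lost_final = true; break; }
      pop = saved;
    }
  } else {
    for (int g = 0; g < era_gens; ++g) {
      step(pop, scratch, mu_total, rec_total, L, -1.0, 0.0);
      if (g % 32 == 31) purge_fixed(pop, -1.0);
    }
    gens_run = era_gens;
  }

  std::vector<int> test_idx = sample_indices(n2, n_sample);

  // union of positions present in the sampled haplotypes (plus reference)
  std::unordered_map<double, int> present;
  for (size_t i = 0; i < test_idx.size(); ++i)
    for (size_t j = 0; j < pop[test_idx[i]].size(); ++j)
      present[pop[test_idx[i]][j]]++;
  if (sample_ref)
    for (int i = 0; i < n_sample; ++i)
      for (size_t j = 0; j < ref_pop[i].size(); ++j)
        present[ref_pop[i][j]]++;
  std::vector<double> sites;
  sites.reserve(present.size());
  int n_total = n_sample * (sample_ref ? 2 : 1);
  for (std::unordered_map<double, int>::iterator it = present.begin();
       it != present.end(); ++it)
    if (it->second < n_total || it->first == ben_pos)
      sites.push_back(it->first);  // drop sites fixed across all samples
  std::sort(sites.begin(), sites.end());

  IntegerMatrix test = build_matrix(pop, test_idx, sites);
  int ben_col = -1;
  if (sweep) {
    std::vector<double>::iterator it =
        std::lower_bound(sites.begin(), sites.end(), ben_pos);
    if (it != sites.end() && *it == ben_pos)
      ben_col = (int)(it - sites.begin());
  }

  List out = List::create(
      _["haplotypes"] = test,
      _["positions"] = NumericVector(sites.begin(), sites.end()),
      _["ben_col"] = ben_col + 1,  // 1-based, 0 if absent
      _["retries"] = retries,
      _["fixed"] = fixed,
      _["lost"] = lost_final,
      _["gens_run"] = gens_run);
  if (sample_ref) {
    std::vector<int> all_ref(n_sample);
    for (int i = 0; i < n_sample; ++i) all_ref[i] = i;
    out["ref_haplotypes"] = build_matrix(ref_pop, all_ref, sites);
  }
  return out;
}
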