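// Kingman coalescent engine for a three-population demographic model.
//
// Backwards in time: within each population, pairs of lineages coalesce at
// rate 1/(2N) per pair per generation (N = diploid size). Demographic events
// are applied at fixed times: a "merge" moves every lineage of a derived
// population into its source (a forward-in-time population split) and may
// reset the source size; a "pulse" moves each lineage of a sink population
// into a source with probability m (a forward-in-time admixture pulse).
//
// Two entry points:
//  - coal_branch_profile(): expected branch length subtending each joint
//    descendant configuration (i,j,k) across populations, the raw material
//    for expected site-frequency spectra under the infinite-sites model.
//  - coal_genotypes(): one genealogy per site; a single mutation is placed
//    on a branch chosen proportional to length, giving haploid 0/1 alleles
//    (every site segregates among the sampled lineages).
//
// Events matrix columns: time, type (0 = merge, 1 = pulse), a, b, x
//  merge: all lineages in pop a -> pop b, size[b] = x when x > 0
//  pulse: lineage in pop a -> pop b with probability x
// Populations are 0-based here; the R wrappers use 1-based labels.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Engine {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit Engine(uint64_t seed) : rng(seed) {}
  double runif() {
    double u;
    do { u = unif(rng); } while (u <= 0.0 || u >= 1.0);
    return u;
  }
  double rexp(double rate) { return -std::log(runif()) / rate; }
  int rint(int n) { return static_cast<int>(runif() * n) % n; }
};

struct EventRow {
  double time;
  int type; // 0 merge, 1 pulse
  int a, b;
  double x;
};

std::vector<EventRow> parse_events(const NumericMatrix& ev) {
  std::vector<EventRow> out;
  for (int r = 0; r < ev.nrow(); ++r) {
    EventRow e;
    e.time = ev(r, 0);
    e.type = static_cast<int>(ev(r, 1));
    e.a = static_cast<int>(ev(r, 2));
    e.b = static_cast<int>(ev(r, 3));
    e.x = ev(r, 4);
    out.push_back(e);
  }
  for (size_t r = 1; r < out.size(); ++r)
    if (out[r].time < out[r - 1].time)
      stop("demographic events must be sorted by time");
  return out;
}

} // namespace

// [[Rcpp::export(name = ".coal_branch_profile")]]
List coal_branch_profile(IntegerVector n_samples, NumericVector pop_sizes,
                         NumericMatrix events, int n_genealogies,
                         double seed) {
  const int npop = 3;
  if (n_samples.size() != npop || pop_sizes.size() != npop)
    stop("three populations expected");
  const int n1 = n_samples[0], n2 = n_samples[1], n3 = n_samples[2];
  const int ntot = n1 + n2 + n3;
  if (ntot < 2) stop("need at least two sampled lineages");
  const int d1 = n1 + 1, d2 = n2 + 1, d3 = n3 + 1;
  const int ncfg = d1 * d2 * d3;
  std::vector<EventRow> evs = parse_events(events);
  Engine eng(static_cast<uint64_t>(seed));

  std::vector<double> profile(ncfg, 0.0);
  double total_sum = 0.0;

  // A lineage's descendant configuration is fixed over its lifetime, so its
  // whole contribution to the branch profile is accrued once, at coalescence.
  const int nslots = 2 * ntot - 1;
  std::vector<int> cfg(nslots);
  std::vector<double> birth(nslots);
  std::vector<int> mem[3]; // active lineage slots per population
  for (int p = 0; p < npop; ++p) mem[p].reserve(nslots);

  for (int g = 0; g < n_genealogies; ++g) {
    for (int p = 0; p < npop; ++p) mem[p].clear();
    for (int i = 0; i < ntot; ++i) {
      int p = (i < n1) ? 0 : (i < n1 + n2 ? 1 : 2);
      // column-major strides so the R side can set dim = (n1+1, n2+1, n3+1)
      cfg[i] = (p == 0 ? 1 : (p == 1 ? d1 : d1 * d2));
      birth[i] = 0.0;
      mem[p].push_back(i);
    }
    double sizes[3] = {pop_sizes[0], pop_sizes[1], pop_sizes[2]};
    double t = 0.0;
    size_t iev = 0;
    int next_slot = ntot;
    int nact = ntot;

    while (nact > 1) {
      double rate[3], R = 0.0;
      for (int p = 0; p < npop; ++p) {
        double k = static_cast<double>(mem[p].size());
        rate[p] = 0.25 * k * (k - 1) / sizes[p];
        R += rate[p];
      }
      double t_next = (iev < evs.size()) ? evs[iev].time : R_PosInf;
      bool do_event;
      if (R <= 0.0) {
        if (!std::isfinite(t_next)) stop("lineages cannot reach a common ancestor under this model");
        t = t_next;
        do_event = true;
      } else {
        double w = eng.rexp(R);
        if (t + w >= t_next) { t = t_next; do_event = true; }
        else { t += w; do_event = false; }
      }
      if (do_event) {
        const EventRow& e = evs[iev];
        if (e.type == 0) {
          // a == b is a pure size change (ghost-ancestor relabelling)
          if (e.a != e.b && !mem[e.a].empty()) {
            mem[e.b].insert(mem[e.b].end(), mem[e.a].begin(), mem[e.a].end());
            mem[e.a].clear();
          }
          if (e.x > 0) sizes[e.b] = e.x;
        } else {
          std::vector<int>& src = mem[e.a];
          for (size_t i = 0; i < src.size();) {
            if (eng.runif() < e.x) {
              mem[e.b].push_back(src[i]);
              src[i] = src.back();
              src.pop_back();
            } else ++i;
          }
        }
        ++iev;
        continue;
      }
      // coalescence: pick population, then an unordered pair within it
      double u = eng.runif() * R;
      int p = 0;
      while (p < npop - 1 && u > rate[p]) { u -= rate[p]; ++p; }
      std::vector<int>& m = mem[p];
      int msz = static_cast<int>(m.size());
      int ia = eng.rint(msz);
      int ib = eng.rint(msz - 1);
      if (ib >= ia) ++ib;
      int li = m[ia], lj = m[ib];
      profile[cfg[li]] += t - birth[li];
      profile[cfg[lj]] += t - birth[lj];
      total_sum += (t - birth[li]) + (t - birth[lj]);
      int v = next_slot++;
      cfg[v] = cfg[li] + cfg[lj];
      birth[v] = t;
      // replace ia with the parent, swap-remove ib
      m[ia] = v;
      m[ib] = m.back();
      m.pop_back();
      --nact;
    }
  }

  NumericVector out(ncfg);
  for (int i = 0; i < ncfg; ++i) out[i] = profile[i] / n_genealogies;
  out.attr("dim") = IntegerVector::create(n1 + 1, n2 + 1, n3 + 1);
  return List::create(_["profile"] = out,
                      _["mean_total_length"] = total_sum / n_genealogies);
}

namespace {

struct Tree {
  std::vector<int> child1, child2;
  std::vector<double> node_time, blen;
  int root;
  double total;
};

// simulate one genealogy; fills tr and returns its total branch length
void simulate_tree(Engine& eng, int n1, int n2, int n3,
                   const NumericVector& pop_sizes,
                   const std::vector<EventRow>& evs, Tree& tr) {
  const int npop = 3;
  const int ntot = n1 + n2 + n3;
  const int nnodes = 2 * ntot - 1;
  tr.child1.assign(nnodes, -1);
  tr.child2.assign(nnodes, -1);
  tr.node_time.assign(nnodes, 0.0);
  tr.blen.assign(nnodes, 0.0);
  std::vector<int> node_pop(nnodes), active(ntot);
  int nact = ntot;
  for (int i = 0; i < ntot; ++i) {
    node_pop[i] = (i < n1) ? 0 : (i < n1 + n2 ? 1 : 2);
    active[i] = i;
  }
  double sizes[3] = {pop_sizes[0], pop_sizes[1], pop_sizes[2]};
  double t = 0.0;
  size_t iev = 0;
  int next_node = ntot;
  std::vector<int> members;

  while (nact > 1) {
    int k[3] = {0, 0, 0};
    for (int i = 0; i < nact; ++i) k[node_pop[active[i]]]++;
    double rate[3], R = 0.0;
    for (int p = 0; p < npop; ++p) {
      rate[p] = 0.25 * k[p] * (k[p] - 1) / sizes[p];
      R += rate[p];
    }
    double t_next = (iev < evs.size()) ? evs[iev].time : R_PosInf;
    bool do_event;
    if (R <= 0.0) {
      if (!std::isfinite(t_next))
        stop("lineages cannot reach a common ancestor under this model");
      t = t_next;
      do_event = true;
    } else {
      double w = eng.rexp(R);
      if (t + w >= t_next) { t = t_next; do_event = true; }
      else { t += w; do_event = false; }
    }
    if (do_event) {
      const EventRow& e = evs[iev];
      for (int i = 0; i < nact; ++i) {
        int v = active[i];
        if (e.type == 0) { if (node_pop[v] == e.a) node_pop[v] = e.b; }
        else if (node_pop[v] == e.a && eng.runif() < e.x) node_pop[v] = e.b;
      }
      if (e.type == 0 && e.x > 0) sizes[e.b] = e.x;
      ++iev;
      continue;
    }
    double u = eng.runif() * R;
    int p = 0;
    while (p < npop - 1 && u > rate[p]) { u -= rate[p]; ++p; }
    members.clear();
    for (int i = 0; i < nact; ++i)
      if (node_pop[active[i]] == p) members.push_back(i);
    int m = static_cast<int>(members.size());
    int ia = eng.rint(m), ib = eng.rint(m - 1);
    if (ib >= ia) ++ib;
    int v = next_node++;
    node_pop[v] = p;
    tr.node_time[v] = t;
    tr.child1[v] = active[members[ia]];
    tr.child2[v] = active[members[ib]];
    active[members[ia]] = v;
    active[members[ib]] = active[nact - 1];
    --nact;
  }
  tr.root = active[0];
  double tot = 0.0;
  for (int v = ntot; v < nnodes; ++v) {
    tr.blen[tr.child1[v]] = tr.node_time[v] - tr.node_time[tr.child1[v]];
    tr.blen[tr.child2[v]] = tr.node_time[v] - tr.node_time[tr.child2[v]];
  }
  for (int v = 0; v < nnodes; ++v) if (v != tr.root) tot += tr.blen[v];
  tr.total = tot;
}

} // namespace

// One segregating site per sampled genealogy, with genealogies drawn
// proportional to their total branch length: under infinite sites the
// mutation count of a genealogy is proportional to its length, so the
// site-frequency distribution is E[l_i] / E[T], not E[l_i / T]. A pool of
// n_sites genealogies is simulated with recorded sub-seeds, then sites
// resample the pool length-weighted and replay the chosen genealogy.
// [[Rcpp::export(name = ".coal_genotypes")]]
List coal_genotypes(IntegerVector n_samples, NumericVector pop_sizes,
                    NumericMatrix events, int n_sites, double seed) {
  const int npop = 3;
  if (n_samples.size() != npop || pop_sizes.size() != npop)
    stop("three populations expected");
  const int n1 = n_samples[0], n2 = n_samples[1], n3 = n_samples[2];
  const int ntot = n1 + n2 + n3;
  if (ntot < 2) stop("need at least two sampled lineages");
  std::vector<EventRow> evs = parse_events(events);
  Engine eng(static_cast<uint64_t>(seed));

  IntegerMatrix alleles(ntot, n_sites);
  Tree tr;
  std::vector<uint64_t> subseed(n_sites);
  std::vector<double> cumlen(n_sites);
  double total_sum = 0.0;

  for (int g = 0; g < n_sites; ++g) {
    subseed[g] = eng.rng();
    Engine sub(subseed[g]);
    simulate_tree(sub, n1, n2, n3, pop_sizes, evs, tr);
    total_sum += tr.total;
    cumlen[g] = (g ? cumlen[g - 1] : 0.0) + tr.total;
  }

  std::vector<int> stack_;
  const int nnodes = 2 * ntot - 1;
  for (int s = 0; s < n_sites; ++s) {
    double u = eng.runif() * cumlen[n_sites - 1];
    int j = static_cast<int>(std::lower_bound(cumlen.begin(), cumlen.end(), u)
                             - cumlen.begin());
    Engine sub(subseed[j]);
    simulate_tree(sub, n1, n2, n3, pop_sizes, evs, tr);
    double um = eng.runif() * tr.total, acc = 0.0;
    int mut = -1;
    for (int v = 0; v < nnodes; ++v) {
      if (v == tr.root) continue;
      acc += tr.blen[v];
      if (um <= acc) { mut = v; break; }
    }
    if (mut < 0) mut = (tr.root == 0) ? 1 : 0;
    stack_.clear();
    stack_.push_back(mut);
    while (!stack_.empty()) {
      int v = stack_.back();
      stack_.pop_back();
      if (v < ntot) alleles(v, s) = 1;
      else { stack_.push_back(tr.child1[v]); stack_.push_back(tr.child2[v]); }
    }
  }

  return List::create(_["alleles"] = alleles,
                      _["mean_total_length"] = total_sum / std::max(n_sites, 1));
}
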