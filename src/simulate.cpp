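// Forward Wright-Fisher simulation engine.
//
// Discrete generations, diploid random mating, infinite-sites mutation on a
// continuous [0, L) region, crossover recombination under a flat rate or a
// piecewise-constant genetic map, population splits / size changes /
// admixture pulses / ancient sampling, a focal selected mutation introduced
// at the region midpoint with checkpoint-restore rejection sampling, and an
// optional DFE mode (neutral + deleterious gamma-distributed mutations).
//
// All parameters arrive pre-scaled (N/Q, T/Q, mu*Q, r*Q, s*Q); the engine
// knows nothing about scaling. Times are integer generations before present;
// state(t) is produced from state(t+1) as t counts down to 0.

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256** with splitmix64 seeding. Self-contained so that the full
// engine state (including the generator) can be copied for checkpoints
// without touching R's RNG.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t x) {
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // uniform on (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline int rint(int n) {  // uniform integer on [0, n)
    return (int)(u01() * n) % n;
  }
  int rpois(double lambda) {
    if (lambda <= 0) return 0;
    if (lambda < 30.0) {  // Knuth
      double p = std::exp(-lambda), f = p, u = u01();
      int k = 0;
      while (u > f && k < 10000) { k++; p *= lambda / k; f += p; }
      return k;
    }
    double x = std::round(lambda + std::sqrt(lambda) * rnorm());
    return x < 0 ? 0 : (int)x;
  }
  double rnorm() {  // polar Box-Muller, one value per call (no cache: state simplicity)
    double u, v, w;
    do {
      u = 2.0 * u01() - 1.0; v = 2.0 * u01() - 1.0;
      w = u * u + v * v;
    } while (w >= 1.0 || w == 0.0);
    return u * std::sqrt(-2.0 * std::log(w) / w);
  }
  double rgamma(double shape, double scale) {
    // Marsaglia-Tsang; boost for shape < 1.
    if (shape < 1.0) {
      double u = u01();
      return rgamma(shape + 1.0, scale) * std::pow(u, 1.0 / shape);
    }
    double d = shape - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = rnorm(), v = 1.0 + c * x;
      if (v <= 0) continue;
      v = v * v * v;
      double u = u01();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v * scale;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v * scale;
    }
  }
};

// ---------------------------------------------------------------------------
// Haplotypes and populations
// ---------------------------------------------------------------------------
struct SelMut {
  double pos;
  double s;
  double h;
  bool focal;
};

struct Hap {
  std::vector<double> neut;   // sorted positions of neutral mutations
  std::vector<SelMut> sel;    // sorted (by pos) selected mutations (focal/DFE)
};

struct Pop {
  bool active = false;
  int N = 0;                  // diploid size
  std::vector<Hap> haps;      // 2N haplotypes; individual i owns rows 2i, 2i+1
  std::vector<Hap> back;      // reusable buffer for the next generation
};

struct ArchivedSample {
  int panel;
  std::vector<Hap> haps;      // 2 per individual, pairs adjacent
};

// event types
enum EvType { EV_SPLIT = 0, EV_PULSE = 1, EV_SIZE = 2, EV_SAMPLE = 3 };

struct Event {
  int type;
  int time;
  int pop = -1;      // child (split), dest (pulse), pop (size/sample)
  int other = -1;    // parent (split), source (pulse)
  int N = 0;         // size (split/size)
  double frac = 0;   // pulse fraction
  int n_ind = 0;     // sample size (individuals)
  int panel = -1;    // sample panel id
};

struct Engine {
  // configuration
  double L, mu_hap;                 // region length; mutations per haplotype per gen
  std::vector<double> map_phys;    // piecewise map breakpoints (len = nseg+1)
  std::vector<double> map_cumM;    // cumulative Morgans at breakpoints
  double total_M;
  bool dfe_enabled = false;
  double dfe_p_del = 0, dfe_shape = 0, dfe_scale = 0, dfe_h = 0, dfe_smul = 1;
  int scenario = 0;                // 0 neutral, 1 sweep, 2 ai, 3 dfe
  double focal_pos = 0, focal_s = 0, focal_h = 0.5;
  int intro_pop = -1, sel_pop = -1, T_mut = -1, T_sel = -1, T_pulse_cond = -1;
  double min_freq = 0.01;
  int max_attempts = 2000;
  int recipient_panel = -1;
  int prune_interval = 64;

  std::vector<Event> events;       // sorted by time descending
  std::vector<Pop> pops;
  std::vector<ArchivedSample> archived;
  Rng rng;

  // mutable bookkeeping (reused across generations)
  std::vector<std::vector<double> > cums;   // cumulative fitness weights

  struct Checkpoint {
    std::vector<Pop> pops;
    std::vector<ArchivedSample> archived;
    int t;
    bool valid = false;
  };

  Checkpoint save(int t) {
    Checkpoint c;
    c.pops = pops;
    c.archived = archived;
    c.t = t;
    c.valid = true;
    return c;
  }
  void restore(const Checkpoint &c) {
    pops = c.pops;
    archived = c.archived;
    // rng deliberately NOT restored: replays must explore new trajectories
  }

  // crossover position: invert the piecewise-linear cumulative map
  double crossover_pos() {
    double g = u() * total_M;
    size_t lo = 0, hi = map_cumM.size() - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (map_cumM[mid] <= g) lo = mid; else hi = mid;
    }
    double seg_M = map_cumM[hi] - map_cumM[lo];
    double f = seg_M > 0 ? (g - map_cumM[lo]) / seg_M : 0.5;
    return map_phys[lo] + f * (map_phys[hi] - map_phys[lo]);
  }

  inline double u() { return rng.u01(); }

  void add_mutations(Hap &child) {
    int nm = rng.rpois(mu_hap);
    for (int i = 0; i < nm; i++) {
      double pos = u() * L;
      if (dfe_enabled && u() < dfe_p_del) {
        SelMut m;
        m.pos = pos;
        m.s = -dfe_smul * rng.rgamma(dfe_shape, dfe_scale);
        m.h = dfe_h;
        m.focal = false;
        child.sel.insert(
          std::upper_bound(child.sel.begin(), child.sel.end(), m,
                           [](const SelMut &a, const SelMut &b) { return a.pos < b.pos; }),
          m);
      } else {
        child.neut.insert(std::upper_bound(child.neut.begin(), child.neut.end(), pos), pos);
      }
    }
  }

  void meiosis(const Hap &a, const Hap &b, Hap &child) {
    int nc = total_M > 0 ? rng.rpois(total_M) : 0;
    if (nc == 0) {
      child = (u() < 0.5) ? a : b;
    } else {
      std::vector<double> bp(nc);
      for (int i = 0; i < nc; i++) bp[i] = crossover_pos();
      std::sort(bp.begin(), bp.end());
      bp.push_back(L + 1.0);
      child.neut.clear();
      child.sel.clear();
      const Hap *cur = (u() < 0.5) ? &a : &b;
      double prev = -1.0;
      for (double cut : bp) {
        {  // neutral segment [prev, cut)
          auto lo = std::upper_bound(cur->neut.begin(), cur->neut.end(), prev);
          auto hi = std::lower_bound(cur->neut.begin(), cur->neut.end(), cut);
          child.neut.insert(child.neut.end(), lo, hi);
        }
        {
          auto cmp = [](const SelMut &m, double p) { return m.pos < p; };
          auto lo = std::lower_bound(cur->sel.begin(), cur->sel.end(), prev, cmp);
          while (lo != cur->sel.end() && lo->pos <= prev) ++lo;
          auto hi = std::lower_bound(cur->sel.begin(), cur->sel.end(), cut, cmp);
          child.sel.insert(child.sel.end(), lo, hi);
        }
        cur = (cur == &a) ? &b : &a;
        prev = cut;
      }
    }
    add_mutations(child);
  }

  // does selection act in population p when producing generation t?
  inline bool focal_active(int p, int t) const {
    return (scenario == 1 || scenario == 2) && p == sel_pop && T_sel >= 0 && t < T_sel;
  }

  // fitness of individual j in pop p (focal selection toggled by `fa`)
  double fitness(const Pop &pp, int j, bool fa) {
    const Hap &h1 = pp.haps[2 * j], &h2 = pp.haps[2 * j + 1];
    double w = 1.0;
    size_t i1 = 0, i2 = 0;
    while (i1 < h1.sel.size() || i2 < h2.sel.size()) {
      bool take1;
      if (i1 >= h1.sel.size()) take1 = false;
      else if (i2 >= h2.sel.size()) take1 = true;
      else take1 = h1.sel[i1].pos <= h2.sel[i2].pos;
      if (i1 < h1.sel.size() && i2 < h2.sel.size() &&
          h1.sel[i1].pos == h2.sel[i2].pos) {
        const SelMut &m = h1.sel[i1];
        if (!m.focal || fa) w *= (1.0 + m.s);       // homozygote
        i1++; i2++;
      } else if (take1) {
        const SelMut &m = h1.sel[i1];
        if (!m.focal || fa) w *= (1.0 + m.h * m.s); // heterozygote
        i1++;
      } else {
        const SelMut &m = h2.sel[i2];
        if (!m.focal || fa) w *= (1.0 + m.h * m.s);
        i2++;
      }
    }
    return w > 0 ? w : 0.0;
  }

  // cumulative fitness weights for pop p; returns false if uniform (fast path)
  bool build_weights(const Pop &pp, bool fa, std::vector<double> &cum) {
    bool any_sel = false;
    for (const Hap &h : pp.haps) {
      for (const SelMut &m : h.sel) {
        if (!m.focal || fa) { any_sel = true; break; }
      }
      if (any_sel) break;
    }
    if (!any_sel) return false;
    cum.resize(pp.N);
    double acc = 0;
    for (int j = 0; j < pp.N; j++) {
      acc += fitness(pp, j, fa);
      cum[j] = acc;
    }
    if (acc <= 0) return false;  // degenerate: all inviable, fall back to drift
    return true;
  }

  int pick_parent(const Pop &pp, const std::vector<double> &cum, bool weighted) {
    if (!weighted) return rng.rint(pp.N);
    double g = u() * cum.back();
    return (int)(std::lower_bound(cum.begin(), cum.end(), g) - cum.begin());
  }

  // produce generation t for all active pops, honouring events at time t
  void step(int t, const std::unordered_map<int, std::vector<const Event *> > &sched) {
    std::vector<const Event *> splits, pulses, sizes, samples;
    auto it = sched.find(t);
    if (it != sched.end()) {
      for (const Event *e : it->second) {
        switch (e->type) {
          case EV_SPLIT:  splits.push_back(e);  break;
          case EV_PULSE:  pulses.push_back(e);  break;
          case EV_SIZE:   sizes.push_back(e);   break;
          case EV_SAMPLE: samples.push_back(e); break;
        }
      }
    }
    // pulse lookup: dest pop -> (source, frac)
    std::vector<int> pulse_src(pops.size(), -1);
    std::vector<double> pulse_frac(pops.size(), 0.0);
    for (const Event *e : pulses) {
      pulse_src[e->pop] = e->other;
      pulse_frac[e->pop] = e->frac;
    }
    // size changes apply to generation t
    std::vector<int> newN(pops.size());
    std::vector<char> was_active(pops.size());
    for (size_t p = 0; p < pops.size(); p++) {
      newN[p] = pops[p].N;
      was_active[p] = pops[p].active ? 1 : 0;
    }
    for (const Event *e : sizes) newN[e->pop] = e->N;
    std::vector<int> split_src(pops.size(), -1);
    for (const Event *e : splits) {
      split_src[e->pop] = e->other;
      newN[e->pop] = e->N;
    }

    // fitness weights are computed from the parent generation (state t+1),
    // which stays untouched in pops[...].haps until the final swap
    std::vector<char> weighted(pops.size(), 0);
    if (cums.size() != pops.size()) cums.resize(pops.size());
    for (size_t p = 0; p < pops.size(); p++) {
      if (was_active[p]) {
        weighted[p] = build_weights(pops[p], focal_active((int)p, t), cums[p]) ? 1 : 0;
      }
    }

    for (size_t p = 0; p < pops.size(); p++) {
      if (!was_active[p] && split_src[p] < 0) continue;
      int Nn = newN[p];
      std::vector<Hap> &nh = pops[p].back;
      nh.resize(2 * Nn);
      for (int i = 0; i < Nn; i++) {
        for (int k = 0; k < 2; k++) {
          int pp;
          if (split_src[p] >= 0) {
            pp = split_src[p];
          } else if (pulse_src[p] >= 0 && u() < pulse_frac[p]) {
            pp = pulse_src[p];
          } else {
            pp = (int)p;
          }
          const Pop &par = pops[pp];
          int j = pick_parent(par, cums[pp], weighted[pp] != 0);
          meiosis(par.haps[2 * j], par.haps[2 * j + 1], nh[2 * i + k]);
        }
      }
    }
    for (size_t p = 0; p < pops.size(); p++) {
      if (!was_active[p] && split_src[p] < 0) continue;
      pops[p].haps.swap(pops[p].back);
      pops[p].N = newN[p];
      pops[p].active = true;
    }

    // ancient sampling (after the generation exists)
    for (const Event *e : samples) {
      if (e->time == 0) continue;  // present-day panels handled at the end
      archive_sample(*e);
    }
  }

  void archive_sample(const Event &e) {
    ArchivedSample a;
    a.panel = e.panel;
    const Pop &pp = pops[e.pop];
    std::vector<int> idx(pp.N);
    for (int i = 0; i < pp.N; i++) idx[i] = i;
    // partial Fisher-Yates: first n_ind entries are the sampled individuals
    for (int i = 0; i < e.n_ind && i < pp.N; i++) {
      int j = i + rng.rint(pp.N - i);
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < e.n_ind; i++) {
      a.haps.push_back(pp.haps[2 * idx[i]]);
      a.haps.push_back(pp.haps[2 * idx[i] + 1]);
    }
    archived.push_back(a);
  }

  void introduce_focal() {
    Pop &pp = pops[intro_pop];
    int j = rng.rint(2 * pp.N);
    SelMut m;
    m.pos = focal_pos;
    m.s = focal_s;
    m.h = focal_h;
    m.focal = true;
    Hap &h = pp.haps[j];
    h.sel.insert(
      std::upper_bound(h.sel.begin(), h.sel.end(), m,
                       [](const SelMut &a, const SelMut &b) { return a.pos < b.pos; }),
      m);
  }

  long focal_count(const Pop &pp) const {
    long c = 0;
    for (const Hap &h : pp.haps)
      for (const SelMut &m : h.sel)
        if (m.focal) { c++; break; }
    return c;
  }
  long focal_count_all() const {
    long c = 0;
    for (const Pop &pp : pops) if (pp.active) c += focal_count(pp);
    return c;
  }

  // remove positions fixed across every current haplotype and every archived
  // haplotype (they are monomorphic in any possible output)
  void prune_fixed() {
    std::unordered_map<double, long> counts;
    long total = 0;
    auto tally = [&](const Hap &h) {
      total++;
      for (double p : h.neut) counts[p]++;
      for (const SelMut &m : h.sel) if (!m.focal) counts[m.pos]++;
    };
    for (const Pop &pp : pops) if (pp.active) for (const Hap &h : pp.haps) tally(h);
    for (const ArchivedSample &a : archived) for (const Hap &h : a.haps) tally(h);
    if (total == 0) return;
    std::unordered_map<double, char> fixed;
    for (auto &kv : counts) if (kv.second == total) fixed[kv.first] = 1;
    if (fixed.empty()) return;
    auto strip = [&](Hap &h) {
      size_t w = 0;
      for (size_t i = 0; i < h.neut.size(); i++)
        if (fixed.find(h.neut[i]) == fixed.end()) h.neut[w++] = h.neut[i];
      h.neut.resize(w);
      w = 0;
      for (size_t i = 0; i < h.sel.size(); i++)
        if (h.sel[i].focal || fixed.find(h.sel[i].pos) == fixed.end()) h.sel[w++] = h.sel[i];
      h.sel.resize(w);
    };
    for (Pop &pp : pops) if (pp.active) for (Hap &h : pp.haps) strip(h);
    for (ArchivedSample &a : archived) for (Hap &h : a.haps) strip(h);
  }
};

// [[Rcpp::export(name = ".wf_simulate")]]
List wf_simulate(List cfg) {
  Engine E;
  E.L = as<double>(cfg["L"]);
  double mu = as<double>(cfg["mu"]);          // per site per generation, scaled
  E.mu_hap = mu * E.L;
  E.map_phys = as<std::vector<double> >(cfg["map_phys"]);
  E.map_cumM = as<std::vector<double> >(cfg["map_cumM"]);
  E.total_M = E.map_cumM.back();
  E.prune_interval = as<int>(cfg["prune_interval"]);
  E.rng.seed((uint64_t)as<double>(cfg["seed"]));

  E.scenario = as<int>(cfg["scenario"]);
  if (E.scenario == 1 || E.scenario == 2) {
    List f = cfg["focal"];
    E.focal_pos = as<double>(f["pos"]);
    E.focal_s = as<double>(f["s"]);
    E.focal_h = as<double>(f["h"]);
    E.intro_pop = as<int>(f["intro_pop"]);
    E.sel_pop = as<int>(f["sel_pop"]);
    E.T_mut = as<int>(f["T_mut"]);
    E.T_sel = as<int>(f["T_sel"]);
    E.T_pulse_cond = as<int>(f["T_pulse_cond"]);   // -1 for sweep
    E.min_freq = as<double>(f["min_freq"]);
    E.max_attempts = as<int>(f["max_attempts"]);
    E.recipient_panel = as<int>(f["recipient_panel"]);
  }
  if (cfg.containsElementNamed("dfe") && !Rf_isNull(cfg["dfe"])) {
    List d = cfg["dfe"];
    E.dfe_enabled = true;
    E.dfe_p_del = as<double>(d["p_del"]);
    E.dfe_shape = as<double>(d["shape"]);
    // reflected gamma with expected value E[s] < 0: scale = |E[s]| / shape
    E.dfe_scale = as<double>(d["mean_abs"]) / E.dfe_shape;
    E.dfe_h = as<double>(d["h"]);
    E.dfe_smul = as<double>(d["s_multiplier"]);
  }

  // populations and events
  std::vector<int> N_init = as<std::vector<int> >(cfg["pop_N"]);
  int npop = (int)N_init.size();
  E.pops.resize(npop);
  List evl = cfg["events"];
  int max_time = 0;
  for (int i = 0; i < evl.size(); i++) {
    List e = evl[i];
    Event ev;
    ev.type = as<int>(e["type"]);
    ev.time = as<int>(e["time"]);
    if (e.containsElementNamed("pop")) ev.pop = as<int>(e["pop"]);
    if (e.containsElementNamed("other")) ev.other = as<int>(e["other"]);
    if (e.containsElementNamed("N")) ev.N = as<int>(e["N"]);
    if (e.containsElementNamed("frac")) ev.frac = as<double>(e["frac"]);
    if (e.containsElementNamed("n_ind")) ev.n_ind = as<int>(e["n_ind"]);
    if (e.containsElementNamed("panel")) ev.panel = as<int>(e["panel"]);
    E.events.push_back(ev);
    if (ev.time > max_time) max_time = ev.time;
  }
  std::unordered_map<int, std::vector<const Event *> > sched;
  for (const Event &e : E.events) sched[e.time].push_back(&e);

  int burnin = as<int>(cfg["burnin"]);
  int t_start = max_time + burnin;
  int root = as<int>(cfg["root_pop"]);
  E.pops[root].active = true;
  E.pops[root].N = N_init[root];
  E.pops[root].haps.assign(2 * N_init[root], Hap());

  // driver with rejection sampling
  Engine::Checkpoint ckptA, ckptB;
  int attempts_intro = 0, attempts_end = 0;
  bool need_cond = (E.scenario == 1 || E.scenario == 2);
  bool failed = false;

  int t = t_start;
  int since_prune = 0;
  while (t > 0) {
    t--;
    E.step(t, sched);
    if (++since_prune >= E.prune_interval) {
      E.prune_fixed();
      since_prune = 0;
    }

    if (need_cond && t == E.T_mut) {
      ckptA = E.save(t);             // state saved before the mutation exists
      E.introduce_focal();
    }
    if (need_cond && t < E.T_mut) {
      bool at_pulse = (E.scenario == 2 && t == E.T_pulse_cond);
      bool lost = ckptB.valid ? (E.focal_count(E.pops[E.sel_pop]) == 0)
                              : (E.focal_count_all() == 0);
      bool transfer_fail =
        at_pulse && E.focal_count(E.pops[E.sel_pop]) == 0;
      if (lost || transfer_fail) {
        const Engine::Checkpoint &ck = ckptB.valid ? ckptB : ckptA;
        int &ctr = ckptB.valid ? attempts_end : attempts_intro;
        if (++ctr > E.max_attempts) { failed = true; break; }
        E.restore(ck);
        t = ck.t;
        if (!ckptB.valid) E.introduce_focal();
        since_prune = 0;
        continue;
      }
      if (at_pulse && !ckptB.valid) {
        ckptB = E.save(t);           // transfer succeeded: new restore point
      }
    }

    if (t == 0 && need_cond) {
      const Pop &rec = E.pops[E.sel_pop];
      double freq = (double)E.focal_count(rec) / (2.0 * rec.N);
      if (freq < E.min_freq) {
        const Engine::Checkpoint &ck = ckptB.valid ? ckptB : ckptA;
        int &ctr = ckptB.valid ? attempts_end : attempts_intro;
        if (++ctr > E.max_attempts) { failed = true; break; }
        E.restore(ck);
        t = ck.t;
        if (!ckptB.valid) E.introduce_focal();
        since_prune = 0;
      }
    }
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }

  if (failed) {
    return List::create(_["success"] = false,
                        _["attempts_intro"] = attempts_intro,
                        _["attempts_end"] = attempts_end);
  }

  // present-day sampling
  for (const Event &e : E.events) {
    if (e.type == EV_SAMPLE && e.time == 0) E.archive_sample(e);
  }
  // order samples by panel id
  std::stable_sort(E.archived.begin(), E.archived.end(),
                   [](const ArchivedSample &a, const ArchivedSample &b) {
                     return a.panel < b.panel;
                   });

  std::vector<const Hap *> sample_haps;
  std::vector<int> sample_panel;
  for (const ArchivedSample &a : E.archived) {
    for (const Hap &h : a.haps) {
      sample_haps.push_back(&h);
      sample_panel.push_back(a.panel);
    }
  }
  int nh = (int)sample_haps.size();

  // segregating sites among the sampled haplotypes
  std::unordered_map<double, int> counts;
  for (const Hap *h : sample_haps) {
    for (double p : h->neut) counts[p]++;
    for (const SelMut &m : h->sel) counts[m.pos]++;
  }
  std::vector<double> seg;
  for (auto &kv : counts)
    if (kv.second > 0 && kv.second < nh) seg.push_back(kv.first);
  std::sort(seg.begin(), seg.end());

  // integer bp positions (1-based); collisions pushed right
  int ns = (int)seg.size();
  IntegerVector positions(ns);
  std::unordered_map<double, int> col_of;
  {
    int prev = 0;
    for (int i = 0; i < ns; i++) {
      int bp = (int)std::floor(seg[i]) + 1;
      if (bp <= prev) bp = prev + 1;
      positions[i] = bp;
      prev = bp;
      col_of[seg[i]] = i;
    }
  }

  IntegerMatrix haps(nh, ns);
  for (int r = 0; r < nh; r++) {
    const Hap *h = sample_haps[r];
    for (double p : h->neut) {
      auto it = col_of.find(p);
      if (it != col_of.end()) haps(r, it->second) = 1;
    }
    for (const SelMut &m : h->sel) {
      auto it = col_of.find(m.pos);
      if (it != col_of.end()) haps(r, it->second) = 1;
    }
  }

  // focal bookkeeping
  double focal_pop_freq = NA_REAL, focal_sample_freq = NA_REAL;
  int focal_bp = NA_INTEGER;
  if (need_cond) {
    const Pop &rec = E.pops[E.sel_pop];
    focal_pop_freq = (double)E.focal_count(rec) / (2.0 * rec.N);
    int cnt = 0, tot = 0;
    for (int r = 0; r < nh; r++) {
      if (sample_panel[r] != E.recipient_panel) continue;
      tot++;
      for (const SelMut &m : sample_haps[r]->sel)
        if (m.focal) { cnt++; break; }
    }
    focal_sample_freq = tot > 0 ? (double)cnt / tot : NA_REAL;
    auto it = col_of.find(E.focal_pos);
    if (it != col_of.end()) focal_bp = positions[it->second];
  }

  return List::create(
    _["success"] = true,
    _["haps"] = haps,
    _["positions"] = positions,
    _["panel"] = IntegerVector(sample_panel.begin(), sample_panel.end()),
    _["focal_bp"] = focal_bp,
    _["focal_pop_freq"] = focal_pop_freq,
    _["focal_sample_freq"] = focal_sample_freq,
    _["attempts_intro"] = attempts_intro,
    _["attempts_end"] = attempts_end);
}
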