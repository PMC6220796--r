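#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Continuous-time Gillespie engine for the gridded diversification model.
//
// State is population-based: a population is the presence of one species in
// one cell. All three processes (speciation lambda, colonization gamma,
// local extinction mu) are per-population with uniform rates, so the total
// event rate is N_pop * (lambda + gamma + mu) and each event draws a
// population uniformly. Cells are linear indices 0..A-1 on an
// nrow x ncol grid, row-major.
//
// Event kind codes: 1 speciation, 2 colonization, 3 local_extinction,
// 4 species_extinction. Death type codes: 0 extant, 1 local extinction of
// the last population, 2 pseudoextinction (single-population parent
// relabeled at speciation).

namespace {

struct EventLog {
  std::vector<double> time;
  std::vector<int> kind, species, cell, daughter;
  std::vector<int> no_effect;
  void push(double t, int k, int sp, int cl, int dau, int noeff) {
    time.push_back(t); kind.push_back(k); species.push_back(sp);
    cell.push_back(cl); daughter.push_back(dau); no_effect.push_back(noeff);
  }
};

struct Engine {
  int nrow, ncol, A, KL;
  double lambda, gamma, mu, T;
  bool global;          // global (any eligible cell) vs local (4-neighbour)
  bool global_uniform;  // variant: global target uniform over all cells, no-op if ineligible
  int max_species;
  bool record_full;
  long check_every;

  double t = 0.0;
  std::vector<int> pop_sp, pop_cell;            // flat population index
  std::vector<std::vector<int>> occ;            // per-cell occupant species
  std::vector<int> sp_range;                    // per-species range size (1-based ids; [0] unused)
  std::vector<int> sp_parent;
  std::vector<double> sp_origin, sp_death;
  std::vector<int> sp_death_type;
  int n_extant = 0;
  long n_spec = 0, n_col_ok = 0, n_col_noop = 0, n_locext = 0, n_spext = 0;
  EventLog log;
  std::vector<int> elig;                        // scratch for global dispersal

  void new_species(int parent, double origin) {
    sp_parent.push_back(parent);
    sp_origin.push_back(origin);
    sp_death.push_back(NA_REAL);
    sp_death_type.push_back(0);
    sp_range.push_back(0);
    ++n_extant;
  }

  int n_created() const { return (int)sp_parent.size() - 1; }

  void add_pop(int sp, int cell) {
    pop_sp.push_back(sp); pop_cell.push_back(cell);
    occ[cell].push_back(sp);
    ++sp_range[sp];
  }

  bool cell_has(int cell, int sp) const {
    const std::vector<int>& v = occ[cell];
    for (size_t i = 0; i < v.size(); ++i) if (v[i] == sp) return true;
    return false;
  }

  void occ_remove(int cell, int sp) {
    std::vector<int>& v = occ[cell];
    for (size_t i = 0; i < v.size(); ++i)
      if (v[i] == sp) { v[i] = v.back(); v.pop_back(); return; }
    stop("internal: occupant list inconsistent");
  }

  // remove population j (swap-with-last delete)
  void remove_pop(int j) {
    int sp = pop_sp[j], cell = pop_cell[j];
    occ_remove(cell, sp);
    --sp_range[sp];
    pop_sp[j] = pop_sp.back(); pop_cell[j] = pop_cell.back();
    pop_sp.pop_back(); pop_cell.pop_back();
    (void)sp;
  }

  void kill_species(int sp, int type) {
    sp_death[sp] = t;
    sp_death_type[sp] = type;
    --n_extant;
    ++n_spext;
    if (record_full) log.push(t, 4, sp, NA_INTEGER, NA_INTEGER, NA_INTEGER);
  }

  void do_speciation(int j) {
    int parent = pop_sp[j], cell = pop_cell[j];
    new_species(parent, t);
    int dau = n_created();           // ids are 1-based: founder = 1
    // relabel population j
    occ_remove(cell, parent);
    occ[cell].push_back(dau);
    pop_sp[j] = dau;
    --sp_range[parent];
    ++sp_range[dau];
    ++n_spec;
    if (record_full) log.push(t, 1, parent, cell, dau, NA_INTEGER);
    if (sp_range[parent] == 0) kill_species(parent, 2);
  }

  void do_local_extinction(int j) {
    int sp = pop_sp[j], cell = pop_cell[j];
    remove_pop(j);
    ++n_locext;
    if (record_full) log.push(t, 3, sp, cell, NA_INTEGER, NA_INTEGER);
    if (sp_range[sp] == 0) kill_species(sp, 1);
  }

  bool eligible(int cell, int sp) const {
    return (int)occ[cell].size() < KL && !cell_has(cell, sp);
  }

  void do_colonization(int j) {
    int sp = pop_sp[j], cell = pop_cell[j];
    int target = -1;
    if (!global) {
      int dir = (int)(unif_rand() * 4.0); if (dir > 3) dir = 3;
      int r = cell / ncol, c = cell % ncol;
      switch (dir) {
        case 0: --r; break; case 1: ++r; break;
        case 2: --c; break; default: ++c; break;
      }
      if (r >= 0 && r < nrow && c >= 0 && c < ncol) {
        int cand = r * ncol + c;
        if (eligible(cand, sp)) target = cand;
      }
    } else if (global_uniform) {
      int cand = (int)(unif_rand() * A); if (cand >= A) cand = A - 1;
      if (eligible(cand, sp)) target = cand;
    } else {
      elig.clear();
      for (int cand = 0; cand < A; ++cand)
        if (eligible(cand, sp)) elig.push_back(cand);
      if (!elig.empty()) {
        int k = (int)(unif_rand() * elig.size());
        if (k >= (int)elig.size()) k = (int)elig.size() - 1;
        target = elig[k];
      }
    }
    if (target >= 0) {
      add_pop(sp, target);
      ++n_col_ok;
      if (record_full) log.push(t, 2, sp, target, NA_INTEGER, 0);
    } else {
      ++n_col_noop;
      if (record_full) log.push(t, 2, sp, cell, NA_INTEGER, 1);
    }
  }

  void check_state() const {
    long tot = 0;
    std::vector<int> rng(sp_range.size(), 0);
    for (int c = 0; c < A; ++c) {
      if ((int)occ[c].size() > KL) stop("invariant violated: cell over K_L");
      tot += (long)occ[c].size();
      for (size_t i = 0; i < occ[c].size(); ++i) {
        int sp = occ[c][i];
        ++rng[sp];
        for (size_t k = i + 1; k < occ[c].size(); ++k)
          if (occ[c][k] == sp) stop("invariant violated: duplicate occupant");
      }
    }
    if (tot != (long)pop_sp.size())
      stop("invariant violated: population total mismatch");
    for (size_t s = 1; s < sp_range.size(); ++s) {
      if (rng[s] != sp_range[s]) stop("invariant violated: range index mismatch");
      if (R_IsNA(sp_death[s]) && sp_range[s] < 1)
        stop("invariant violated: extant species with empty range");
    }
    for (size_t j = 0; j < pop_sp.size(); ++j)
      if (!const_cast<Engine*>(this)->cell_has(pop_cell[j], pop_sp[j]))
        stop("invariant violated: population index not in cell list");
  }

  std::string run() {
    // founder: one species in a uniformly random cell
    int cell0 = (int)(unif_rand() * A); if (cell0 >= A) cell0 = A - 1;
    new_species(NA_INTEGER, 0.0);
    add_pop(1, cell0);
    if (record_full) log.push(0.0, 1, NA_INTEGER, cell0, 1, NA_INTEGER);

    const double per_pop = lambda + gamma + mu;
    long n_events = 0;
    for (;;) {
      int N = (int)pop_sp.size();
      if (N == 0) return "extinct";
      double rate = N * per_pop;
      double dt = exp_rand() / rate;
      if (t + dt >= T) { t = T; return "time"; }
      t += dt;
      double u = unif_rand() * per_pop;
      int j = (int)(unif_rand() * N); if (j >= N) j = N - 1;
      if (u < lambda) {
        do_speciation(j);
        if (n_created() >= max_species) return "max_species";
      } else if (u < lambda + gamma) {
        do_colonization(j);
      } else {
        do_local_extinction(j);
      }
      ++n_events;
      if (check_every > 0 && n_events % check_every == 0) check_state();
      if (n_events % 1048576 == 0) Rcpp::checkUserInterrupt();
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int nrow, int ncol, int KL,
                double lambda, double gamma, double mu, double T,
                bool global_dispersal, bool global_uniform,
                int max_species, bool record_full, double check_every) {
  Engine e;
  e.nrow = nrow; e.ncol = ncol; e.A = nrow * ncol; e.KL = KL;
  e.lambda = lambda; e.gamma = gamma; e.mu = mu; e.T = T;
  e.global = global_dispersal; e.global_uniform = global_uniform;
  e.max_species = max_species; e.record_full = record_full;
  e.check_every = (long)check_every;
  e.occ.assign(e.A, std::vector<int>());
  e.sp_parent.push_back(NA_INTEGER); e.sp_origin.push_back(NA_REAL);
  e.sp_death.push_back(NA_REAL); e.sp_death_type.push_back(NA_INTEGER);
  e.sp_range.push_back(0); e.n_extant = 0;   // slot 0 unused

  std::string why = e.run();
  if (e.check_every > 0) e.check_state();

  int nsp = e.n_created();
  IntegerVector id(nsp), parent(nsp), death_type(nsp), range(nsp);
  NumericVector origin(nsp), death(nsp);
  for (int s = 1; s <= nsp; ++s) {
    id[s - 1] = s;
    parent[s - 1] = e.sp_parent[s];
    origin[s - 1] = e.sp_origin[s];
    death[s - 1] = e.sp_death[s];
    death_type[s - 1] = e.sp_death_type[s];
    range[s - 1] = e.sp_range[s];
  }
  DataFrame species = DataFrame::create(
    _["id"] = id, _["parent"] = parent, _["origin"] = origin,
    _["death"] = death, _["death_type"] = death_type, _["range"] = range);

  int N = (int)e.pop_sp.size();
  IntegerVector psp(N), pcell(N);
  for (int j = 0; j < N; ++j) { psp[j] = e.pop_sp[j]; pcell[j] = e.pop_cell[j]; }
  DataFrame pops = DataFrame::create(_["species"] = psp, _["cell"] = pcell);

  List out = List::create(
    _["species"] = species,
    _["populations"] = pops,
    _["t_end"] = e.t,
    _["termination"] = why,
    _["n_extant"] = e.n_extant,
    _["counts"] = IntegerVector::create(
      _["speciation"] = (int)e.n_spec,
      _["colonization"] = (int)e.n_col_ok,
      _["colonization_noop"] = (int)e.n_col_noop,
      _["local_extinction"] = (int)e.n_locext,
      _["species_extinction"] = (int)e.n_spext));
  if (record_full) {
    int M = (int)e.log.time.size();
    NumericVector lt(M); IntegerVector lk(M), ls(M), lc(M), ld(M), ln(M);
    for (int i = 0; i < M; ++i) {
      lt[i] = e.log.time[i]; lk[i] = e.log.kind[i]; ls[i] = e.log.species[i];
      lc[i] = e.log.cell[i]; ld[i] = e.log.daughter[i]; ln[i] = e.log.no_effect[i];
    }
    out["events"] = DataFrame::create(
      _["time"] = lt, _["kind"] = lk, _["species"] = ls,
      _["cell"] = lc, _["daughter"] = ld, _["no_effect"] = ln);
  }
  return out;
}
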