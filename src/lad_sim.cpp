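// Discrete-generation branching-process simulator of tumor initiation with
// lesion repair / translesion replication at driver loci, genealogy tracking
// and MRCA/LAD extraction.
//
// Duplex states at a driver locus: 0=WW, 1=LW, 2=LL, 3=LM (heteroduplex),
// 4=MM. Driver present on >=1 strand iff state 3 or 4.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

static inline int repair_locus(int s, double r, double u) {
  // one round of repair before replication; returns post-repair state
  if (s == 0 || s == 4) return s;
  double full = r - u;
  if (s == 1) {                    // lesion opposite wildtype
    double x = unif_rand();
    if (x < full) return 0;        // full repair -> WW
    if (x < r) return 3;           // mutagenic repair -> heteroduplex
    return 1;
  }
  if (s == 3) {                    // lesion opposite mutation
    double x = unif_rand();
    if (x < full) return 4;        // resynthesis from mutant template -> MM
    return 3;                      // mutagenic or no repair keeps LM
  }
  // s == 2 (lesion on both strands): treat strands sequentially; mutagenic
  // repair of either lesion writes a mutation opposite, i.e. onto the
  // partner strand, erasing that strand's lesion.
  double x1 = unif_rand();
  if (x1 < full) {                 // strand 1 fully repaired -> now LW
    double x2 = unif_rand();
    if (x2 < full) return 0;
    if (x2 < r) return 3;
    return 1;
  }
  if (x1 < r) return 3;            // mutagenic -> LM
  double x2 = unif_rand();         // strand 1 unrepaired
  if (x2 < full) return 1;
  if (x2 < r) return 3;
  return 2;
}

static inline void replicate_locus(int s, double eps, int &d1, int &d2) {
  // daughter duplexes from the two template strands, order randomized
  switch (s) {
  case 0: d1 = d2 = 0; return;
  case 4: d1 = d2 = 4; return;
  case 2:
    d1 = (unif_rand() < eps) ? 1 : 3;
    d2 = (unif_rand() < eps) ? 1 : 3;
    return;
  case 1:
    d1 = (unif_rand() < eps) ? 1 : 3;  // lesion strand
    d2 = 0;                             // wildtype strand
    break;
  default: // 3
    d1 = (unif_rand() < eps) ? 1 : 3;  // lesion strand
    d2 = 4;                             // mutant strand
    break;
  }
  if (unif_rand() < 0.5) std::swap(d1, d2);
}

struct CellStore {
  std::vector<int> parent;           // global index of parent (-1 for root)
  std::vector<int> gen;
  std::vector<char> competent;       // post-repair: driver on >=1 strand at ALL loci
  std::vector<int> state;            // n_loci entries per cell (pre-repair state)
  int n_loci;
  int add(int par, int g, const int *st) {
    parent.push_back(par); gen.push_back(g); competent.push_back(0);
    for (int l = 0; l < n_loci; ++l) state.push_back(st[l]);
    return (int)parent.size() - 1;
  }
};

// [[Rcpp::export]]
List cpp_simulate_tumors(int n_tumors,
                         NumericVector b_by_k, NumericVector d_by_k,
                         double r, double u, double eps,
                         int n_drivers, int horizon, int cap,
                         int max_attempts, bool het_fit) {
  RNGScope scope;
  IntegerVector lad_out(n_tumors), att_out(n_tumors), hor_out(n_tumors),
    nclone_out(n_tumors);
  LogicalVector trunc_out(n_tumors), comp_out(n_tumors);

  std::vector<int> st0(n_drivers, 2);  // exposed cell: lesions on both strands
  std::vector<int> c1(n_drivers), c2(n_drivers);

  for (int t = 0; t < n_tumors; ++t) {
    bool formed = false;
    int attempts = 0;
    while (!formed && attempts < max_attempts) {
      ++attempts;
      Rcpp::checkUserInterrupt();
      CellStore cs; cs.n_loci = n_drivers;
      cs.parent.reserve(1024); cs.state.reserve(1024 * n_drivers);
      int root = cs.add(-1, 0, st0.data());
      std::vector<int> alive(1, root);
      bool truncated = false;
      int g = 0;
      for (; g < horizon; ++g) {
        std::vector<int> next;
        next.reserve(alive.size() * 2);
        for (size_t i = 0; i < alive.size(); ++i) {
          int c = alive[i];
          int *stc = &cs.state[(size_t)c * n_drivers];
          int n_any = 0, n_mut = 0;
          for (int l = 0; l < n_drivers; ++l) {
            stc[l] = repair_locus(stc[l], r, u);
            if (stc[l] == 3 || stc[l] == 4) ++n_any;
            if (stc[l] == 4) ++n_mut;
          }
          cs.competent[c] = (n_any == n_drivers);
          int k = het_fit ? n_any : n_mut;   // acquired drivers for fitness
          double b = b_by_k[k], d = d_by_k[k];
          double x = unif_rand();
          int nd = (x < b) ? 2 : (x < b + d ? 0 : 1);
          if (nd == 0) continue;
          for (int l = 0; l < n_drivers; ++l) {
            int a, bb; replicate_locus(stc[l], eps, a, bb);
            c1[l] = a; c2[l] = bb;
          }
          // daughters with any homozygous-wildtype driver locus can never
          // found a driver clone (WW is absorbing): not tracked
          bool ok1 = true, ok2 = true;
          for (int l = 0; l < n_drivers; ++l) {
            if (c1[l] == 0) ok1 = false;
            if (c2[l] == 0) ok2 = false;
          }
          if (nd == 2) {
            if (ok1) next.push_back(cs.add(c, g + 1, c1.data()));
            if (ok2) next.push_back(cs.add(c, g + 1, c2.data()));
          } else {
            bool pick1 = unif_rand() < 0.5;
            if (pick1 ? ok1 : ok2)
              next.push_back(cs.add(c, g + 1, pick1 ? c1.data() : c2.data()));
          }
        }
        alive.swap(next);
        if (alive.empty()) break;
        if ((int)alive.size() > cap) { truncated = true; ++g; break; }
      }
      if (alive.empty()) continue;
      int h_used = g;
      // tumor cells: alive cells with driver on >=1 strand at all loci
      // (pre-repair states of the final generation; apply the same
      // competence rule on raw states 3/4)
      std::vector<int> tumor;
      for (size_t i = 0; i < alive.size(); ++i) {
        int c = alive[i];
        const int *stc = &cs.state[(size_t)c * n_drivers];
        bool ok = true;
        for (int l = 0; l < n_drivers; ++l)
          if (stc[l] != 3 && stc[l] != 4) { ok = false; break; }
        if (ok) tumor.push_back(c);
      }
      if (tumor.empty()) continue;
      // clone grouping by earliest driver-competent ancestor
      std::unordered_map<int, std::vector<int> > clones;
      for (size_t i = 0; i < tumor.size(); ++i) {
        int c = tumor[i], earliest = -1;
        for (int a = c; a != -1; a = cs.parent[a])
          if (cs.competent[a]) earliest = a;
        if (earliest == -1) earliest = c;  // horizon cell itself (pre-repair driver)
        clones[earliest].push_back(c);
      }
      // winning clone: largest; ties broken by seeded RNG
      size_t best_n = 0;
      for (std::unordered_map<int, std::vector<int> >::iterator it = clones.begin();
           it != clones.end(); ++it)
        if (it->second.size() > best_n) best_n = it->second.size();
      std::vector<int> tied;
      for (std::unordered_map<int, std::vector<int> >::iterator it = clones.begin();
           it != clones.end(); ++it)
        if (it->second.size() == best_n) tied.push_back(it->first);
      int win = tied[(int)(unif_rand() * tied.size()) % tied.size()];
      std::vector<int> &clone = clones[win];
      // MRCA: deepest common ancestor of the clone's horizon cells
      int mrca = clone[0];
      for (size_t i = 1; i < clone.size(); ++i) {
        int a = mrca, b = clone[i];
        while (cs.gen[a] < cs.gen[b]) b = cs.parent[b];
        while (cs.gen[b] < cs.gen[a]) a = cs.parent[a];
        while (a != b) { a = cs.parent[a]; b = cs.parent[b]; }
        mrca = a;
      }
      lad_out[t] = cs.gen[mrca];
      comp_out[t] = cs.competent[mrca] != 0;
      att_out[t] = attempts;
      trunc_out[t] = truncated;
      hor_out[t] = h_used;
      nclone_out[t] = (int)clones.size();
      formed = true;
    }
    if (!formed) {
      lad_out[t] = NA_INTEGER; comp_out[t] = NA_LOGICAL;
      att_out[t] = attempts; trunc_out[t] = false; hor_out[t] = NA_INTEGER;
      nclone_out[t] = NA_INTEGER;
    }
  }
  return List::create(_["lad"] = lad_out, _["attempts"] = att_out,
                      _["truncated"] = trunc_out,
                      _["mrca_competent"] = comp_out,
                      _["horizon_used"] = hor_out,
                      _["n_clones"] = nclone_out);
}
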