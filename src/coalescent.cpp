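// Structured-coalescent engine: three populations, piecewise-constant sizes,
// symmetric pairwise migration, population joins, infinite-sites mutation.
// Time runs backward in generations; sizes are already inheritance-scaled
// (diploid Ne times 1.0 for nuclear, 0.25 for mtDNA), so the pairwise
// coalescence rate inside a population of scaled size N is 1/(2N).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// events: rows (time, type, a, b) sorted by time (type 0 before 1 on ties)
//   type 0: set scaled size of population a to b
//   type 1: join -- move all lineages of population a into population b,
//           population a ceases to exist further back in time
// mig: 3x3 matrix of scaled rates; per-lineage backward migration rate from
//   population i to j is mig(i,j) / (4 * N_i(t)).
static void sim_genealogy_internal(const IntegerVector& n_samp,
                                   const NumericVector& sizes,
                                   const NumericMatrix& events,
                                   const NumericMatrix& mig,
                                   std::vector<int>& parent,
                                   std::vector<double>& ntime) {
  const int n = n_samp[0] + n_samp[1] + n_samp[2];
  if (n < 2) stop("need at least 2 sampled lineages");
  const int n_nodes = 2 * n - 1;
  parent.assign(n_nodes, -1);
  ntime.assign(n_nodes, 0.0);

  std::vector<std::vector<int> > act(3);
  int id = 0;
  for (int p = 0; p < 3; ++p) {
    act[p].reserve(n);
    for (int k = 0; k < n_samp[p]; ++k) act[p].push_back(id++);
  }
  double N[3] = { sizes[0], sizes[1], sizes[2] };
  for (int i = 0; i < 3; ++i)
    if (!(N[i] > 0)) stop("population sizes must be positive");
  bool alive[3] = { true, true, true };
  int next_id = n;
  int total = n;
  double t = 0.0;
  const int ne = events.nrow();
  int ei = 0;

  while (total > 1) {
    double cr[3], mr[3][3];
    double crate = 0.0, mrate = 0.0;
    for (int i = 0; i < 3; ++i) {
      const double k = static_cast<double>(act[i].size());
      cr[i] = (k >= 2.0) ? k * (k - 1.0) / (4.0 * N[i]) : 0.0;
      crate += cr[i];
      for (int j = 0; j < 3; ++j) {
        mr[i][j] = 0.0;
        if (i != j && alive[j] && k > 0.0 && mig(i, j) > 0.0) {
          mr[i][j] = k * mig(i, j) / (4.0 * N[i]);
          mrate += mr[i][j];
        }
      }
    }
    const double rate = crate + mrate;
    const double t_next = (ei < ne) ? events(ei, 0) : R_PosInf;
    const double dt = (rate > 0.0) ? R::exp_rand() / rate : R_PosInf;

    if (t + dt >= t_next) {
      if (!R_FINITE(t_next))
        stop("coalescent stalled: isolated lineages with zero total rate");
      t = t_next;
      const int type = static_cast<int>(events(ei, 1));
      const int a = static_cast<int>(events(ei, 2));
      if (type == 0) {
        N[a] = events(ei, 3);
        if (!(N[a] > 0)) stop("size-change event with non-positive size");
      } else {
        const int b = static_cast<int>(events(ei, 3));
        for (size_t q = 0; q < act[a].size(); ++q) act[b].push_back(act[a][q]);
        act[a].clear();
        alive[a] = false;
      }
      ++ei;
      continue;
    }

    t += dt;
    double u = unif_rand() * rate;
    if (u < crate) {
      int i = 0;
      double acc = cr[0];
      while (u >= acc && i < 2) { ++i; acc += cr[i]; }
      const int k = static_cast<int>(act[i].size());
      int x = static_cast<int>(unif_rand() * k); if (x >= k) x = k - 1;
      int y = static_cast<int>(unif_rand() * (k - 1)); if (y >= k - 1) y = k - 2;
      if (y >= x) ++y;
      const int c1 = act[i][x], c2 = act[i][y];
      const int p = next_id++;
      parent[c1] = p;
      parent[c2] = p;
      ntime[p] = t;
      if (x > y) std::swap(x, y);
      act[i][x] = p;
      act[i].erase(act[i].begin() + y);
      --total;
    } else {
      u -= crate;
      int ii = -1, jj = -1;
      double acc = 0.0;
      for (int i = 0; i < 3 && ii < 0; ++i) {
        for (int j = 0; j < 3; ++j) {
          if (i == j) continue;
          acc += mr[i][j];
          if (u < acc) { ii = i; jj = j; break; }
        }
      }
      if (ii < 0) continue;  // numerical slack: redraw
      const int k = static_cast<int>(act[ii].size());
      int x = static_cast<int>(unif_rand() * k); if (x >= k) x = k - 1;
      const int lin = act[ii][x];
      act[ii].erase(act[ii].begin() + x);
      act[jj].push_back(lin);
    }
  }
}

// Genealogy only (for TMRCA / tree-level checks). Node ids are 1-based on
// return; leaves 1..n in population-block order, root parent = 0.
// [[Rcpp::export]]
List coal_genealogy_cpp(IntegerVector n_samp, NumericVector sizes,
                        NumericMatrix events, NumericMatrix mig) {
  std::vector<int> parent;
  std::vector<double> ntime;
  sim_genealogy_internal(n_samp, sizes, events, mig, parent, ntime);
  const int n_nodes = static_cast<int>(parent.size());
  IntegerVector par(n_nodes);
  NumericVector tim(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    par[v] = parent[v] + 1;  // root -> 0
    tim[v] = ntime[v];
  }
  return List::create(_["parent"] = par, _["time"] = tim,
                      _["n_leaves"] = n_samp[0] + n_samp[1] + n_samp[2]);
}

// Genealogy + infinite-sites mutations in one call (bulk simulation path).
// Returns the 0/1 haplotype matrix (rows = leaves in population-block order)
// and strictly increasing relative positions in (0,1).
// [[Rcpp::export]]
List coal_locus_cpp(IntegerVector n_samp, NumericVector sizes,
                    NumericMatrix events, NumericMatrix mig,
                    double mu, double locus_length) {
  std::vector<int> parent;
  std::vector<double> ntime;
  sim_genealogy_internal(n_samp, sizes, events, mig, parent, ntime);
  const int n = n_samp[0] + n_samp[1] + n_samp[2];
  const int n_nodes = static_cast<int>(parent.size());

  std::vector<double> bl(n_nodes, 0.0);
  double tot = 0.0;
  for (int v = 0; v < n_nodes; ++v)
    if (parent[v] >= 0) { bl[v] = ntime[parent[v]] - ntime[v]; tot += bl[v]; }

  const int S = static_cast<int>(R::rpois(tot * mu * locus_length));
  IntegerMatrix m(n, S);
  NumericVector pos(S);
  if (S > 0) {
    // leaf descendant lists; children always have smaller ids than parents
    std::vector<std::vector<int> > desc(n_nodes);
    for (int v = 0; v < n; ++v) desc[v].push_back(v);
    for (int v = 0; v < n_nodes; ++v)
      if (parent[v] >= 0)
        desc[parent[v]].insert(desc[parent[v]].end(),
                               desc[v].begin(), desc[v].end());

    std::vector<double> cum(n_nodes);
    double a = 0.0;
    for (int v = 0; v < n_nodes; ++v) { a += bl[v]; cum[v] = a; }

    std::vector<double> pvec(S);
    for (int s = 0; s < S; ++s) pvec[s] = unif_rand();
    std::sort(pvec.begin(), pvec.end());
    for (int s = 1; s < S; ++s)  // infinite sites: enforce unique positions
      if (pvec[s] <= pvec[s - 1])
        pvec[s] = std::nextafter(pvec[s - 1], 1.0);

    for (int s = 0; s < S; ++s) {
      const double u = unif_rand() * tot;
      int b = static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) -
                               cum.begin());
      if (b >= n_nodes) b = n_nodes - 1;
      while (b > 0 && bl[b] <= 0.0) --b;  // never mutate a zero-length branch
      const std::vector<int>& d = desc[b];
      for (size_t q = 0; q < d.size(); ++q) m(d[q], s) = 1;
      pos[s] = pvec[s];
    }
  }
  return List::create(_["matrix"] = m, _["positions"] = pos);
}
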