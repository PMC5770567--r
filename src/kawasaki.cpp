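#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Small deterministic PRNG (splitmix64 seeded xorshift), independent of R's
// RNG stream so lattice realisations are reproducible across platforms.
namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) {
    // splitmix64 scramble of the seed
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x1234567887654321ULL;
  }
  uint64_t next() {
    uint64_t x = s;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    s = x;
    return x;
  }
  double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) {
    return (int)(next() % (uint64_t)n);
  }
};

} // namespace

// Kawasaki (nearest-neighbour exchange) Monte Carlo for a two-leaflet lattice
// mixture. Composition of every species is conserved exactly in each leaflet.
//
// labels: 0-based species codes, one vector per leaflet (length n_sites).
// nbr: n_sites x k matrix of 0-based neighbour indices (triangular lattice k=6).
// cost: symmetric n_species x n_species pair-energy matrix in kT units
//       (0 on the diagonal; J for unlike pairs, possibly discounted).
// lambda: interleaflet alignment bonus in kT, acting on the binary
//       ordered/disordered relabelling given by ordered_flag per species.
// sweeps: one sweep = one attempted exchange per site per leaflet.
// record_every: if > 0, snapshot labels every that many sweeps (plus final).
//
// Returns list(upper = list of integer vectors, lower = ..., sweep = numeric).
// [[Rcpp::export(name = ".kawasaki_mc")]]
List kawasaki_mc(IntegerVector labels_upper,
                 IntegerVector labels_lower,
                 IntegerMatrix nbr,
                 NumericMatrix cost,
                 double lambda,
                 IntegerVector ordered_flag,
                 int sweeps,
                 double seed,
                 int record_every) {
  const int n = labels_upper.size();
  if (labels_lower.size() != n)
    stop("leaflets must have the same number of sites");
  const int k = nbr.ncol();

  std::vector<int> up(labels_upper.begin(), labels_upper.end());
  std::vector<int> lo(labels_lower.begin(), labels_lower.end());
  std::vector<int> ord(ordered_flag.begin(), ordered_flag.end());

  XorShift rng((uint64_t)seed);

  std::vector<std::vector<int> > rec_up, rec_lo;
  std::vector<double> rec_sweep;

  auto snapshot = [&](int sw) {
    rec_up.push_back(up);
    rec_lo.push_back(lo);
    rec_sweep.push_back((double)sw);
  };

  // local energy of site `site` with hypothetical label `lab`, skipping
  // neighbour `skip` (the exchange partner: the i-j pair cost is invariant
  // under the swap)
  auto local_e = [&](const std::vector<int> &lab_vec,
                     const std::vector<int> &other_vec,
                     int site, int lab, int skip) {
    double e = 0.0;
    for (int m = 0; m < k; ++m) {
      int j = nbr(site, m);
      if (j == skip) continue;
      e += cost(lab, lab_vec[j]);
    }
    if (lambda != 0.0 && ord[lab] == ord[other_vec[site]]) e -= lambda;
    return e;
  };

  const long attempts_per_sweep = 2L * n; // both leaflets
  for (int sw = 0; sw < sweeps; ++sw) {
    for (long a = 0; a < attempts_per_sweep; ++a) {
      bool upper = (rng.next() & 1ULL) != 0ULL;
      std::vector<int> &lab = upper ? up : lo;
      std::vector<int> &oth = upper ? lo : up;
      int i = rng.below(n);
      int j = nbr(i, rng.below(k));
      int si = lab[i], sj = lab[j];
      if (si == sj) continue;
      double e_old = local_e(lab, oth, i, si, j) + local_e(lab, oth, j, sj, i);
      double e_new = local_e(lab, oth, i, sj, j) + local_e(lab, oth, j, si, i);
      double dE = e_new - e_old;
      if (dE <= 0.0 || rng.unif() < std::exp(-dE)) {
        lab[i] = sj;
        lab[j] = si;
      }
    }
    if (record_every > 0 && ((sw + 1) % record_every == 0) && (sw + 1) < sweeps)
      snapshot(sw + 1);
    if ((sw & 255) == 0) Rcpp::checkUserInterrupt();
  }
  snapshot(sweeps);

  int nr = rec_up.size();
  List out_up(nr), out_lo(nr);
  NumericVector out_sw(nr);
  for (int r = 0; r < nr; ++r) {
    out_up[r] = IntegerVector(rec_up[r].begin(), rec_up[r].end());
    out_lo[r] = IntegerVector(rec_lo[r].begin(), rec_lo[r].end());
    out_sw[r] = rec_sweep[r];
  }
  return List::create(_["upper"] = out_up, _["lower"] = out_lo,
                      _["sweep"] = out_sw);
}
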