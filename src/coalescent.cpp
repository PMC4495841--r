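#include <Rcpp.h>
using namespace Rcpp;

// Tajima (1989) normalising constants for sample size n.
static void tajima_constants(int n, double &a1, double &e1, double &e2) {
  double a2 = 0.0;
  a1 = 0.0;
  for (int i = 1; i < n; ++i) {
    a1 += 1.0 / i;
    a2 += 1.0 / ((double)i * i);
  }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * ((double)n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  e1 = c1 / a1;
  e2 = c2 / (a1 * a1 + a2);
}

static double tajima_D_from_counts(const std::vector<int> &counts, int n,
                                   double a1, double e1, double e2) {
  int S = (int)counts.size();
  if (S == 0) return NA_REAL;
  double khat = 0.0;
  for (int j = 0; j < S; ++j) {
    double c = counts[j];
    khat += 2.0 * c * (n - c);
  }
  khat /= (double)n * (n - 1.0);
  double num = khat - S / a1;
  double den = std::sqrt(e1 * S + e2 * (double)S * (S - 1.0));
  return num / den;
}

// One neutral coalescent genealogy of n tips; mutations are dropped on the
// tree either as a fixed count S (uniform on total branch length) or as a
// Poisson process with rate theta/2 per unit branch length. Derived-allele
// counts feed Tajima's D. Uses R's RNG so set.seed() on the R side makes
// runs reproducible.
static double simulate_D_once(int n, int S_fixed, double theta,
                              double a1, double e1, double e2,
                              std::vector<int> &sizes,
                              std::vector<double> &times) {
  // epoch k has k active lineages and exponential duration with rate
  // k(k-1)/2 (coalescent time units)
  double total_len = 0.0;
  for (int k = n; k >= 2; --k) {
    double rate = k * (k - 1.0) / 2.0;
    double t = R::exp_rand() / rate;
    times[k] = t;
    total_len += k * t;
  }
  int S = S_fixed >= 0 ? S_fixed : (int)R::rpois(0.5 * theta * total_len);
  if (S == 0) return NA_REAL;

  // epoch of each mutation, proportional to k * T_k
  std::vector<int> muts_per_epoch(n + 1, 0);
  for (int m = 0; m < S; ++m) {
    double u = R::unif_rand() * total_len, acc = 0.0;
    int chosen = 2;
    for (int k = n; k >= 2; --k) {
      acc += k * times[k];
      if (u <= acc) { chosen = k; break; }
    }
    muts_per_epoch[chosen]++;
  }

  // replay the merge history, assigning each epoch's mutations to a
  // uniformly chosen active lineage
  sizes.assign(n, 1);
  std::vector<int> counts;
  counts.reserve(S);
  for (int k = n; k >= 2; --k) {
    for (int m = 0; m < muts_per_epoch[k]; ++m) {
      int idx = (int)(R::unif_rand() * k);
      if (idx >= k) idx = k - 1;
      counts.push_back(sizes[idx]);
    }
    int i = (int)(R::unif_rand() * k);
    int j = (int)(R::unif_rand() * (k - 1));
    if (j >= i) j++;
    if (i > j) std::swap(i, j);
    sizes[i] += sizes[j];
    sizes[j] = sizes[k - 1];
  }
  // mutations with derived count n would be fixed, not segregating; they
  // cannot arise here because the root epoch has two lineages of size < n
  return tajima_D_from_counts(counts, n, a1, e1, e2);
}

//' @name coalescent_D_null
//' @title Null distribution of Tajima's D from neutral coalescent samples
//' @param n sample size (chromosomes), n >= 4
//' @param reps number of replicates
//' @param S fixed segregating-site count (set to -1 to use theta)
//' @param theta scaled mutation rate used when S < 0 (Poisson mutations)
//' @return numeric vector of simulated D values (NA when a replicate has
//'   no segregating site, only possible in theta mode)
//' @keywords internal
// [[Rcpp::export]]
NumericVector coalescent_D_null(int n, int reps, int S = -1,
                                double theta = 0.0) {
  if (n < 4) stop("n must be at least 4");
  if (S < 0 && theta <= 0) stop("either S >= 1 or theta > 0 is required");
  if (S == 0) stop("S must be at least 1");
  double a1, e1, e2;
  tajima_constants(n, a1, e1, e2);
  NumericVector out(reps);
  std::vector<int> sizes(n);
  std::vector<double> times(n + 1);
  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    out[r] = simulate_D_once(n, S, theta, a1, e1, e2, sizes, times);
  }
  return out;
}
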