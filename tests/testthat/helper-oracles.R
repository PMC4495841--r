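# Shared helpers: tiny panels and independent brute-force oracles used to
# cross-check the analytical implementations.

# Random haplotype matrix (n x sites, 0/1) for diversity oracles.
random_haplotypes <- function(n, sites) {
  matrix(rbinom(n * sites, 1, runif(sites, 0.1, 0.9)),
         nrow = n, byrow = TRUE)
}

# Brute-force nucleotide diversity: average Hamming distance over all
# unordered haplotype pairs, per site of length L.
pi_bruteforce <- function(haps, L) {
  n <- nrow(haps)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(haps[i, ] != haps[j, ])
  }
  tot / choose(n, 2) / L
}

# Brute-force AMOVA sums of squared deviations from the full item-by-item
# squared distance matrix (double loops, no count tricks).
ssd_bruteforce <- function(d2, groups) {
  N <- nrow(d2)
  ssd_tot <- sum(d2) / (2 * N)
  ssd_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssd_within <- ssd_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  list(total = ssd_tot, within = ssd_within, among = ssd_tot - ssd_within)
}

# Multinomial-HWE log-likelihood of genotype data for given haplotype
# frequencies: used by the grid-search oracle for the EM.
hwe_loglik <- function(geno, haps, f) {
  # haps: matrix H x sites of 0/1; f: frequencies
  H <- nrow(haps)
  ll <- 0
  for (i in seq_len(nrow(geno))) {
    p <- 0
    for (a in seq_len(H)) for (b in seq_len(H)) {
      if (all(haps[a, ] + haps[b, ] == geno[i, ])) p <- p + f[a] * f[b]
    }
    ll <- ll + log(p)
  }
  ll
}

toy_genotype_panel <- function() {
  g <- matrix(c(0L, 1L,
                2L, 0L), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("Met420del", "Arg61Cys")))
  genotype_panel(c("s1", "s2"), c("A", "A"), g)
}
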