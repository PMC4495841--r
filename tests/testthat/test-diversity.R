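test_that("pi equals the brute-force pairwise average on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    sites <- sample(1:12, 1)
    L <- sample(c(500, 1000, 1665), 1)
    haps <- random_haplotypes(n, sites)
    counts <- colSums(haps)
    expect_equal(nucleotide_diversity(counts, n, L),
                 pi_bruteforce(haps, L), tolerance = 1e-12)
  }
})

test_that("pi and theta handle forced and degenerate cases", {
  expect_equal(nucleotide_diversity(integer(0), 10, 1000), 0)
  # two haplotypes differing at exactly one site
  expect_equal(nucleotide_diversity(1, 2, 1000), 1e-3)
  expect_error(nucleotide_diversity(1, 1, 1000), "at least 2")
  expect_equal(watterson_theta(0, 10, 1000), 0)
  expect_equal(watterson_theta(1, 2, 1000), 1e-3)
  # independent harmonic-sum evaluation
  a1 <- sum(1 / 1:9)
  expect_equal(watterson_theta(3, 10, 1662), 3 / (a1 * 1662))
  expect_error(watterson_theta(1, 1, 1000), "at least 2")
})

test_that("Tajima's D reproduces the hand-evaluated n=4 singleton case", {
  # constants for n=4: a1=11/6, b1=5/9, b2=23/54; D = -0.61237
  k <- tajima_constants(4)
  expect_equal(k$a1, 11 / 6)
  expect_equal(k$b1, 5 / 9)
  expect_equal(k$b2, 23 / 54)
  td <- tajimas_d(1, 4)
  expect_equal(td$D, -0.6123724, tolerance = 1e-6)
  expect_error(tajimas_d(1, 3), "at least 4")
  td0 <- tajimas_d(integer(0), 10)
  expect_true(is.na(td0$D))
  expect_equal(td0$reason, "no segregating sites")
})

test_that("Tajima's D is invariant to the normalising length", {
  fx <- oct1_fixtures()
  vc <- classify_variants(fx$activity, fx$alleles, fx$variants)
  strata <- region_site_strata(fx, vc)
  s1 <- stratified_diversity(strata, L = 1665)$table
  s2 <- stratified_diversity(strata, L = 500)$table
  expect_equal(s1$tajimas_D, s2$tajimas_D)
  expect_false(isTRUE(all.equal(s1$pi_per_site, s2$pi_per_site)))
})

test_that("the coalescent null is centred near zero and brackets it", {
  set.seed(3)
  sims <- lofscape:::coalescent_D_null(100L, 1000L, S = -1L, theta = 5)
  expect_gt(mean(sims, na.rm = TRUE), -0.25)
  expect_lt(mean(sims, na.rm = TRUE), 0.1)
  q <- quantile(sims, c(0.01, 0.99), na.rm = TRUE)
  expect_lt(q[1], 0)
  expect_gt(q[2], 0)
})

test_that("simulation p-values are seed-stable and respect the alternative", {
  td1 <- tajimas_d(c(1, 1, 2), 40, p_value = TRUE, n_sims = 500, seed = 7)
  td2 <- tajimas_d(c(1, 1, 2), 40, p_value = TRUE, n_sims = 500, seed = 7)
  expect_equal(td1$p_value, td2$p_value)
  tdg <- tajimas_d(c(1, 1, 2), 40, p_value = TRUE, n_sims = 500, seed = 7,
                   alternative = "greater")
  expect_gt(tdg$p_value, td1$p_value)  # D is negative here
})

test_that("region summaries pool and stratify as documented", {
  fx <- oct1_fixtures()
  vc <- classify_variants(fx$activity, fx$alleles, fx$variants)
  strata <- region_site_strata(fx, vc)
  # n is the number of non-admixed chromosomes of the region
  ns <- tapply(strata$n, strata$region, unique)
  expect_equal(unname(ns[["East Asia and Oceania"]]), 1052)
  expect_equal(unname(ns[["America"]]), 128)
  expect_false("Admixed" %in% strata$region)
  sd <- stratified_diversity(strata, L = 1665)
  tab <- sd$table
  # S = 0 reports pi = theta = 0 and a missing D, not 0
  empty <- tab[tab$S == 0, ]
  if (nrow(empty) > 0) {
    expect_true(all(empty$pi_per_site == 0))
    expect_true(all(is.na(empty$tajimas_D)))
  }
  # stratum invariance to site order: shuffle rows of the strata table
  set.seed(1)
  sd2 <- stratified_diversity(strata[sample(nrow(strata)), ], L = 1665)
  o1 <- sd$table[order(sd$table$region, sd$table$stratum), ]
  o2 <- sd2$table[order(sd2$table$region, sd2$table$stratum), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("pooled variant frequencies follow the allele definitions", {
  fx <- oct1_fixtures()
  cm <- fixture_count_matrix(fx)
  # a variant absent from a subset pools to 0
  expect_equal(pooled_variant_maf("Gly465Arg", cm, fx$alleles, fx$panel,
                                  populations = "Surui"), 0)
  expect_error(pooled_variant_maf("NoSuchVariant", cm, fx$alleles, fx$panel),
               "unknown variant")
  # Met420del pools *2 + *5 + *6 + *14
  pops <- c("Surui", "Tu")
  manual <- sum(cm[pops, c("*2", "*5", "*6", "*14")]) /
    sum(fx$panel$n_chromosomes[match(pops, fx$panel$population)])
  expect_equal(pooled_variant_maf("Met420del", cm, fx$alleles, fx$panel,
                                  populations = pops), manual)
})
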