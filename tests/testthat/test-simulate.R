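fx <- oct1_fixtures()

test_that("simulation honours fixed points and determinism", {
  pops <- data.frame(population = "P", region = "R", n_individuals = 20)
  f1 <- matrix(1, 1, dimnames = list("P", "*1"))
  sim <- simulate_panel(pops, f1, fx$alleles, seed = 1)
  expect_true(ncol(sim$panel$genotypes) == 0L ||
                all(sim$panel$genotypes == 0L))
  expect_true(all(sim$truth$a1 == "*1" & sim$truth$a2 == "*1"))

  f2 <- matrix(c(0.6, 0.4), 1, dimnames = list("P", c("*1", "*2")))
  s1 <- simulate_panel(pops, f2, fx$alleles, seed = 99)
  s2 <- simulate_panel(pops, f2, fx$alleles, seed = 99)
  expect_identical(s1$panel$genotypes, s2$panel$genotypes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_panel(pops, f2, fx$alleles, seed = 100)
  expect_false(identical(s1$truth, s3$truth))
  # an allele of unknown composition is rejected
  f3 <- matrix(c(0.5, 0.5), 1, dimnames = list("P", c("*1", "*16")))
  expect_error(simulate_panel(pops, f3, fx$alleles, seed = 1), "\\*16")
})

test_that("realized frequencies are binomially consistent at large N", {
  pops <- data.frame(population = "P", region = "R", n_individuals = 5000)
  f <- matrix(c(0.7, 0.3), 1, dimnames = list("P", c("*1", "*2")))
  sim <- simulate_panel(pops, f, fx$alleles, seed = 7)
  p_hat <- mean(sim$panel$genotypes[, "Met420del"]) / 2
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(p_hat - 0.3), 3 * se)
  # genotype counts are reachable from the truth diplotypes per sample
  ind <- (sim$truth$a1 == "*2") + (sim$truth$a2 == "*2")
  expect_identical(as.integer(sim$panel$genotypes[, "Met420del"]),
                   as.integer(ind))
})

test_that("realized counts are multinomial under F = 0", {
  pops <- data.frame(population = "P", region = "R", n_individuals = 50)
  f <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list("P", c("*1", "*2", "*3")))
  tot <- c(0, 0, 0)
  set.seed(11)
  for (s in 1:200) {
    sim <- simulate_panel(pops, f, fx$alleles, seed = sample.int(1e6, 1))
    tot <- tot + sim$realized["P", ]
  }
  gof <- stats::chisq.test(tot, p = c(0.5, 0.3, 0.2))
  expect_gt(gof$p.value, 0.01)
})

test_that("inbreeding produces the expected homozygote excess", {
  pops <- data.frame(population = "P", region = "R", n_individuals = 4000)
  f <- matrix(c(0.5, 0.5), 1, dimnames = list("P", c("*1", "*2")))
  sim <- simulate_panel(pops, f, fx$alleles, inbreeding_F = 0.3, seed = 13)
  hom <- mean(sim$truth$a1 == sim$truth$a2)
  # P(homozygote) = sum p^2 + F * sum pq = 0.5 + 0.3 * 0.5
  expect_lt(abs(hom - 0.65), 3 * sqrt(0.65 * 0.35 / 4000))
})

test_that("genotyping error perturbs genotypes but not the truth", {
  pops <- data.frame(population = "P", region = "R", n_individuals = 500)
  f <- matrix(c(0.6, 0.4), 1, dimnames = list("P", c("*1", "*2")))
  clean <- simulate_panel(pops, f, fx$alleles, seed = 21)
  noisy <- simulate_panel(pops, f, fx$alleles, error_rate = 0.2, seed = 21)
  expect_identical(clean$truth$a1, noisy$truth$a1)
  expect_false(identical(clean$panel$genotypes, noisy$panel$genotypes))
})

test_that("fixture-driven simulation mirrors the study design", {
  sim <- simulate_from_fixture(fx, seed = 3)
  expect_equal(sim$dropped_alleles, "*16")
  expect_equal(nrow(sim$truth), sum(fx$panel$n_individuals[!fx$panel$admixed]))
  # Japan is fixed for *1 in the fixture
  jp <- sim$truth[sim$truth$population == "Japanese", ]
  expect_true(all(jp$a1 == "*1" & jp$a2 == "*1"))
  # Surui: 16 chromosomes, expectation ~15 carrying *2
  su <- sim$truth[sim$truth$population == "Surui", ]
  expect_equal(nrow(su), 8L)
  n2 <- sum(su$a1 == "*2") + sum(su$a2 == "*2")
  expect_gte(n2, 11)  # within 3 binomial SE of 15/16
  sim2 <- simulate_from_fixture(fx, n_override = 30, seed = 3)
  expect_true(all(table(sim2$truth$population) == 30))
})

test_that("truth comparison scores accuracy and catches mismatches", {
  pops <- data.frame(population = "P", region = "R", n_individuals = 100)
  f <- matrix(c(0.6, 0.4), 1, dimnames = list("P", c("*1", "*2")))
  sim <- simulate_panel(pops, f, fx$alleles, seed = 17)
  r <- em_haplotype_frequencies(sim$panel, "P")
  calls <- assign_diplotypes(r)
  ct <- compare_to_truth(calls, sim$truth, est_freqs = r$haplotype_freqs)
  expect_equal(ct$diplotype_accuracy, 1)  # single biallelic site: unambiguous
  # negative control: shuffling the truth labels destroys the accuracy
  sh <- sim$truth
  set.seed(5)
  sh[, c("hap1", "hap2")] <- sh[sample(nrow(sh)), c("hap1", "hap2")]
  ct2 <- compare_to_truth(calls, sh)
  expect_lt(ct2$diplotype_accuracy, 1)
  expect_error(compare_to_truth(calls[1:5, ] |>
                                  transform(sample_id = paste0("x", 1:5)),
                                sim$truth), "do not match")
})
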