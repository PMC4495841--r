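test_that("AMOVA components match brute-force SSD evaluation on a 3-population toy", {
  # three populations with chosen haplotype counts over 3 states
  D <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  state <- c(rep("a", 6), rep("b", 2),      # pop1
             rep("a", 2), rep("b", 5), "c", # pop2
             rep("c", 7), "a")              # pop3
  pop <- rep(c("p1", "p2", "p3"), each = 8)
  res <- amova(state, pop, region = NULL, distance = D)

  d2 <- outer(state, state, function(i, j) D[cbind(i, j)])
  bf <- ssd_bruteforce(d2, pop)
  expect_equal(unname(res$ssd[["total"]]), bf$total)
  expect_equal(unname(res$ssd[["within"]]), bf$within)
  expect_equal(unname(res$ssd[["among_groups"]]), bf$among)
  # unequal-size variance components, computed independently
  N <- 24; P <- 3
  ms_w <- bf$within / (N - P)
  ms_a <- bf$among / (P - 1)
  n_prime <- (N - sum(table(pop)^2) / N) / (P - 1)
  sigma_a <- (ms_a - ms_w) / n_prime
  expect_equal(unname(res$sigma_raw[["a"]]), sigma_a)
  expect_equal(unname(res$sigma_raw[["c"]]), ms_w)
  expect_equal(unname(res$phi[["phi_ST"]]),
               max(sigma_a, 0) / (max(sigma_a, 0) + ms_w))
})

test_that("three-level SSDs follow the brute-force region decomposition", {
  set.seed(42)
  states <- c("a", "b", "c")
  D <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3,
              dimnames = list(states, states))
  pop <- rep(paste0("p", 1:6), times = c(10, 8, 12, 9, 11, 10))
  region <- c(p1 = "r1", p2 = "r1", p3 = "r1", p4 = "r2", p5 = "r2",
              p6 = "r3")[pop]
  state <- sample(states, length(pop), replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  res <- amova(state, pop, region, D)
  d2 <- outer(state, state, function(i, j) D[cbind(i, j)])
  bf_pop <- ssd_bruteforce(d2, pop)
  bf_reg <- ssd_bruteforce(d2, region)
  expect_equal(unname(res$ssd[["within"]]), bf_pop$within)
  expect_equal(unname(res$ssd[["among_pops"]]), bf_reg$within - bf_pop$within)
  expect_equal(unname(res$ssd[["among_regions"]]), bf_reg$among)
  expect_equal(sum(res$percent), 100)
})

test_that("degenerate structures give the forced Phi values", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  # identical populations: among-group variance truncates to zero
  state <- rep(c("a", "b"), times = 10)
  pop <- rep(c("p1", "p2"), each = 10)
  res <- amova(state, pop, distance = D)
  expect_equal(unname(res$phi[["phi_ST"]]), 0)
  expect_true(res$truncated[["a"]])
  # disjoint fixed populations differing at one site: Phi_ST = 1
  res2 <- amova(c(rep("a", 10), rep("b", 10)), pop, distance = D)
  expect_equal(unname(res2$phi[["phi_ST"]]), 1)
  # all-identical phenotype observations: components zero
  res3 <- phenotype_amova(rep(2L, 20), pop)
  expect_equal(unname(res3$sigma), c(0, 0))
  expect_true(is.na(res3$phi[["phi_ST"]]))
  # two regions fixed at codes 2 and 0: among-regions explains everything
  pop4 <- rep(paste0("p", 1:4), each = 5)
  reg4 <- rep(c("r1", "r2"), each = 10)
  res4 <- phenotype_amova(rep(c(2L, 0L), each = 10), pop4, reg4)
  expect_equal(unname(res4$percent[["a"]]), 100)
})

test_that("percentages are stable under duplicating every observation", {
  # duplication doubles every SSD; only the degrees of freedom shift, so
  # components and percentages must agree closely at moderate sample size
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  set.seed(8)
  state <- c(sample(c("a", "b", "c"), 100, TRUE, prob = c(.6, .3, .1)),
             sample(c("a", "b", "c"), 100, TRUE, prob = c(.2, .3, .5)))
  pop <- rep(c("p1", "p2"), each = 100)
  r1 <- amova(state, pop, distance = D)
  r2 <- amova(rep(state, 2), rep(pop, 2), distance = D)
  expect_equal(unname(r2$ssd), unname(2 * r1$ssd))
  expect_equal(r1$percent, r2$percent, tolerance = 0.02)
  expect_lt(abs(unname(r1$phi[["phi_ST"]]) - unname(r2$phi[["phi_ST"]])),
            0.01)
})

test_that("pairwise Phi_ST matrices are symmetric with zero diagonal", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  state <- c(rep("a", 10), rep("b", 10), rep(c("a", "b"), 5))
  grp <- rep(c("g1", "g2", "g3"), each = 10)
  m <- pairwise_fst(state, grp, D)$phi
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), c("g1", "g2", "g3")))
  expect_equal(m["g1", "g2"], 1)
  expect_warning(
    pairwise_fst(c(state, "a"), c(grp, "tiny"), D), "excluded")
})

test_that("permutation p-values are uniform under a true null", {
  # four states with distinct distances keep ties in the permuted statistic
  # rare, so the p-value distribution is close to uniform
  sts <- c("a", "b", "c", "d")
  D <- matrix(c(0, 1, 2.3, 3.7,
                1, 0, 1.4, 2.6,
                2.3, 1.4, 0, 1.9,
                3.7, 2.6, 1.9, 0), 4, 4, dimnames = list(sts, sts))
  set.seed(77)
  pvals <- replicate(200, {
    state <- sample(sts, 60, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    pop <- rep(c("p1", "p2", "p3"), each = 20)
    amova(state, pop, distance = D, nperm = 99,
          seed = sample.int(1e6, 1))$p_values[["phi_ST"]]
  })
  # coverage at the 5% level and overall mean ((nperm/2 + 1)/(nperm + 1)
  # ~ 0.51 under the add-one convention)
  expect_gt(mean(pvals <= 0.05), 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(abs(mean(pvals) - 0.51), 3 * 0.29 / sqrt(200))
})

test_that("permutation p-values detect genuine structure and are seed-stable", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  state <- c(rep("a", 18), rep("b", 2), rep("b", 18), rep("a", 2))
  pop <- rep(c("p1", "p2"), each = 20)
  r1 <- amova(state, pop, distance = D, nperm = 199, seed = 5)
  r2 <- amova(state, pop, distance = D, nperm = 199, seed = 5)
  expect_equal(r1$p_values, r2$p_values)
  expect_lt(r1$p_values[["phi_ST"]], 0.05)
})
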