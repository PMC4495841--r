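test_that("EM equals direct counting on phase-unambiguous data", {
  g <- matrix(c(0L, 0L,
                2L, 2L,
                0L, 2L,
                2L, 0L), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("vA", "vB")))
  p <- genotype_panel(paste0("s", 1:4), rep("X", 4), g)
  r <- em_haplotype_frequencies(p)
  expect_true(r$converged)
  f <- r$haplotype_freqs
  expect_equal(unname(f["."]), 0.25)
  expect_equal(unname(f["vA,vB"]), 0.25)
  expect_equal(unname(f["vB"]), 0.25)
  expect_equal(unname(f["vA"]), 0.25)
  calls <- assign_diplotypes(r)
  expect_true(all(calls$posterior == 1))
  expect_false(any(calls$tie))
})

test_that("a lone double heterozygote is a symmetric saddle under uniform init", {
  g <- matrix(c(1L, 1L), ncol = 2,
              dimnames = list(NULL, c("vA", "vB")))
  p <- genotype_panel("s1", "X", g)
  r <- em_haplotype_frequencies(p, init = "uniform")
  expect_equal(unname(r$haplotype_freqs), rep(0.25, 4), tolerance = 1e-9)
  calls <- assign_diplotypes(r)
  expect_equal(calls$posterior, 0.5)
  expect_true(calls$tie)
})

test_that("EM log-likelihood is monotone and matches a simplex grid search", {
  g <- matrix(c(1L, 1L,
                1L, 0L,
                0L, 1L), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("vA", "vB")))
  p <- genotype_panel(paste0("s", 1:3), rep("X", 3), g)
  cfg <- analysis_config(em_tol = 1e-12, em_max_iter = 2000L)
  runs <- lapply(c(2L, 1536L, 2936L, 3123L), function(s) {
    em_haplotype_frequencies(p, config = cfg, init = "random", seed = s)
  })
  best <- runs[[which.max(vapply(runs, function(r) r$log_likelihood,
                                 numeric(1)))]]
  # independent oracle: grid search of the multinomial-HWE likelihood over
  # the 4-haplotype frequency simplex (coarse pass then 0.001 refinement)
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  grid_best <- c(-Inf, NA, NA, NA)
  safe_seq <- function(lo, hi, step) if (hi < lo) numeric(0) else
    seq(lo, hi, by = step)
  search <- function(step, centre, width) {
    vals <- safe_seq(max(0, centre[1] - width), min(1, centre[1] + width), step)
    for (f1 in vals) {
      v2 <- safe_seq(max(0, centre[2] - width), min(1 - f1, centre[2] + width),
                     step)
      for (f2 in v2) {
        v3 <- safe_seq(max(0, centre[3] - width),
                       min(1 - f1 - f2, centre[3] + width), step)
        for (f3 in v3) {
          f <- c(f1, f2, f3, 1 - f1 - f2 - f3)
          if (f[4] < 0) next
          ll <- hwe_loglik(g, haps, f)
          if (is.finite(ll) && ll > grid_best[1]) grid_best <<- c(ll, f1, f2, f3)
        }
      }
    }
  }
  search(0.02, c(0.5, 0.5, 0.5), 0.5)
  search(0.001, grid_best[2:4], 0.02)
  expect_gte(best$log_likelihood, grid_best[1] - 1e-6)
  f_grid <- c(grid_best[2:4], 1 - sum(grid_best[2:4]))
  f_em <- unname(best$haplotype_freqs[c(".", "vB", "vA", "vA,vB")])
  expect_equal(f_em, f_grid, tolerance = 0.005)
})

test_that("forced and uniform diplotype assignments behave as specified", {
  g <- matrix(c(1L, 1L), ncol = 2, dimnames = list(NULL, c("vA", "vB")))
  p <- genotype_panel("s1", "X", g)
  r <- em_haplotype_frequencies(p)
  # force frequencies: only the AB/ab resolution has positive probability
  r$haplotype_freqs[] <- 0
  r$haplotype_freqs[c("vA,vB", ".")] <- 0.5
  calls <- assign_diplotypes(r)
  expect_setequal(c(calls$hap1, calls$hap2), c("vA,vB", "."))
  expect_equal(calls$posterior, 1.0)
  # zero-probability genotype: flagged, uniform tie-break
  r$haplotype_freqs[] <- 0
  r$haplotype_freqs[["vA"]] <- 1
  calls <- assign_diplotypes(r)
  expect_true(calls$zero_prob)
})

test_that("multi-seed phasing uses the published seeds and reports agreement", {
  cfg <- analysis_config()
  expect_identical(cfg$em_seeds,
                   c(2L, 1536L, 2936L, 3123L, 4957L, 5283L, 6757L, 7992L,
                     8633L, 9045L))
  # phase-unambiguous data: 100% agreement across seeds
  g <- matrix(c(0L, 2L, 2L, 0L, 0L, 0L), ncol = 1,
              dimnames = list(NULL, "vA"))
  p <- genotype_panel(paste0("s", 1:6), rep("X", 6), g)
  ms <- multi_seed_phasing(p, config = cfg)
  expect_equal(ms$agreement, 1)
  expect_error(multi_seed_phasing(p, config = cfg, seeds = 1L), "two seeds")
})

test_that("EM frequencies converge to truth as samples grow", {
  fx <- oct1_fixtures()
  f <- matrix(c(0.55, 0.25, 0.12, 0.08), 1,
              dimnames = list("P", c("*1", "*2", "*3", "*7")))
  rmse_at <- function(n, seed) {
    pops <- data.frame(population = "P", region = "R", n_individuals = n)
    sim <- simulate_panel(pops, f, fx$alleles, seed = seed)
    r <- em_haplotype_frequencies(sim$panel, "P")
    ct <- compare_to_truth(assign_diplotypes(r), sim$truth,
                           est_freqs = r$haplotype_freqs)
    ct$freq_rmse
  }
  expect_lt(rmse_at(1000, 31), rmse_at(100, 31) + 1e-6)
  expect_lt(rmse_at(1000, 31), 0.02)
})
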