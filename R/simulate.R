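#' Simulate an unphased genotype panel under Hardy-Weinberg sampling
#'
#' Draws, for each individual, two star alleles from the population's allele
#' frequency vector (independent draws with probability 1 - F, identical by
#' descent with probability F), expands each allele to its defining variant
#' set, and emits unphased 0/1/2 alternate-copy counts per variant. An
#' optional symmetric per-site error flips the presence of a variant on a
#' haplotype with the given rate (applied after expansion; the truth file
#' keeps the uncorrupted draw). This is the sampling model the worldwide
#' analysis itself assumes: star-allele structured haplotypes in
#' Hardy-Weinberg proportions within populations.
#'
#' @param populations data.frame: population, region, n_individuals.
#' @param freqs population x allele frequency matrix (rows sum to 1;
#'   rownames = populations, colnames = allele names).
#' @param alleles allele definition table; every allele in \code{freqs} must
#'   have a known variant composition.
#' @param inbreeding_F probability that an individual's two alleles are
#'   identical by descent (default 0).
#' @param error_rate per-site, per-haplotype symmetric flip probability.
#' @param seed RNG seed.
#' @return list: \code{panel} (a \code{genotype_panel}), \code{truth}
#'   (per-sample true allele pair and haplotype keys), \code{realized}
#'   (population x allele realized chromosome counts).
#' @export
simulate_panel <- function(populations, freqs, alleles, inbreeding_F = 0,
                           error_rate = 0, seed = NULL) {
  stopifnot(inbreeding_F >= 0, inbreeding_F <= 1,
            error_rate >= 0, error_rate < 1)
  if (is.null(rownames(freqs)) || is.null(colnames(freqs))) {
    stop("freqs needs population rownames and allele colnames")
  }
  if (any(abs(rowSums(freqs) - 1) > 1e-9)) {
    stop("each population's allele frequencies must sum to 1")
  }
  defs <- alleles[match(colnames(freqs), alleles$allele), ]
  if (anyNA(defs$allele)) {
    stop("alleles missing from the definition table: ",
         paste(setdiff(colnames(freqs), alleles$allele), collapse = ", "))
  }
  if (any(vapply(defs$variant_set, anyNA, logical(1)))) {
    stop("alleles of unknown composition cannot be simulated: ",
         paste(defs$allele[vapply(defs$variant_set, anyNA, logical(1))],
               collapse = ", "))
  }
  variants <- sort(unique(unlist(defs$variant_set)))
  if (length(variants) == 0L) variants <- character(0)
  # allele x variant indicator
  ind <- vapply(variants, function(v) {
    vapply(defs$variant_set, function(s) v %in% s, logical(1))
  }, logical(nrow(defs)))
  ind <- matrix(ind, nrow = nrow(defs),
                dimnames = list(defs$allele, variants))

  with_seed(seed, {
    rows <- list()
    K <- ncol(freqs)
    for (pi in seq_len(nrow(populations))) {
      pop <- populations$population[pi]
      N <- populations$n_individuals[pi]
      f <- freqs[pop, ]
      a1 <- sample.int(K, N, replace = TRUE, prob = f)
      ibd <- runif(N) < inbreeding_F
      a2 <- ifelse(ibd, a1, sample.int(K, N, replace = TRUE, prob = f))
      rows[[pi]] <- data.frame(
        sample_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "_", pop),
                            seq_len(N)),
        population = pop,
        a1 = colnames(freqs)[a1], a2 = colnames(freqs)[a2],
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    h1 <- ind[truth$a1, , drop = FALSE]
    h2 <- ind[truth$a2, , drop = FALSE]
    if (error_rate > 0 && length(variants) > 0L) {
      flip1 <- matrix(runif(length(h1)) < error_rate, nrow = nrow(h1))
      flip2 <- matrix(runif(length(h2)) < error_rate, nrow = nrow(h2))
      g1 <- xor(h1, flip1); g2 <- xor(h2, flip2)
    } else {
      g1 <- h1; g2 <- h2
    }
    geno <- matrix(as.integer(g1) + as.integer(g2), nrow = nrow(truth),
                   dimnames = list(NULL, variants))

    truth$hap1 <- apply(h1, 1L, function(z) hap_key(variants[z]))
    truth$hap2 <- apply(h2, 1L, function(z) hap_key(variants[z]))
    realized <- t(vapply(unique(truth$population), function(p) {
      sel <- truth$population == p
      tabulate(match(c(truth$a1[sel], truth$a2[sel]), colnames(freqs)),
               nbins = K)
    }, integer(K)))
    colnames(realized) <- colnames(freqs)

    panel_df <- data.frame(population = populations$population,
                           region = populations$region,
                           n_individuals = populations$n_individuals,
                           n_chromosomes = 2L * populations$n_individuals,
                           admixed = if ("admixed" %in% colnames(populations))
                             populations$admixed else FALSE,
                           source = "simulated",
                           stringsAsFactors = FALSE)
    list(panel = genotype_panel(truth$sample_id, truth$population, geno,
                                panel = panel_df),
         truth = truth, realized = realized)
  })
}

#' Simulate a world-scale panel from the packaged frequency fixture
#'
#' Uses the per-population star-allele frequencies of the worldwide fixture
#' as the sampling distribution, mirroring the study's population sizes
#' (optionally overridden). Alleles of unknown composition (e.g. *16) are
#' dropped with renormalisation of the remaining frequencies.
#'
#' @param fx fixtures from [oct1_fixtures()].
#' @param n_override single number of individuals per population, or NULL
#'   to mirror the fixture sizes.
#' @param include_admixed include the admixed 1000 Genomes populations.
#' @param seed RNG seed.
#' @return as [simulate_panel()], plus \code{dropped_alleles}.
#' @export
simulate_from_fixture <- function(fx, n_override = NULL,
                                  include_admixed = FALSE, seed = NULL) {
  panel <- fx$panel
  if (!include_admixed) panel <- panel[!panel$admixed, ]
  freqs <- fx$allele_freqs[panel$population, , drop = FALSE]
  known <- colnames(freqs)[!vapply(
    fx$alleles$variant_set[match(colnames(freqs), fx$alleles$allele)],
    anyNA, logical(1))]
  dropped <- setdiff(colnames(freqs), known)
  freqs <- freqs[, known, drop = FALSE]
  freqs <- sweep(freqs, 1, rowSums(freqs), "/")
  pops <- data.frame(population = panel$population, region = panel$region,
                     n_individuals = if (is.null(n_override))
                       panel$n_individuals else as.integer(n_override),
                     admixed = panel$admixed,
                     stringsAsFactors = FALSE)
  out <- simulate_panel(pops, freqs, fx$alleles, seed = seed)
  out$dropped_alleles <- dropped
  out
}

#' Compare pipeline output with simulation truth
#'
#' Scores phased diplotype calls against the true haplotype pairs of a
#' simulated panel: per-sample diplotype accuracy (unordered pair match on
#' haplotype keys), per-population haplotype frequency RMSE, and a
#' confusion table of phenotype calls when classifications are supplied.
#'
#' @param calls data.frame with sample_id, hap1, hap2 (haplotype keys).
#' @param truth truth data.frame from [simulate_panel()].
#' @param est_freqs optional named estimated haplotype frequencies to score
#'   against the realized truth frequencies (single-group case).
#' @return list: diplotype_accuracy, freq_rmse (NA unless est_freqs given),
#'   n.
#' @export
compare_to_truth <- function(calls, truth, est_freqs = NULL) {
  m <- match(calls$sample_id, truth$sample_id)
  if (anyNA(m)) stop("sample sets of calls and truth do not match")
  tt <- truth[m, ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "||")
  acc <- mean(key(calls$hap1, calls$hap2) == key(tt$hap1, tt$hap2))
  rmse <- NA_real_
  if (!is.null(est_freqs)) {
    true_tab <- table(c(tt$hap1, tt$hap2)) / (2 * nrow(tt))
    all_h <- union(names(true_tab), names(est_freqs))
    tv <- setNames(numeric(length(all_h)), all_h)
    ev <- tv
    tv[names(true_tab)] <- as.numeric(true_tab)
    ev[names(est_freqs)] <- est_freqs
    rmse <- sqrt(mean((tv - ev)^2))
  }
  list(diplotype_accuracy = acc, freq_rmse = rmse, n = nrow(tt))
}
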