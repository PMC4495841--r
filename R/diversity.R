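#' Allele frequency summaries in the style of the worldwide table
#'
#' Computes, from per-population allele counts, the within-population
#' frequencies, unweighted per-region means (arithmetic mean over member
#' populations, admixed populations excluded from their own region rows),
#' a worldwide summary row (unweighted mean over all populations, the
#' convention of the published table), and chromosome-weighted pooled
#' frequencies for an arbitrary population subset.
#'
#' @param allele_counts population x allele integer matrix (rownames are
#'   populations), e.g. built from \code{oct1_fixtures()}.
#' @param panel population panel data.frame.
#' @param pool_subset optional character vector of populations to pool with
#'   chromosome weights (e.g. the 53 HGDP-CEPH populations).
#' @return list: \code{population} (percent data.frame), \code{region_means}
#'   (percent), \code{worldwide_mean} (percent, unweighted over all
#'   populations), \code{pooled} (percent, NULL unless requested).
#' @export
frequency_table <- function(allele_counts, panel, pool_subset = NULL) {
  stopifnot(all(rownames(allele_counts) %in% panel$population))
  panel <- panel[match(rownames(allele_counts), panel$population), ]
  freq <- sweep(allele_counts, 1, panel$n_chromosomes, "/")

  regions <- unique(panel$region[!panel$admixed])
  region_means <- t(vapply(regions, function(r) {
    rows <- which(panel$region == r & !panel$admixed)
    colMeans(freq[rows, , drop = FALSE])
  }, numeric(ncol(freq))))
  rownames(region_means) <- regions

  worldwide <- colMeans(freq)

  pooled <- NULL
  if (!is.null(pool_subset)) {
    rows <- match(pool_subset, rownames(allele_counts))
    if (anyNA(rows)) {
      stop("pool_subset populations not found: ",
           paste(pool_subset[is.na(rows)], collapse = ", "))
    }
    pooled <- colSums(allele_counts[rows, , drop = FALSE]) /
      sum(panel$n_chromosomes[rows])
  }

  list(population = 100 * freq,
       region_means = 100 * region_means,
       worldwide_mean = 100 * worldwide,
       pooled = if (is.null(pooled)) NULL else 100 * pooled,
       n_chromosomes = setNames(panel$n_chromosomes, panel$population))
}

#' Pooled frequency of an amino-acid variant over a population subset
#'
#' A variant's chromosome count is the sum of the counts of every star
#' allele whose definition contains it (e.g. Met420del travels on *2, *5,
#' *6 and *14). The pooled frequency is chromosome-weighted over the subset.
#'
#' @param variant variant id.
#' @param allele_counts population x allele count matrix.
#' @param alleles allele definition table.
#' @param panel population panel.
#' @param populations subset of populations (default: all rows).
#' @return frequency in [0, 1].
#' @export
pooled_variant_maf <- function(variant, allele_counts, alleles, panel,
                               populations = rownames(allele_counts)) {
  known <- !vapply(alleles$variant_set, anyNA, logical(1))
  if (!variant %in% unlist(alleles$variant_set[known])) {
    stop("unknown variant: ", variant)
  }
  carriers <- alleles$allele[known][vapply(alleles$variant_set[known],
                                           function(v) variant %in% v,
                                           logical(1))]
  carriers <- intersect(carriers, colnames(allele_counts))
  rows <- match(populations, rownames(allele_counts))
  if (anyNA(rows)) stop("populations not found in allele counts")
  cnt <- sum(allele_counts[rows, carriers, drop = FALSE])
  chr <- sum(panel$n_chromosomes[match(populations, panel$population)])
  cnt / chr
}

#' Nucleotide diversity from per-site variant counts
#'
#' \eqn{\pi = \frac{n}{n-1} \sum_s 2 p_s (1 - p_s) / L}, the average number
#' of pairwise differences per site: the unbiased heterozygosity summed over
#' segregating sites and normalised by the coding-region length L.
#'
#' @param counts integer vector of variant-allele counts per site (sites
#'   with count 0 or n contribute nothing and may be omitted).
#' @param n number of chromosomes sampled (must be >= 2 and constant across
#'   sites).
#' @param L normalising sequence length in bp.
#' @return per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(counts, n, L) {
  if (n < 2) stop("nucleotide diversity needs at least 2 chromosomes")
  if (any(counts < 0 | counts > n)) stop("counts must lie in [0, n]")
  p <- counts / n
  (n / (n - 1)) * sum(2 * p * (1 - p)) / L
}

#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S number of segregating sites.
#' @param n number of chromosomes.
#' @param L normalising length in bp.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("Watterson's theta needs at least 2 chromosomes")
  if (S == 0) return(0)
  a1 <- sum(1 / seq_len(n - 1))
  S / (a1 * L)
}

#' Tajima's D constants
#'
#' The 1989 normalising constants a1, a2, b1, b2, c1, c2, e1, e2 for sample
#' size n.
#'
#' @param n sample size (chromosomes).
#' @return named list of constants.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D with an optional coalescent-simulation p-value
#'
#' \eqn{D = (\hat{k} - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}} where
#' \eqn{\hat{k}} is the mean number of pairwise differences. The p-value is
#' obtained by simulating neutral coalescent genealogies at the same n with
#' S mutations dropped on the tree. The default convention follows the
#' simulation test of the classical population-genetics packages: the
#' lower-tail probability \eqn{P(D_{sim} \le D_{obs})}, which is the
#' quantity to compare with a significance level when testing for an excess
#' of rare variants (purifying selection or expansion). The two-sided count
#' \eqn{P(|D_{sim}| \ge |D_{obs}|)} and the upper tail are also available.
#' All p-values use the add-one correction.
#'
#' @param counts per-site variant-allele counts (0 < count < n for
#'   segregating sites).
#' @param n chromosomes sampled.
#' @param p_value simulate a null p-value?
#' @param n_sims replicates for the null distribution.
#' @param seed RNG seed for the simulation.
#' @param alternative "less" (default), "greater" or "two.sided".
#' @return list: D, S, p_value (NA unless requested), n_sims, alternative.
#' @export
tajimas_d <- function(counts, n, p_value = FALSE, n_sims = 10000L,
                      seed = NULL,
                      alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n < 4) stop("Tajima's D needs at least 4 chromosomes")
  counts <- counts[counts > 0 & counts < n]
  S <- length(counts)
  if (S == 0) {
    return(list(D = NA_real_, S = 0L, p_value = NA_real_,
                reason = "no segregating sites"))
  }
  k <- tajima_constants(n)
  khat <- sum(2 * counts * (n - counts)) / (n * (n - 1))
  D <- (khat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  p <- NA_real_
  if (p_value) {
    sims <- with_seed(seed, coalescent_D_null(as.integer(n),
                                              as.integer(n_sims),
                                              S = as.integer(S)))
    hits <- switch(alternative,
                   less = sum(sims <= D, na.rm = TRUE),
                   greater = sum(sims >= D, na.rm = TRUE),
                   two.sided = sum(abs(sims) >= abs(D), na.rm = TRUE))
    p <- (hits + 1) / (n_sims + 1)
  }
  list(D = D, S = S, p_value = p, n_sims = if (p_value) n_sims else 0L,
       alternative = alternative)
}

#' Per-region site-frequency strata from the packaged fixtures
#'
#' Builds, for every non-admixed world region, the pooled per-variant
#' chromosome counts that feed the stratified diversity table. Counts of
#' variants carried by major star alleles come from the allele-count
#' fixture (a variant's count is the sum over carrier alleles); counts of
#' the activity-neutral variants that segregate only on sub-alleles are
#' taken from the synthetic per-region frequency reconstruction and rounded
#' to chromosomes.
#'
#' @param fx fixture list from [oct1_fixtures()].
#' @param variant_classes output of [classify_variants()].
#' @param include_nonlof include the synthetic neutral-variant counts.
#' @return data.frame: region, variant_id, functional_class, count, n.
#' @export
region_site_strata <- function(fx, variant_classes,
                               include_nonlof = TRUE) {
  panel <- fx$panel[!fx$panel$admixed, ]
  cmat <- matrix(fx$allele_counts$count,
                 nrow = length(unique(fx$allele_counts$population)),
                 dimnames = list(unique(fx$allele_counts$population),
                                 unique(fx$allele_counts$allele)))
  known <- !vapply(fx$alleles$variant_set, anyNA, logical(1))
  defs <- fx$alleles[known, ]
  variants_on_major <- unique(unlist(defs$variant_set[defs$allele %in%
                                                        colnames(cmat)]))
  cls <- setNames(variant_classes$functional_class,
                  variant_classes$variant_id)
  out <- list()
  for (r in unique(panel$region)) {
    pops <- panel$population[panel$region == r]
    n_r <- sum(panel$n_chromosomes[panel$region == r])
    for (v in variants_on_major) {
      carriers <- defs$allele[vapply(defs$variant_set, function(s) v %in% s,
                                     logical(1))]
      carriers <- intersect(carriers, colnames(cmat))
      cnt <- sum(cmat[pops, carriers, drop = FALSE])
      if (cnt > 0L && cnt < n_r) {
        out[[length(out) + 1L]] <- data.frame(
          region = r, variant_id = v,
          functional_class = unname(cls[v]),
          count = cnt, n = n_r, stringsAsFactors = FALSE)
      }
    }
    if (include_nonlof) {
      nl <- fx$nonlof_freqs[fx$nonlof_freqs$region == r, , drop = FALSE]
      if (nrow(nl) == 1L) {
        for (v in setdiff(colnames(nl), "region")) {
          cnt <- round(nl[[v]] * n_r)
          if (cnt > 0L && cnt < n_r) {
            out[[length(out) + 1L]] <- data.frame(
              region = r, variant_id = v,
              functional_class = unname(cls[v]),
              count = cnt, n = n_r, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Functionally stratified diversity table
#'
#' For each region and stratum (all sites, LOF sites, non-LOF sites):
#' number of segregating sites S, per-site nucleotide diversity, Watterson's
#' theta and Tajima's D (with optional simulation p-value), plus the
#' pi_LOF / pi_non-LOF ratio per region. Regions with no segregating sites
#' in a stratum report pi = theta = 0 and D as missing.
#'
#' @param strata data.frame from [region_site_strata()].
#' @param L normalising length (bp).
#' @param d_pvalues simulate p-values for D?
#' @param n_sims,seed null-simulation settings.
#' @return list: \code{table} (region x stratum rows), \code{ratios}
#'   (pi_LOF / pi_non-LOF per region; 0 when pi_LOF = 0, NA when
#'   pi_non-LOF = 0).
#' @export
stratified_diversity <- function(strata, L = 1665, d_pvalues = FALSE,
                                 n_sims = 10000L, seed = NULL) {
  pick <- function(df, stratum) {
    switch(stratum,
           all = df,
           LOF = df[df$functional_class == "LOF", , drop = FALSE],
           non_LOF = df[df$functional_class == "non_LOF", , drop = FALSE])
  }
  rows <- list()
  for (r in unique(strata$region)) {
    df_r <- strata[strata$region == r, , drop = FALSE]
    n_r <- df_r$n[1]
    for (st in c("all", "LOF", "non_LOF")) {
      d <- pick(df_r, st)
      S <- nrow(d)
      pi <- if (S == 0) 0 else nucleotide_diversity(d$count, n_r, L)
      th <- watterson_theta(S, n_r, L)
      td <- if (S >= 1 && n_r >= 4) {
        tajimas_d(d$count, n_r, p_value = d_pvalues, n_sims = n_sims,
                  seed = seed)
      } else list(D = NA_real_, p_value = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, stratum = st, n = n_r, S = S,
        pi_per_site = pi, theta_per_site = th,
        tajimas_D = td$D, D_p_value = td$p_value, L = L,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ratios <- vapply(unique(tab$region), function(r) {
    plof <- tab$pi_per_site[tab$region == r & tab$stratum == "LOF"]
    pnon <- tab$pi_per_site[tab$region == r & tab$stratum == "non_LOF"]
    if (pnon == 0) return(NA_real_)
    plof / pnon
  }, numeric(1))
  list(table = tab, ratios = ratios)
}
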