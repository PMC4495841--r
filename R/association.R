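#' Carrier distribution under Hardy-Weinberg equilibrium
#'
#' Probabilities of carrying two, one or zero fully active alleles given the
#' frequency p of active alleles: \eqn{(p^2, 2p(1-p), (1-p)^2)}.
#'
#' @param p_active frequency of fully active alleles in [0, 1].
#' @return named numeric vector (p_two, p_one, p_zero), summing to 1.
#' @export
hwe_carrier_distribution <- function(p_active) {
  if (is.na(p_active) || p_active < 0 || p_active > 1) {
    stop("p_active must lie in [0, 1]")
  }
  q <- 1 - p_active
  c(p_two = p_active^2, p_one = 2 * p_active * q, p_zero = q^2)
}

#' Exact multinomial point probability
#'
#' Probability of observing exactly the given category counts under a
#' multinomial distribution: \eqn{n!/(\prod_i k_i!) \prod_i p_i^{k_i}}.
#' A category with probability zero and a positive count gives 0.
#'
#' @param counts non-negative integer counts per category.
#' @param probs category probabilities (same length; normalised internally).
#' @return the point probability.
#' @export
multinomial_point_probability <- function(counts, probs) {
  if (length(counts) != length(probs)) stop("counts and probs must align")
  if (any(counts < 0)) stop("negative counts")
  if (any(probs < 0)) stop("negative probabilities")
  # probabilities are used as supplied: published carrier splits are rounded
  # percentages and may miss 1 by a little; renormalising would change the
  # reproduced values
  if (abs(sum(probs) - 1) > 0.05) stop("probabilities must sum to ~1")
  if (any(probs == 0 & counts > 0)) return(0)
  n <- sum(counts)
  keep <- counts > 0
  exp(lgamma(n + 1) - sum(lgamma(counts + 1)) +
        sum(counts[keep] * log(probs[keep])))
}

# All k-category count vectors summing to n (compositions), as a matrix.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

#' Exact multinomial tail probability
#'
#' Total probability of all outcomes at most as probable as the observed
#' one (the exact multinomial test): sums the point masses of every count
#' vector with point probability less than or equal to that of the observed
#' counts. Enumeration is exact and limited to small n.
#'
#' @param counts observed category counts (sum n <= 20).
#' @param probs category probabilities.
#' @return the tail probability in (0, 1].
#' @export
multinomial_tail_probability <- function(counts, probs) {
  n <- sum(counts)
  if (n > 20) stop("enumeration limited to n <= 20")
  p_obs <- multinomial_point_probability(counts, probs)
  cmp <- compositions(n, length(counts))
  masses <- apply(cmp, 1L, multinomial_point_probability, probs = probs)
  sum(masses[masses <= p_obs * (1 + 1e-12)])
}

#' Pearson correlation with a t-test p-value
#'
#' Standard product-moment correlation between paired per-population values
#' with the two-sided t-distribution p-value. Zero variance in either
#' variable is flagged rather than returning a spurious value.
#'
#' @param x,y paired numeric vectors (n >= 3, finite).
#' @return list: r, r_squared, n, p_value, degenerate flag.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    return(list(r = NA_real_, r_squared = NA_real_, n = n,
                p_value = NA_real_, degenerate = TRUE))
  }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, r_squared = r^2, n = n, p_value = p, degenerate = FALSE)
}

#' Per-population loss-of-activity frequency
#'
#' Summarises loss of OCT1 activity per population either as the frequency
#' of non-active star alleles ("allele") or as the frequency of individuals
#' carrying at most one active allele ("carrier", from a phenotype
#' distribution).
#'
#' @param allele_counts population x allele count matrix.
#' @param classification output of [classify_alleles()]; alleles missing
#'   from it count as non-active.
#' @param metric "allele" or "carrier".
#' @param phenotype_dist phenotype distribution (from [score_phenotypes()])
#'   required for \code{metric = "carrier"}.
#' @return named vector of per-population loss frequencies in [0, 1].
#' @export
loss_frequency_per_population <- function(allele_counts, classification,
                                          metric = c("allele", "carrier"),
                                          phenotype_dist = NULL) {
  metric <- match.arg(metric)
  if (metric == "allele") {
    act <- classification$allele[classification$active_for_phenotype]
    active_cols <- intersect(colnames(allele_counts), act)
    tot <- rowSums(allele_counts)
    active <- rowSums(allele_counts[, active_cols, drop = FALSE])
    return((tot - active) / tot)
  }
  if (is.null(phenotype_dist)) {
    stop("carrier metric needs a phenotype distribution")
  }
  setNames((phenotype_dist$one_active + phenotype_dist$zero_active) /
             phenotype_dist$n, phenotype_dist$population)
}
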