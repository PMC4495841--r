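# Haplotype keys are comma-joined sorted variant ids; "." is the reference
# haplotype carrying no variant (an empty string would not be addressable by
# name in R vectors).

hap_key <- function(variants) {
  if (length(variants) == 0L) "." else paste(sort(variants), collapse = ",")
}

hap_variants <- function(key) {
  if (!nzchar(key) || identical(key, ".")) character(0)
  else strsplit(key, ",", fixed = TRUE)[[1]]
}

# Enumerate the genotype-consistent unordered haplotype pairs of one
# genotype vector (0/1/2 per site). Returns a 2-column character matrix of
# haplotype keys; 2^(m-1) rows for m heterozygous sites.
enumerate_pairs <- function(geno, sites) {
  het <- sites[geno == 1L]
  hom <- sites[geno == 2L]
  m <- length(het)
  if (m > 20L) {
    stop("more than 20 heterozygous sites in one individual; ",
         "phase enumeration is infeasible - filter sites first")
  }
  if (m == 0L) {
    k <- hap_key(hom)
    return(matrix(c(k, k), ncol = 2))
  }
  n_half <- 2L^(m - 1L)
  out <- matrix("", nrow = n_half, ncol = 2)
  for (s in seq_len(n_half) - 1L) {
    # first het site always goes to hap1: enumerates unordered pairs once
    pick <- c(TRUE, as.logical(bitwAnd(s, 2L^(seq_len(m - 1L) - 1L))))
    out[s + 1L, 1L] <- hap_key(c(hom, het[pick]))
    out[s + 1L, 2L] <- hap_key(c(hom, het[!pick]))
  }
  out
}

# Collapse a genotype matrix into unique genotype classes and build the
# pair table used by the EM. Returns list(haps, pairs, class_of_sample, ...).
build_phase_space <- function(genotypes) {
  if (ncol(genotypes) > 25L) {
    stop("more than 25 variant sites; restrict to the polymorphic sites ",
         "of interest before phasing")
  }
  key <- apply(genotypes, 1L, paste, collapse = "|")
  classes <- match(key, unique(key))
  uniq <- genotypes[!duplicated(key), , drop = FALSE]
  sites <- colnames(genotypes)
  pair_list <- lapply(seq_len(nrow(uniq)), function(i) {
    enumerate_pairs(uniq[i, ], sites)
  })
  haps <- sort(unique(unlist(pair_list)))
  pairs <- do.call(rbind, lapply(seq_along(pair_list), function(i) {
    p <- pair_list[[i]]
    cbind(class = i, h1 = match(p[, 1], haps), h2 = match(p[, 2], haps))
  }))
  list(haps = haps, pairs = pairs, class_of_sample = classes,
       class_count = tabulate(classes, nbins = length(pair_list)),
       pair_rows_of_class = split(seq_len(nrow(pairs)), pairs[, "class"]))
}

#' Estimate haplotype frequencies by EM
#'
#' Expectation-maximisation estimate of haplotype frequencies from unphased
#' diploid genotypes under random union of gametes (Hardy-Weinberg at the
#' haplotype level): the classical approach of gene-counting for multi-site
#' phase ambiguity. The log-likelihood is non-decreasing over iterations and
#' the iteration stops when its gain drops below \code{config$em_tol} or
#' after \code{config$em_max_iter} iterations.
#'
#' @param panel a \code{genotype_panel}.
#' @param group optional population name(s) to phase; default all samples.
#' @param config an [analysis_config()].
#' @param init "uniform" or "random" (Dirichlet-like random start).
#' @param seed RNG seed used when \code{init = "random"}.
#' @return object of class \code{phasing_result}: haplotype frequencies
#'   (named, summing to 1), log-likelihood, iteration count, convergence
#'   flag, and the internal phase space reused by [assign_diplotypes()].
#' @export
em_haplotype_frequencies <- function(panel, group = NULL, config = analysis_config(),
                                     init = c("uniform", "random"), seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  init <- match.arg(init)
  keep <- if (is.null(group)) rep(TRUE, nrow(panel$genotypes)) else
    panel$samples$population %in% group
  if (!any(keep)) stop("no samples in the requested group")
  g <- panel$genotypes[keep, , drop = FALSE]
  ids <- panel$samples$sample_id[keep]

  sp <- build_phase_space(g)
  H <- length(sp$haps)
  n <- nrow(g)

  f <- if (init == "uniform") rep(1 / H, H) else
    with_seed(seed, { x <- runif(H, min = 0.05); x / sum(x) })

  h1 <- sp$pairs[, "h1"]; h2 <- sp$pairs[, "h2"]
  cls <- sp$pairs[, "class"]
  het <- as.numeric(h1 != h2)
  wc <- sp$class_count
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- f[h1] * f[h2] * (1 + het)          # P(pair | f)
    denom <- as.vector(rowsum(w, cls))      # P(genotype | f) per class
    if (any(denom <= 0)) {                  # degenerate start: reset flat
      f <- rep(1 / H, H); next
    }
    ll <- sum(wc * log(denom))
    post <- wc[cls] * w / denom[cls]
    f_new <- numeric(H)
    acc1 <- rowsum(post, h1)
    f_new[as.integer(rownames(acc1))] <- acc1
    acc2 <- rowsum(post, h2)
    f_new[as.integer(rownames(acc2))] <-
      f_new[as.integer(rownames(acc2))] + acc2
    f_new <- f_new / (2 * n)
    if (ll - ll_old < config$em_tol && iter > 1L) {
      converged <- TRUE
      f <- f_new
      ll_old <- ll
      break
    }
    f <- f_new
    ll_old <- ll
    if (iter >= config$em_max_iter) break
  }
  # report the likelihood of the frequencies actually returned
  w <- f[h1] * f[h2] * (1 + het)
  denom <- as.vector(rowsum(w, cls))
  ll_old <- sum(wc * log(denom))
  names(f) <- sp$haps
  structure(list(haplotype_freqs = f, log_likelihood = ll_old,
                 n_iterations = iter, converged = converged, seed = seed,
                 sample_id = ids,
                 population = panel$samples$population[keep],
                 phase_space = sp, n = n),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat("EM phasing:", x$n, "samples,", length(x$haplotype_freqs),
      "haplotypes, logLik", format(x$log_likelihood, digits = 6),
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  invisible(x)
}

#' Assign the most probable diplotype to each sample
#'
#' For each sample the genotype-consistent haplotype pair maximising
#' \eqn{f_{h_1} f_{h_2}} (doubled for heterotypic pairs) is chosen; its
#' posterior probability under the fitted frequencies is reported. Exact
#' ties are broken lexicographically on the haplotype labels and flagged.
#' Samples whose genotype has probability zero under the fitted frequencies
#' are assigned by a uniform tie-break over consistent pairs and flagged.
#'
#' @param result a \code{phasing_result}.
#' @return data.frame: sample_id, population, hap1, hap2, posterior,
#'   tie (logical), zero_prob (logical).
#' @export
assign_diplotypes <- function(result) {
  stopifnot(inherits(result, "phasing_result"))
  sp <- result$phase_space
  f <- result$haplotype_freqs
  h1 <- sp$pairs[, "h1"]; h2 <- sp$pairs[, "h2"]
  het <- as.numeric(h1 != h2)
  w <- f[h1] * f[h2] * (1 + het)
  out <- lapply(seq_along(sp$class_count), function(ci) {
    rows <- sp$pair_rows_of_class[[as.character(ci)]]
    if (is.null(rows)) rows <- which(sp$pairs[, "class"] == ci)
    wi <- w[rows]
    zero <- sum(wi) <= 0
    if (zero) wi <- rep(1, length(wi))
    post <- wi / sum(wi)
    lab1 <- sp$haps[h1[rows]]; lab2 <- sp$haps[h2[rows]]
    best <- which(wi == max(wi))
    tie <- length(best) > 1L
    if (tie) best <- best[order(lab1[best], lab2[best])][1L] else best <- best[1L]
    data.frame(hap1 = lab1[best], hap2 = lab2[best],
               posterior = post[best], tie = tie, zero_prob = zero,
               stringsAsFactors = FALSE)
  })
  cls <- sp$class_of_sample
  calls <- do.call(rbind, out)[cls, , drop = FALSE]
  rownames(calls) <- NULL
  cbind(data.frame(sample_id = result$sample_id,
                   population = result$population,
                   stringsAsFactors = FALSE), calls)
}

#' Multi-seed EM phasing with a consistency report
#'
#' Runs the EM from several random starts (by default the ten seeds of the
#' published haplotype-inference protocol), keeps the best-likelihood run,
#' and reports the fraction of samples whose most-probable diplotype call is
#' identical across all runs. Disagreement across seeds marks samples whose
#' phase is not determined by the data (e.g. symmetric double
#' heterozygotes).
#'
#' @param panel a \code{genotype_panel}.
#' @param group optional population subset.
#' @param config an [analysis_config()].
#' @param seeds integer seeds (>= 2 required); default \code{config$em_seeds}.
#' @return list: \code{best} (phasing_result), \code{agreement} (fraction of
#'   samples with seed-stable calls), \code{calls} (diplotypes of the best
#'   run), \code{seed_lls} (named log-likelihoods).
#' @export
multi_seed_phasing <- function(panel, group = NULL, config = analysis_config(),
                               seeds = config$em_seeds) {
  if (length(seeds) < 2L) stop("at least two seeds are required")
  runs <- lapply(seeds, function(s) {
    em_haplotype_frequencies(panel, group, config, init = "random", seed = s)
  })
  calls <- lapply(runs, function(r) {
    d <- assign_diplotypes(r)
    paste(d$hap1, d$hap2, sep = "|")
  })
  same <- Reduce(`&`, lapply(calls[-1], function(x) x == calls[[1]]))
  lls <- vapply(runs, function(r) r$log_likelihood, numeric(1))
  best <- runs[[which.max(lls)]]
  list(best = best, agreement = mean(same),
       calls = assign_diplotypes(best),
       seed_lls = setNames(lls, seeds))
}
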