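# Squared-distance bookkeeping shared by AMOVA and pairwise Phi_ST.
# Observations are items (chromosomes or individuals) carrying a state id
# into a symmetric squared-distance matrix D; group sums use the state
# count matrix C (states x groups): sum_{i,j in g} d2_ij = c_g' D c_g.

amova_ssd <- function(C, D, sizes) {
  M <- D %*% C
  W <- colSums(C * M)            # per group: sum over ordered pairs
  ssd_within <- sum(W / (2 * sizes))
  tot <- rowSums(C)
  ssd_total <- as.numeric(tot %*% D %*% tot) / (2 * sum(sizes))
  list(within = ssd_within, total = ssd_total)
}

# Hierarchical decomposition for populations nested in regions (or a single
# level when region is NULL). Returns components BEFORE truncation.
amova_components <- function(hap_id, pop_id, region_of_pop, D) {
  H <- nrow(D)
  P <- length(unique(pop_id))
  N <- length(hap_id)
  C <- matrix(tabulate(hap_id + H * (pop_id - 1L), H * P), nrow = H)
  n_p <- colSums(C)
  three <- !is.null(region_of_pop)

  ss <- amova_ssd(C, D, n_p)
  ssd_wp <- ss$within
  ssd_total <- ss$total

  if (!three) {
    df_ap <- P - 1L
    df_wp <- N - P
    ssd_ap <- ssd_total - ssd_wp
    ms_wp <- ssd_wp / df_wp
    ms_ap <- ssd_ap / df_ap
    n_prime <- (N - sum(n_p^2) / N) / (P - 1)
    sigma_c <- ms_wp
    sigma_a <- (ms_ap - sigma_c) / n_prime
    return(list(levels = 2L, N = N,
                ssd = c(among_groups = ssd_ap, within = ssd_wp,
                        total = ssd_total),
                df = c(among_groups = df_ap, within = df_wp),
                sigma = c(a = sigma_a, c = sigma_c)))
  }

  G <- length(unique(region_of_pop))
  reg_of_pop <- as.integer(factor(region_of_pop))
  # pooled-by-region SSD
  Creg <- t(rowsum(t(C), reg_of_pop))
  n_g <- colSums(Creg)
  ssd_wr <- amova_ssd(Creg, D, n_g)$within
  ssd_ap <- ssd_wr - ssd_wp        # among populations within regions
  ssd_ag <- ssd_total - ssd_wr     # among regions
  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- N - P
  ms_wp <- ssd_wp / df_wp
  ms_ap <- if (df_ap > 0) ssd_ap / df_ap else 0
  ms_ag <- ssd_ag / df_ag

  sum_np2_by_g <- vapply(seq_len(G), function(g) {
    sum(n_p[reg_of_pop == g]^2) / n_g[g]
  }, numeric(1))
  n1 <- if (df_ap > 0) (N - sum(sum_np2_by_g)) / df_ap else 1
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag

  sigma_c <- ms_wp
  sigma_b <- if (df_ap > 0) (ms_ap - sigma_c) / n1 else 0
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  list(levels = 3L, N = N,
       ssd = c(among_regions = ssd_ag, among_pops = ssd_ap,
               within = ssd_wp, total = ssd_total),
       df = c(among_regions = df_ag, among_pops = df_ap, within = df_wp),
       sigma = c(a = sigma_a, b = sigma_b, c = sigma_c))
}

phi_from_sigma <- function(sigma) {
  if (length(sigma) == 2L) {
    tot <- sum(sigma)
    return(c(phi_ST = if (tot > 0) sigma[["a"]] / tot else NA_real_))
  }
  tot <- sum(sigma)
  c(phi_CT = if (tot > 0) sigma[["a"]] / tot else NA_real_,
    phi_SC = if (sigma[["b"]] + sigma[["c"]] > 0)
      sigma[["b"]] / (sigma[["b"]] + sigma[["c"]]) else NA_real_,
    phi_ST = if (tot > 0) (sigma[["a"]] + sigma[["b"]]) / tot else NA_real_)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Decomposes the total molecular variance of chromosome-level observations
#' into components among regions, among populations within regions, and
#' within populations (or two levels when no regions are given), following
#' the sums-of-squared-deviations formulation from a squared pairwise
#' distance matrix with the standard unequal-sample-size coefficients.
#' Negative variance components are truncated to zero (and flagged) before
#' percentages are formed. Phi statistics are the F-statistic analogues;
#' their p-values come from permutations: chromosomes among populations
#' (Phi_ST), chromosomes among populations within regions (Phi_SC), and
#' whole populations among regions (Phi_CT).
#'
#' @param state per-observation state label (haplotype name or phenotype
#'   code); must index \code{distance}.
#' @param population per-observation population label.
#' @param region optional per-observation region label (3-level AMOVA).
#' @param distance symmetric squared-distance matrix between states, with
#'   dimnames. For haplotypes the number of differing variant sites is used
#'   directly as the squared distance (the molecular convention); for
#'   phenotype codes use \code{(a-b)^2}.
#' @param nperm permutation count for p-values (0 = point estimates only).
#' @param seed RNG seed for permutations.
#' @return object of class \code{amova_result}: per-level SSD, df, variance
#'   components (raw and truncated), percentages, Phi statistics,
#'   permutation p-values.
#' @export
amova <- function(state, population, region = NULL, distance, nperm = 0L,
                  seed = NULL) {
  stopifnot(length(state) == length(population))
  if (!is.null(region)) stopifnot(length(region) == length(state))
  labs <- rownames(distance)
  hap_id <- match(as.character(state), labs)
  if (anyNA(hap_id)) {
    stop("states absent from the distance matrix: ",
         paste(unique(state[is.na(hap_id)]), collapse = ", "))
  }
  pop_f <- factor(population)
  pop_id <- as.integer(pop_f)
  P <- nlevels(pop_f)
  if (P < 2L) stop("AMOVA needs at least 2 populations")
  region_of_pop <- NULL
  if (!is.null(region)) {
    map <- unique(data.frame(pop = pop_id, region = as.character(region)))
    if (anyDuplicated(map$pop)) stop("each population must lie in one region")
    region_of_pop <- map$region[order(map$pop)]
    if (length(unique(region_of_pop)) < 2L) {
      stop("3-level AMOVA needs at least 2 regions")
    }
  }

  obs <- amova_components(hap_id, pop_id, region_of_pop, distance)
  sigma_raw <- obs$sigma
  truncated <- sigma_raw < 0
  sigma <- pmax(sigma_raw, 0)
  tot <- sum(sigma)
  pct <- if (tot > 0) 100 * sigma / tot else rep(NA_real_, length(sigma))
  phi <- phi_from_sigma(sigma)

  # p-values compare the raw (untruncated) statistics: truncation piles
  # permuted values into a tie at zero and would make the test miscalibrated
  phi_raw <- phi_from_sigma(sigma_raw)
  pvals <- setNames(rep(NA_real_, length(phi)), names(phi))
  if (nperm > 0L) {
    pvals <- with_seed(seed, {
      N <- obs$N
      phi_perm <- matrix(NA_real_, nrow = nperm, ncol = length(phi))
      for (b in seq_len(nperm)) {
        # Phi_ST: chromosomes among populations, whole sample
        perm_all <- amova_components(hap_id[sample.int(N)], pop_id,
                                     region_of_pop, distance)
        p_all <- phi_from_sigma(perm_all$sigma)
        if (is.null(region_of_pop)) {
          phi_perm[b, ] <- p_all
        } else {
          # Phi_SC: chromosomes among populations within regions
          idx <- seq_len(N)
          reg_of_obs <- region_of_pop[pop_id]
          for (g in unique(reg_of_obs)) {
            w <- which(reg_of_obs == g)
            idx[w] <- w[sample.int(length(w))]
          }
          perm_wr <- amova_components(hap_id[idx], pop_id, region_of_pop,
                                      distance)
          p_wr <- phi_from_sigma(perm_wr$sigma)
          # Phi_CT: whole populations among regions
          perm_ct <- amova_components(hap_id, pop_id,
                                      sample(region_of_pop), distance)
          p_ct <- phi_from_sigma(perm_ct$sigma)
          phi_perm[b, ] <- c(p_ct[["phi_CT"]], p_wr[["phi_SC"]],
                             p_all[["phi_ST"]])
        }
      }
      vapply(seq_along(phi), function(j) {
        (sum(phi_perm[, j] >= phi_raw[j], na.rm = TRUE) + 1) / (nperm + 1)
      }, numeric(1)) |> setNames(names(phi))
    })
  }

  structure(list(levels = obs$levels, ssd = obs$ssd, df = obs$df,
                 sigma_raw = sigma_raw, sigma = sigma, truncated = truncated,
                 percent = pct, phi = phi, p_values = pvals,
                 nperm = as.integer(nperm), N = obs$N),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(x$levels, "-level AMOVA on ", x$N, " observations\n", sep = "")
  lvl <- if (x$levels == 3L) {
    c(a = "among regions", b = "among populations within regions",
      c = "within populations")
  } else {
    c(a = "among groups", c = "within groups")
  }
  for (k in names(x$sigma)) {
    cat(sprintf("  %-36s sigma2 = %8.5f (%5.1f%%)%s\n", lvl[[k]],
                x$sigma[[k]], x$percent[[k]],
                if (x$truncated[[k]]) " [truncated]" else ""))
  }
  for (k in names(x$phi)) {
    cat(sprintf("  %s = %.4f", k, x$phi[[k]]))
    if (!is.na(x$p_values[[k]])) cat(sprintf("  (p = %.4g)", x$p_values[[k]]))
    cat("\n")
  }
  invisible(x)
}

#' Haplotype pairwise-difference distance matrix
#'
#' Number of differing variant sites between star alleles (used directly as
#' the squared molecular distance in AMOVA). Alleles of unknown composition
#' are rejected.
#'
#' @param allele_names alleles to include.
#' @param alleles allele definition table.
#' @return symmetric integer matrix with dimnames.
#' @export
haplotype_distance_matrix <- function(allele_names, alleles) {
  sets <- alleles$variant_set[match(allele_names, alleles$allele)]
  if (any(vapply(sets, anyNA, logical(1)))) {
    stop("alleles of unknown composition cannot enter a distance matrix: ",
         paste(allele_names[vapply(sets, anyNA, logical(1))], collapse = ", "))
  }
  k <- length(sets)
  D <- matrix(0L, k, k, dimnames = list(allele_names, allele_names))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    D[i, j] <- length(setdiff(sets[[i]], sets[[j]])) +
      length(setdiff(sets[[j]], sets[[i]]))
  }
  D
}

#' Phenotype-level AMOVA
#'
#' AMOVA on individuals coded 0, 1 or 2 active alleles, with the squared
#' code difference as distance; each individual (not chromosome) is one
#' observation.
#'
#' @param n_active per-individual count of active alleles (0/1/2).
#' @param population,region,nperm,seed as in [amova()].
#' @export
phenotype_amova <- function(n_active, population, region = NULL, nperm = 0L,
                            seed = NULL) {
  codes <- 0:2
  D <- outer(codes, codes, function(a, b) (a - b)^2)
  dimnames(D) <- list(codes, codes)
  amova(as.character(n_active), population, region, D, nperm = nperm,
        seed = seed)
}

#' Pairwise Phi_ST matrix between groups
#'
#' Two-level Phi_ST for every pair of groups from a shared squared-distance
#' matrix, with optional permutation p-values (chromosomes among the two
#' groups).
#'
#' @param state per-observation state label.
#' @param group per-observation group label (population or region).
#' @param distance squared-distance matrix between states.
#' @param nperm permutations per pair (0 = none).
#' @param seed RNG seed.
#' @return list: \code{phi} (symmetric matrix, diagonal 0), \code{p_values}
#'   (matrix or NULL).
#' @export
pairwise_fst <- function(state, group, distance, nperm = 0L, seed = NULL) {
  grp <- factor(group)
  gl <- levels(grp)
  sizes <- table(grp)
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) < length(gl)) {
    warning("groups with fewer than 2 observations excluded: ",
            paste(setdiff(gl, keep), collapse = ", "))
    gl <- keep
  }
  k <- length(gl)
  if (k < 2L) stop("need at least 2 groups of size >= 2")
  phi <- matrix(0, k, k, dimnames = list(gl, gl))
  pv <- if (nperm > 0L) matrix(NA_real_, k, k, dimnames = list(gl, gl)) else NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sel <- group %in% c(gl[i], gl[j])
    res <- amova(state[sel], group[sel], region = NULL, distance,
                 nperm = nperm, seed = seed)
    phi[i, j] <- phi[j, i] <- unname(res$phi[["phi_ST"]])
    if (!is.null(pv)) pv[i, j] <- pv[j, i] <- unname(res$p_values[["phi_ST"]])
  }
  list(phi = phi, p_values = pv)
}

#' Expand grouped counts to per-observation vectors
#'
#' Convenience for fixture-based analyses: turns a population x state count
#' matrix into per-chromosome state/population/region vectors for [amova()].
#'
#' @param counts population x state matrix (rownames populations).
#' @param panel population panel (for region labels).
#' @return data.frame: state, population, region.
#' @export
expand_counts <- function(counts, panel) {
  idx <- which(counts > 0, arr.ind = TRUE)
  n <- counts[idx]
  pops <- rownames(counts)[idx[, 1]]
  states <- colnames(counts)[idx[, 2]]
  data.frame(
    state = rep(states, n),
    population = rep(pops, n),
    region = rep(panel$region[match(pops, panel$population)], n),
    stringsAsFactors = FALSE)
}
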