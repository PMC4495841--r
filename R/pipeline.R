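#' Run the worldwide loss-of-activity analysis
#'
#' Orchestrates the full analysis: allele frequency summaries, activity
#' classification, phenotype distributions, functionally stratified
#' diversity statistics, hierarchical AMOVA, and region-level pairwise
#' Phi_ST. Two modes are supported: fixture-only (frequency-based
#' statistics; diplotype-level outputs are marked unavailable) and genotype
#' mode, where an unphased [genotype_panel()] is phased per population with
#' the multi-seed EM protocol, haplotypes are named as star alleles, and
#' individual 0/1/2-active phenotypes are scored.
#'
#' @param config an [analysis_config()].
#' @param fx fixtures from [oct1_fixtures()].
#' @param genotypes optional \code{genotype_panel} of unphased genotypes.
#' @param out_dir optional directory; when given, every table is written as
#'   TSV together with a JSON run manifest.
#' @return list of result tables; see Details.
#' @details Elements: \code{frequencies} (per-population, region means,
#'   worldwide, pooled HGDP), \code{classification},
#'   \code{variant_classes}, \code{phenotype_distribution} (observed in
#'   genotype mode; Hardy-Weinberg expectation from allele frequencies in
#'   fixture mode), \code{diversity} (stratified table and ratios),
#'   \code{amova_haplotype}, \code{amova_phenotype} (NULL in fixture mode),
#'   \code{fst_regions}, \code{diplotypes} (NULL in fixture mode),
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = analysis_config(), fx = oct1_fixtures(),
                         genotypes = NULL, out_dir = NULL) {
  if (is.null(fx$activity)) stop("activity matrix is required for classification")
  cmat <- fixture_count_matrix(fx)
  hgdp <- fx$panel$population[fx$panel$source == "HGDP"]
  freqs <- frequency_table(cmat, fx$panel, pool_subset = hgdp)

  classification <- classify_alleles(fx$activity, config, alleles = fx$alleles)
  variant_classes <- classify_variants(fx$activity, fx$alleles, fx$variants,
                                       config)

  diplotypes <- NULL
  if (!is.null(genotypes)) {
    pops <- unique(genotypes$samples$population)
    calls <- do.call(rbind, lapply(pops, function(p) {
      multi_seed_phasing(genotypes, group = p, config = config)$calls
    }))
    calls$allele1 <- vapply(calls$hap1, function(h)
      name_haplotype(h, fx$alleles)$allele, character(1))
    calls$allele2 <- vapply(calls$hap2, function(h)
      name_haplotype(h, fx$alleles)$allele, character(1))
    diplotypes <- calls
    pheno <- score_phenotypes(calls, classification)
    pheno_dist <- pheno$distribution
    pheno_mode <- "observed"
  } else {
    act <- classification$allele[classification$active_for_phenotype]
    p_active <- rowSums(cmat[, intersect(colnames(cmat), act), drop = FALSE]) /
      rowSums(cmat)
    hw <- t(vapply(p_active, hwe_carrier_distribution, numeric(3)))
    pheno_dist <- data.frame(population = rownames(cmat),
                             p_two = hw[, "p_two"], p_one = hw[, "p_one"],
                             p_zero = hw[, "p_zero"],
                             stringsAsFactors = FALSE)
    pheno <- NULL
    pheno_mode <- "hwe_expected"
  }

  strata <- region_site_strata(fx, variant_classes)
  diversity <- stratified_diversity(strata, L = config$coding_length_L,
                                    d_pvalues = config$permutations > 0,
                                    n_sims = max(config$permutations, 1000L),
                                    seed = config$rng_seed)

  # chromosome-level AMOVA from the fixture counts (admixed excluded)
  keep <- !fx$panel$admixed
  known_alleles <- fx$alleles$allele[!vapply(fx$alleles$variant_set, anyNA,
                                             logical(1))]
  acols <- intersect(colnames(cmat), known_alleles)
  obs <- expand_counts(cmat[keep, acols, drop = FALSE], fx$panel)
  D <- haplotype_distance_matrix(acols, fx$alleles)
  amova_hap <- amova(obs$state, obs$population, obs$region, D,
                     nperm = config$permutations, seed = config$rng_seed)
  fst_regions <- pairwise_fst(obs$state, obs$region, D)

  amova_pheno <- NULL
  if (!is.null(genotypes)) {
    reg <- genotypes$panel$region[match(pheno$calls$population,
                                        genotypes$panel$population)]
    amova_pheno <- phenotype_amova(pheno$calls$n_active,
                                   pheno$calls$population, reg,
                                   nperm = config$permutations,
                                   seed = config$rng_seed)
  }

  manifest <- list(
    package = "lofscape",
    version = as.character(utils::packageVersion("lofscape")),
    rng_seed = config$rng_seed,
    permutations = config$permutations,
    coding_length_L = config$coding_length_L,
    active_allele_set = config$active_allele_set,
    mode = if (is.null(genotypes)) "fixture_only" else "genotype",
    phenotype_mode = pheno_mode,
    p_values_computed = config$permutations > 0
  )

  res <- list(frequencies = freqs, classification = classification,
              variant_classes = variant_classes,
              phenotype_distribution = pheno_dist,
              phenotype_mode = pheno_mode,
              diversity = diversity, amova_haplotype = amova_hap,
              amova_phenotype = amova_pheno, fst_regions = fst_regions,
              diplotypes = diplotypes, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    wt(data.frame(population = rownames(freqs$population),
                  round(freqs$population, 1), check.names = FALSE),
       "frequencies_population.tsv")
    wt(data.frame(region = rownames(freqs$region_means),
                  round(freqs$region_means, 1), check.names = FALSE),
       "frequencies_region_means.tsv")
    wt(classification, "allele_classification.tsv")
    wt(variant_classes, "variant_classes.tsv")
    wt(pheno_dist, "phenotype_distribution.tsv")
    wt(diversity$table, "diversity_stratified.tsv")
    amova_df <- data.frame(component = names(amova_hap$sigma),
                           sigma2 = amova_hap$sigma,
                           percent = amova_hap$percent)
    wt(amova_df, "amova_haplotype.tsv")
    wt(data.frame(region = rownames(fst_regions$phi),
                  fst_regions$phi, check.names = FALSE),
       "fst_regions.tsv")
    if (!is.null(diplotypes)) wt(diplotypes, "diplotypes.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Population x allele count matrix from the fixtures
#'
#' @param fx fixtures from [oct1_fixtures()].
#' @return integer matrix, populations x alleles.
#' @export
fixture_count_matrix <- function(fx) {
  pops <- unique(fx$allele_counts$population)
  alls <- unique(fx$allele_counts$allele)
  matrix(fx$allele_counts$count, nrow = length(pops),
         dimnames = list(pops, alls))
}
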