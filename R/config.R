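#' Analysis configuration
#'
#' Collects the knobs shared across the pipeline. \code{coding_length_L} is
#' the length in base pairs used to express nucleotide diversity and
#' Watterson's theta per site; the default 1665 bp corresponds to the
#' 554-codon OCT1 coding sequence plus the stop codon. The activity
#' thresholds implement the published classification rules: a major allele
#' differs from the reference by more than 50\% of activity for at least one
#' substrate, an allele counts as loss of activity if its uptake falls below
#' 35\% of the reference (a more than 65\% reduction) for at least one
#' substrate, and substrate-specific loss requires at least one substrate
#' retained above 90\%.
#'
#' @param coding_length_L coding-region length in bp used for per-site
#'   normalization.
#' @param active_allele_set star alleles regarded as fully active.
#' @param threshold_major percent deviation from reference defining a major
#'   allele (strict inequality, both directions).
#' @param threshold_loss activity (percent of reference) below which an
#'   allele loses phenotype activity (strict).
#' @param threshold_retained activity above which a substrate counts as
#'   retained for the substrate-specific pattern (strict).
#' @param complete_loss_floor activity at or below which a substrate counts
#'   as complete loss (absorbs assay noise in a figure-derived matrix).
#' @param permutations permutation count for AMOVA / F_ST p-values.
#' @param rng_seed integer seed recorded in the run manifest.
#' @param em_max_iter,em_tol,em_seeds EM phasing settings; the default seed
#'   list is the ten-seed consistency protocol used for haplotype inference
#'   in the source study.
#' @return object of class \code{lofscape_config}.
#' @export
analysis_config <- function(coding_length_L = 1665L,
                            active_allele_set = c("*1", "*8", "*9"),
                            threshold_major = 50,
                            threshold_loss = 35,
                            threshold_retained = 90,
                            complete_loss_floor = 5,
                            permutations = 10000L,
                            rng_seed = 1L,
                            em_max_iter = 500L,
                            em_tol = 1e-8,
                            em_seeds = c(2L, 1536L, 2936L, 3123L, 4957L,
                                         5283L, 6757L, 7992L, 8633L, 9045L)) {
  stopifnot(coding_length_L > 0,
            threshold_major > 0, threshold_major < 100,
            threshold_loss > 0, threshold_loss < 100,
            threshold_retained > 0, threshold_retained < 100,
            complete_loss_floor >= 0,
            permutations >= 0, em_max_iter >= 1, em_tol > 0,
            length(em_seeds) >= 1)
  structure(list(coding_length_L = as.integer(coding_length_L),
                 active_allele_set = active_allele_set,
                 threshold_major = threshold_major,
                 threshold_loss = threshold_loss,
                 threshold_retained = threshold_retained,
                 complete_loss_floor = complete_loss_floor,
                 permutations = as.integer(permutations),
                 rng_seed = as.integer(rng_seed),
                 em_max_iter = as.integer(em_max_iter),
                 em_tol = em_tol,
                 em_seeds = as.integer(em_seeds)),
            class = "lofscape_config")
}

#' @export
print.lofscape_config <- function(x, ...) {
  cat("lofscape analysis configuration\n")
  cat("  coding length L:", x$coding_length_L, "bp\n")
  cat("  active alleles: ", paste(x$active_allele_set, collapse = ", "), "\n")
  cat("  thresholds: major >", x$threshold_major,
      "% change; loss <", x$threshold_loss,
      "%; retained >", x$threshold_retained,
      "%; complete-loss floor <=", x$complete_loss_floor, "%\n")
  cat("  permutations:", x$permutations, " seed:", x$rng_seed, "\n")
  invisible(x)
}
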