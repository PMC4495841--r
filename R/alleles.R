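#' Name a haplotype as a star allele
#'
#' Exact-match lookup of a variant set against the allele definition table.
#' A haplotype matching no defined allele is returned as \code{"novel"}
#' together with the nearest defined allele by minimum symmetric set
#' difference.
#'
#' @param hap character vector of variant ids (empty vector = reference), or
#'   a comma-joined haplotype key as produced by the phasing module.
#' @param alleles allele definition table from [read_allele_definitions()]
#'   or \code{oct1_fixtures()$alleles}.
#' @return list: \code{allele} (name or "novel"), \code{nearest} (name, NA
#'   when matched), \code{distance} (symmetric difference size to nearest).
#' @export
name_haplotype <- function(hap, alleles) {
  if (length(hap) == 1L && is.character(hap) &&
      (grepl(",", hap) || hap %in% c("", "."))) {
    hap <- hap_variants(hap)
  }
  hap <- sort(unique(hap))
  known <- !vapply(alleles$variant_set, function(v) anyNA(v), logical(1))
  keys <- vapply(alleles$variant_set[known], hap_key, character(1))
  target <- hap_key(hap)
  hit <- which(keys == target)
  if (length(hit) == 1L) {
    return(list(allele = alleles$allele[known][hit], nearest = NA_character_,
                distance = 0L))
  }
  d <- vapply(alleles$variant_set[known], function(v) {
    length(setdiff(hap, v)) + length(setdiff(v, hap))
  }, integer(1))
  best <- which.min(d)
  list(allele = "novel", nearest = alleles$allele[known][best],
       distance = d[best])
}

#' Classify star alleles from a substrate activity matrix
#'
#' Applies the activity-threshold rules to an allele-by-substrate matrix of
#' percent-of-reference uptake values:
#' \itemize{
#'   \item \emph{major} allele: more than a 50\% decrease or increase versus
#'     the reference for at least one substrate (strict inequalities);
#'     otherwise \emph{sub} (activity-neutral).
#'   \item activity mode: \emph{gain} (some substrate above 150\%, none
#'     below 50\%), \emph{loss_substrate_wide_complete} (all substrates at
#'     or below the complete-loss floor), \emph{loss_substrate_specific}
#'     (some substrate below 50\% while another is retained above 90\%),
#'     \emph{loss_substrate_wide_partial} (the remaining losses), or
#'     \emph{normal}.
#'   \item \code{active_for_phenotype}: an allele keeps full phenotype
#'     activity unless its uptake drops below 35\% of reference (a more
#'     than 65\% reduction) for at least one substrate. Alleles named in
#'     \code{config$active_allele_set} are active by configuration.
#' }
#' Alleles defined as sub-alleles in \code{alleles} inherit the activity
#' mode and phenotype activity of their parent major allele.
#'
#' @param activity numeric matrix from [read_activity_matrix()].
#' @param config an [analysis_config()].
#' @param alleles optional allele definition table used to classify
#'   sub-alleles by inheritance and flag composition-unknown alleles.
#' @return data.frame: allele, category, activity_mode,
#'   active_for_phenotype, min_activity, max_activity.
#' @export
classify_alleles <- function(activity, config = analysis_config(),
                             alleles = NULL) {
  lo <- 100 - config$threshold_major   # 50 by default
  hi <- 100 + config$threshold_major   # 150
  res <- lapply(rownames(activity), function(a) {
    v <- activity[a, ]
    major <- any(v < lo) || any(v > hi)
    mode <- if (all(v <= config$complete_loss_floor)) {
      "loss_substrate_wide_complete"
    } else if (any(v > hi) && !any(v < lo)) {
      "gain"
    } else if (any(v < lo) && any(v > config$threshold_retained)) {
      "loss_substrate_specific"
    } else if (any(v < lo)) {
      "loss_substrate_wide_partial"
    } else {
      "normal"
    }
    active <- a %in% config$active_allele_set || !any(v < config$threshold_loss)
    data.frame(allele = a,
               category = if (identical(a, "*1")) "reference"
                          else if (major) "major" else "sub",
               activity_mode = if (identical(a, "*1")) "normal" else mode,
               active_for_phenotype = if (identical(a, "*1")) TRUE else active,
               min_activity = min(v), max_activity = max(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(alleles)) {
    subs <- alleles[alleles$category == "sub", , drop = FALSE]
    extra <- subs[!subs$allele %in% out$allele, , drop = FALSE]
    if (nrow(extra) > 0L) {
      parent_rows <- match(extra$parent, out$allele)
      if (anyNA(parent_rows)) {
        stop("sub-alleles with parents missing from the activity matrix: ",
             paste(extra$allele[is.na(parent_rows)], collapse = ", "))
      }
      inherited <- out[parent_rows, , drop = FALSE]
      inherited$allele <- extra$allele
      inherited$category <- "sub"
      out <- rbind(out, inherited)
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify amino-acid variants as LOF / non-LOF
#'
#' A variant is loss-of-function (LOF) when a single-variant allele carrying
#' it shows more than a 50\% reduction of activity for at least one
#' substrate; otherwise it is non-LOF. Variants never observed alone (only
#' in combination with another functional variant) cannot be classified from
#' the allele matrix and must carry an override in the variant table
#' (\code{functional_override}); with the packaged fixtures those are
#' Cys88Arg, Arg206Cys and Gly465Arg, which travel with Met420del, plus the
#' activity-neutral variants that only appear on sub-alleles.
#'
#' @param activity allele-by-substrate matrix.
#' @param alleles allele definition table.
#' @param variants variant table with optional \code{functional_override}.
#' @param config an [analysis_config()].
#' @return data.frame: variant_id, functional_class (LOF / non_LOF /
#'   unknown), source ("measured" or "override").
#' @export
classify_variants <- function(activity, alleles, variants,
                              config = analysis_config()) {
  if (nrow(activity) == 0L) stop("empty activity matrix")
  lo <- 100 - config$threshold_major
  single <- alleles[vapply(alleles$variant_set,
                           function(v) !anyNA(v) && length(v) == 1L,
                           logical(1)), , drop = FALSE]
  res <- lapply(variants$variant_id, function(vid) {
    ov <- variants$functional_override[variants$variant_id == vid]
    row <- single$allele[vapply(single$variant_set, function(v) v == vid,
                                logical(1))]
    row <- row[row %in% rownames(activity)]
    if (length(row) >= 1L) {
      v <- activity[row[1], ]
      cls <- if (any(v < lo)) "LOF" else "non_LOF"
      return(data.frame(variant_id = vid, functional_class = cls,
                        source = "measured", stringsAsFactors = FALSE))
    }
    if (length(ov) == 1L && !is.na(ov)) {
      return(data.frame(variant_id = vid, functional_class = ov,
                        source = "override", stringsAsFactors = FALSE))
    }
    data.frame(variant_id = vid, functional_class = "unknown",
               source = "unattributable", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  # variants that occur on a defined allele but could not be classified are
  # a hard error: their stratum assignment would be silently wrong
  on_alleles <- unique(unlist(alleles$variant_set[!vapply(alleles$variant_set,
                                                          anyNA, logical(1))]))
  bad <- out$variant_id[out$functional_class == "unknown" &
                          out$variant_id %in% on_alleles]
  if (length(bad) > 0L) {
    stop("variants observed only in combination and lacking an override: ",
         paste(bad, collapse = ", "))
  }
  out
}

#' Score diplotypes as 0/1/2 active alleles
#'
#' Counts, per individual, how many of the two carried star alleles are in
#' the fully active set, and tabulates the per-population distribution of
#' carriers of two, one and zero active alleles.
#'
#' @param diplotypes data.frame with columns sample_id, population, allele1,
#'   allele2 (star-allele names; "novel" allowed).
#' @param classification output of [classify_alleles()].
#' @param novel_active how to score alleles absent from the classification
#'   (including "novel"): FALSE (default) scores them inactive.
#' @return list: \code{calls} (per-sample n_active plus a flag for novel
#'   alleles), \code{distribution} (population x counts of 2/1/0 active,
#'   with frequencies).
#' @export
score_phenotypes <- function(diplotypes, classification, novel_active = FALSE) {
  act <- setNames(classification$active_for_phenotype, classification$allele)
  score1 <- function(a) {
    known <- a %in% names(act)
    ifelse(known, unname(act[a]), novel_active)
  }
  n_active <- as.integer(score1(diplotypes$allele1)) +
    as.integer(score1(diplotypes$allele2))
  calls <- data.frame(sample_id = diplotypes$sample_id,
                      population = diplotypes$population,
                      allele1 = diplotypes$allele1,
                      allele2 = diplotypes$allele2,
                      n_active = n_active,
                      novel = !(diplotypes$allele1 %in% names(act)) |
                        !(diplotypes$allele2 %in% names(act)),
                      stringsAsFactors = FALSE)
  tab <- table(factor(calls$population, levels = unique(calls$population)),
               factor(calls$n_active, levels = 2:0))
  dist <- data.frame(population = rownames(tab),
                     two_active = as.integer(tab[, "2"]),
                     one_active = as.integer(tab[, "1"]),
                     zero_active = as.integer(tab[, "0"]),
                     stringsAsFactors = FALSE)
  dist$n <- dist$two_active + dist$one_active + dist$zero_active
  dist$p_two <- dist$two_active / dist$n
  dist$p_one <- dist$one_active / dist$n
  dist$p_zero <- dist$zero_active / dist$n
  list(calls = calls, distribution = dist)
}
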