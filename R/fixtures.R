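#' Packaged worldwide OCT1 fixtures
#'
#' Loads the tables that ship with the package: the worldwide population
#' panel (67 populations: 53 from the enriched HGDP-CEPH collection and 14
#' from the 1000 Genomes Project; 2,171 individuals, 4,342 chromosomes), the
#' per-population star-allele counts reconstructed from the published
#' worldwide frequency table, the star-allele definitions (16 major alleles
#' plus 14 sub-alleles), the amino-acid variant table, and the allele-by-
#' substrate activity matrix.
#'
#' The allele counts are integer chromosome counts recovered from printed
#' percentages; each population row sums exactly to its chromosome total.
#' The activity matrix is figure-derived and approximate: values were read
#' from published bar charts, so they carry a provenance flag rather than a
#' claim of assay precision. The sub-allele variant compositions and the
#' per-region frequencies of the activity-neutral variants
#' (\code{nonlof_freqs}) are synthetic reconstructions calibrated against
#' the published per-region diversity summaries; they are clearly marked as
#' such and live in files with a \code{_synthetic} suffix.
#'
#' @param check if TRUE (default), validate internal consistency (row sums,
#'   population totals, allele counts) and fail hard on mismatch.
#' @return A list with elements \code{panel}, \code{allele_counts} (long
#'   format: population, allele, count), \code{allele_freqs} (wide matrix of
#'   within-population frequencies), \code{alleles} (allele definitions),
#'   \code{variants}, \code{activity} (matrix, alleles x substrates),
#'   \code{nonlof_freqs}.
#' @export
#' @examples
#' fx <- oct1_fixtures()
#' nrow(fx$panel)  # 67 populations
oct1_fixtures <- function(check = TRUE) {
  ext <- function(f) system.file("extdata", f, package = "lofscape", mustWork = TRUE)
  panel <- read_population_panel(ext("population_panel.tsv"))
  counts_wide <- read.delim(ext("table1_allele_counts.tsv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  alleles <- read_allele_definitions(ext("allele_definitions.tsv"))
  variants <- read.delim(ext("variant_table.tsv"), stringsAsFactors = FALSE,
                         na.strings = "NA")
  activity <- read_activity_matrix(ext("activity_matrix_figure_derived.tsv"))
  nonlof <- read.delim(ext("nonlof_region_freqs_synthetic.tsv"),
                       check.names = FALSE, stringsAsFactors = FALSE)

  allele_names <- setdiff(colnames(counts_wide), "population")
  cmat <- as.matrix(counts_wide[, allele_names])
  rownames(cmat) <- counts_wide$population

  if (check) {
    stopifnot(identical(panel$population, counts_wide$population))
    rs <- rowSums(cmat)
    bad <- which(rs != panel$n_chromosomes)
    if (length(bad) > 0L) {
      stop("allele counts do not sum to chromosome totals for: ",
           paste(panel$population[bad], collapse = ", "))
    }
    if (nrow(panel) != 67L) stop("expected 67 populations, got ", nrow(panel))
    if (sum(panel$n_individuals) != 2171L) stop("individual total mismatch")
    if (sum(panel$n_chromosomes) != 4342L) stop("chromosome total mismatch")
    if (sum(alleles$category == "major") + sum(alleles$category %in%
        c("reference", "unknown")) != 16L) stop("expected 16 major alleles")
    if (sum(alleles$category == "sub") != 14L) stop("expected 14 sub-alleles")
  }

  counts_long <- data.frame(
    population = rep(counts_wide$population, times = length(allele_names)),
    allele = rep(allele_names, each = nrow(counts_wide)),
    count = as.vector(cmat),
    stringsAsFactors = FALSE
  )
  freqs <- sweep(cmat, 1, panel$n_chromosomes, "/")

  list(panel = panel, allele_counts = counts_long, allele_freqs = freqs,
       alleles = alleles, variants = variants, activity = activity,
       nonlof_freqs = nonlof)
}

#' Star-allele definitions as variant sets
#'
#' @param path TSV with columns allele, variants (comma-separated variant
#'   ids, empty for the reference allele, NA for composition-unknown
#'   alleles), parent, category.
#' @return data.frame with a list-column \code{variant_set}.
#' @export
read_allele_definitions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (anyDuplicated(df$allele)) stop("duplicate allele names in ", path)
  df$variants[is.na(df$variants) & df$category != "unknown"] <- ""
  df$variant_set <- lapply(seq_len(nrow(df)), function(i) {
    v <- df$variants[i]
    if (is.na(v)) return(NA_character_)  # composition unknown (e.g. *16)
    if (!nzchar(v)) return(character(0))
    sort(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  ref <- df$variant_set[df$category == "reference"]
  if (length(ref) != 1L || length(ref[[1]]) != 0L) {
    stop("exactly one reference allele with an empty variant set is required")
  }
  df
}

#' Read a population panel file
#'
#' @param path TSV with columns population, region, n_individuals,
#'   n_chromosomes, admixed, source.
#' @export
read_population_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "region", "n_individuals", "n_chromosomes",
            "admixed", "source")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("panel file missing columns: ", paste(miss, collapse = ", "))
  df$admixed <- as.logical(df$admixed)
  if (any(df$n_chromosomes != 2L * df$n_individuals)) {
    stop("n_chromosomes must equal 2 * n_individuals")
  }
  if (any(df$n_chromosomes <= 0L)) stop("empty population in panel")
  df
}

#' Read an allele-by-substrate activity matrix
#'
#' Values are percent of the reference (*1) uptake. The reference row must
#' be identically 100.
#'
#' @param path TSV with column \code{allele} then one column per substrate.
#' @param reference name of the reference allele (default "*1").
#' @return numeric matrix, rows alleles, columns substrates.
#' @export
read_activity_matrix <- function(path, reference = "*1") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), "allele"), drop = FALSE])
  rownames(m) <- df$allele
  if (!reference %in% rownames(m)) {
    stop("activity matrix lacks the reference row ", reference)
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop("missing activity for ", rownames(m)[idx[1, 1]], " / ",
         colnames(m)[idx[1, 2]])
  }
  if (any(m[reference, ] != 100)) {
    stop("reference allele row must be identically 100")
  }
  if (any(m < 0)) stop("negative activity values")
  m
}
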