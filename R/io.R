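#' Construct a genotype panel
#'
#' A genotype panel holds unphased diploid genotypes for a set of samples:
#' per sample and per coding variant the number of alternate copies carried
#' (0, 1 or 2), plus the population each sample belongs to.
#'
#' @param sample_id character vector of sample identifiers.
#' @param population character vector, one population per sample.
#' @param genotypes integer matrix (samples x variants) with entries in
#'   \{0, 1, 2\}; column names are variant ids.
#' @param panel optional population panel data.frame; when supplied, every
#'   sample's population must appear in it.
#' @return object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(sample_id, population, genotypes, panel = NULL) {
  genotypes <- as.matrix(genotypes)
  if (length(sample_id) != nrow(genotypes) ||
      length(population) != nrow(genotypes)) {
    stop("sample_id, population and genotype rows must align")
  }
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (ncol(genotypes) > 0L && is.null(colnames(genotypes))) {
    stop("genotype columns must be named by variant id")
  }
  bad <- which(!(genotypes %in% c(0L, 1L, 2L)) | is.na(genotypes))
  if (length(bad) > 0L) {
    i <- arrayInd(bad[1], dim(genotypes))
    stop(sprintf("invalid genotype count '%s' for sample %s, variant %s",
                 genotypes[bad[1]], sample_id[i[1, 1]], colnames(genotypes)[i[1, 2]]))
  }
  storage.mode(genotypes) <- "integer"
  if (!is.null(panel)) {
    unknown <- setdiff(unique(population), panel$population)
    if (length(unknown) > 0L) {
      stop("populations absent from the panel file: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(samples = data.frame(sample_id = as.character(sample_id),
                                      population = as.character(population),
                                      stringsAsFactors = FALSE),
                 genotypes = genotypes,
                 panel = panel),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype panel:", nrow(x$genotypes), "samples (",
      2L * nrow(x$genotypes), "chromosomes ),",
      ncol(x$genotypes), "variant sites,",
      length(unique(x$samples$population)), "populations\n")
  invisible(x)
}

#' Read / write an unphased genotype table
#'
#' The on-disk format is TSV with a header \code{sample_id}, \code{population}
#' and then one column per variant id; cells are alternate-copy counts in
#' \{0, 1, 2\}. Malformed counts are a hard error naming the offending cell.
#'
#' @param path file path.
#' @param panel optional population panel for membership validation.
#' @return \code{read_genotype_table}: a \code{genotype_panel}.
#' @export
read_genotype_table <- function(path, panel = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("sample_id", "population")
  if (!all(need %in% colnames(df))) {
    stop("genotype table must start with columns sample_id, population")
  }
  vcols <- setdiff(colnames(df), need)
  if (length(vcols) == 0L) stop("genotype table has no variant columns")
  g <- suppressWarnings(vapply(df[vcols], as.numeric, numeric(nrow(df))))
  g <- matrix(g, nrow = nrow(df), dimnames = list(NULL, vcols))
  bad <- which(is.na(g) | !(g %in% c(0, 1, 2)))
  if (length(bad) > 0L) {
    i <- arrayInd(bad[1], dim(g))
    stop(sprintf("invalid genotype count '%s' for sample %s, variant %s",
                 df[[vcols[i[1, 2]]]][i[1, 1]], df$sample_id[i[1, 1]],
                 vcols[i[1, 2]]))
  }
  genotype_panel(df$sample_id, df$population, g, panel = panel)
}

#' @param x a \code{genotype_panel}.
#' @rdname read_genotype_table
#' @export
write_genotype_table <- function(x, path) {
  stopifnot(inherits(x, "genotype_panel"))
  out <- cbind(x$samples, as.data.frame(x$genotypes, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write phased haplotype assignments
#'
#' TSV with columns sample_id, population, hap1, hap2 (comma-separated
#' variant ids, empty string for the reference haplotype) and posterior.
#'
#' @param path file path.
#' @export
read_phased_haplotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  df$posterior <- as.numeric(df$posterior)
  df
}

#' @param diplotypes data.frame as returned by [assign_diplotypes()].
#' @rdname read_phased_haplotypes
#' @export
write_phased_haplotypes <- function(diplotypes, path) {
  write.table(diplotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-population covariate table
#'
#' Two-column TSV (population, value), e.g. great-circle distance to Addis
#' Ababa or the loss-of-function allele frequency of another gene.
#'
#' @param path file path.
#' @export
read_covariate_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("covariate table needs columns population, value")
  colnames(df)[1:2] <- c("population", "value")
  df$value <- as.numeric(df$value)
  df
}
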