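#' Diploid multilocus SSR genotype dataset
#'
#' The central container of the package: an individuals x loci x 2 integer
#' array of allele sizes (repeat-unit-scaled fragment lengths) together with
#' the population membership of every individual, the species assignment of
#' every population, and optional per-population geography.
#'
#' Conventions:
#' * Alleles are stored as positive integer fragment sizes exactly as
#'   genotyped; no binning to repeat numbers is attempted.
#' * Missing data use `NA` and always affect both allele slots of a locus
#'   (no half-calls); downstream statistics drop missing slots locus-wise.
#' * Species is an attribute of the population, not of the individual:
#'   individuals flagged as misassigned by the admixture analysis are never
#'   re-homed at the I/O level.
#'
#' @param alleles integer array `n_ind x n_loci x 2` of allele sizes
#'   (`NA` = missing), or a matrix `n_ind x (2*n_loci)` with the two copies
#'   of each locus in adjacent columns.
#' @param individual_ids character vector of unique individual labels.
#' @param locus_names character vector of locus labels.
#' @param pop character vector: population label of each individual.
#' @param species_of_pop named character vector mapping population label to
#'   species label, or `NULL` to treat every population as one species.
#' @param geography optional data frame with columns `population`,
#'   `latitude`, `longitude`, `altitude` (and optionally `species`).
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(alleles, individual_ids = NULL, locus_names = NULL,
                             pop, species_of_pop = NULL, geography = NULL) {
  if (is.matrix(alleles)) {
    stopifnot(ncol(alleles) %% 2 == 0)
    L <- ncol(alleles) / 2L
    arr <- array(NA_integer_, dim = c(nrow(alleles), L, 2L))
    arr[, , 1L] <- alleles[, 2L * seq_len(L) - 1L, drop = FALSE]
    arr[, , 2L] <- alleles[, 2L * seq_len(L), drop = FALSE]
    alleles <- arr
  }
  stopifnot(length(dim(alleles)) == 3L, dim(alleles)[3] == 2L)
  storage.mode(alleles) <- "integer"
  n <- dim(alleles)[1]
  L <- dim(alleles)[2]
  if (is.null(individual_ids))
    individual_ids <- if (n == 0) character(0) else paste0("ind_", seq_len(n))
  if (is.null(locus_names)) locus_names <- paste0("locus_", seq_len(L))
  pop <- as.character(pop)
  stopifnot(length(individual_ids) == n, length(locus_names) == L,
            length(pop) == n, !anyDuplicated(individual_ids))
  if (is.null(species_of_pop)) {
    species_of_pop <- stats::setNames(rep("sp1", length(unique(pop))), unique(pop))
  }
  obj <- structure(
    list(alleles = alleles,
         individual_ids = as.character(individual_ids),
         locus_names = as.character(locus_names),
         pop = pop,
         species_of_pop = species_of_pop,
         geography = geography),
    class = "genotype_dataset")
  validate_genotypes(obj)
  obj
}

#' Validate the structural invariants of a genotype dataset
#'
#' Checks that every individual belongs to a known population, every
#' population to exactly one species, that allele sizes are positive
#' integers, and that missingness is consistent across the two allele slots
#' of a locus.
#'
#' @param x a `genotype_dataset`.
#' @return `x`, invisibly; stops with an informative error on violation.
#' @export
validate_genotypes <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  pops <- unique(x$pop)
  missing_pops <- setdiff(pops, names(x$species_of_pop))
  if (length(missing_pops) > 0)
    stop("populations without species assignment: ",
         paste(missing_pops, collapse = ", "))
  a1 <- x$alleles[, , 1, drop = FALSE]
  a2 <- x$alleles[, , 2, drop = FALSE]
  if (any(is.na(a1) != is.na(a2)))
    stop("half-called genotypes: the two allele slots of a locus must be ",
         "missing together or present together")
  vals <- x$alleles[!is.na(x$alleles)]
  if (length(vals) > 0 && any(vals <= 0))
    stop("allele sizes must be positive integers")
  if (!is.null(x$geography)) {
    need <- c("population", "latitude", "longitude", "altitude")
    if (!all(need %in% names(x$geography)))
      stop("geography table must have columns: ", paste(need, collapse = ", "))
    absent <- setdiff(pops, x$geography$population)
    if (length(absent) > 0)
      stop("populations absent from geography table: ",
           paste(absent, collapse = ", "))
  }
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  sp <- x$species_of_pop[unique(x$pop)]
  cat("genotype_dataset:", n_individuals(x), "individuals,",
      n_loci(x), "loci,", length(unique(x$pop)), "populations,",
      length(unique(sp)), "species\n")
  miss <- mean(is.na(x$alleles[, , 1]))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_dataset
#' @param x a `genotype_dataset`.
#' @export
n_individuals <- function(x) dim(x$alleles)[1]

#' @rdname genotype_dataset
#' @export
n_loci <- function(x) dim(x$alleles)[2]

#' Species label of each individual
#' @param x a `genotype_dataset`.
#' @return character vector of length `n_individuals(x)`.
#' @export
species_of_individual <- function(x) unname(x$species_of_pop[x$pop])

#' Subset a genotype dataset by individuals
#' @param x a `genotype_dataset`.
#' @param keep logical or integer index over individuals.
#' @return a `genotype_dataset` restricted to the selected individuals.
#' @export
subset_individuals <- function(x, keep) {
  genotype_dataset(x$alleles[keep, , , drop = FALSE],
                   individual_ids = x$individual_ids[keep],
                   locus_names = x$locus_names,
                   pop = x$pop[keep],
                   species_of_pop = x$species_of_pop,
                   geography = x$geography)
}

#' Attach per-population geography metadata to a dataset
#'
#' Joins a metadata table (as returned by [read_metadata_csv()]) onto a
#' dataset by population label. If the metadata carries a `species` column it
#' overrides `species_of_pop`.
#'
#' @param x a `genotype_dataset`.
#' @param meta data frame with columns `population`, `species`, `latitude`,
#'   `longitude`, `altitude`.
#' @return the dataset with geography (and species map) filled in.
#' @export
attach_metadata <- function(x, meta) {
  absent <- setdiff(unique(x$pop), meta$population)
  if (length(absent) > 0)
    stop("populations missing from metadata: ", paste(absent, collapse = ", "))
  if ("species" %in% names(meta))
    x$species_of_pop <- stats::setNames(as.character(meta$species),
                                        as.character(meta$population))
  x$geography <- meta
  validate_genotypes(x)
  x
}
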