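#' Assemble a diploid cohort
#'
#' Bundles the variant sites, sample ids, genotype matrices and region of a
#' cohort into one validated object. Genotypes are stored as two integer
#' matrices of allele indices (0 = REF, 1 = first ALT, ...), one per
#' chromosome slot of the diploid call; `NA` marks a missing call. The
#' phase matrix records whether the VCF used `|` separators but is never
#' consulted by the algorithm.
#'
#' @param sites Tibble of variant sites with columns `pos` (1-based position
#'   of the first REF base), `id`, `ref`, `alts` (list column of character
#'   vectors) and `end` (footprint end, `pos + nchar(ref) - 1`). Must be
#'   strictly ascending in `pos`.
#' @param samples Character vector of sample ids (row order of the matrices).
#' @param geno_a,geno_b Integer matrices, samples x sites.
#' @param phased Optional logical matrix of the same shape.
#' @param region [genomic_interval()] the cohort covers; every site footprint
#'   must lie within it.
#' @param reference Optional nucleotide string of exactly the region length.
#'
#' @return An object of class `hap_cohort`.
#' @export
hap_cohort <- function(sites, samples, geno_a, geno_b, phased = NULL,
                       region, reference = NULL) {
  stopifnot(inherits(region, "genomic_interval"))
  sites <- as_tibble(sites)
  needed <- c("pos", "id", "ref", "alts", "end")
  if (!all(needed %in% names(sites))) {
    stop("`sites` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  n_sites <- nrow(sites)
  if (n_sites > 1 && any(diff(sites$pos) <= 0)) {
    stop("site positions must be strictly ascending", call. = FALSE)
  }
  if (n_sites > 0) {
    if (any(sites$end != sites$pos + nchar(sites$ref) - 1)) {
      stop("site footprint ends inconsistent with REF lengths", call. = FALSE)
    }
    bad <- sites$pos < region$start | sites$end > region$end
    if (any(bad)) {
      stop("site footprint outside the region at position ",
           sites$pos[which(bad)[1]], call. = FALSE)
    }
  }
  geno_a <- as.matrix(geno_a)
  geno_b <- as.matrix(geno_b)
  if (!identical(dim(geno_a), c(length(samples), n_sites)) ||
      !identical(dim(geno_b), c(length(samples), n_sites))) {
    # allow 0-col matrices created loosely
    if (!(nrow(geno_a) == length(samples) && ncol(geno_a) == n_sites &&
          nrow(geno_b) == length(samples) && ncol(geno_b) == n_sites)) {
      stop("genotype matrices must be |samples| x |sites|", call. = FALSE)
    }
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (!is.null(reference)) {
    reference <- toupper(reference)
    if (nchar(reference) != interval_length(region)) {
      stop("reference length (", nchar(reference),
           ") must equal region length (", interval_length(region), ")",
           call. = FALSE)
    }
  }
  structure(
    list(sites = sites, samples = as.character(samples),
         geno_a = geno_a, geno_b = geno_b,
         phased = phased, region = region, reference = reference),
    class = "hap_cohort"
  )
}

#' @export
print.hap_cohort <- function(x, ...) {
  cat("<hap_cohort> ", length(x$samples), " samples x ", nrow(x$sites),
      " sites over ", format(x$region),
      if (is.null(x$reference)) "  (no reference attached)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Attach a reference window to a cohort
#'
#' @param cohort A [hap_cohort()].
#' @param reference Nucleotide string of exactly the region length (e.g. from
#'   [read_reference_window()]).
#' @return The cohort with `$reference` set.
#' @export
set_reference <- function(cohort, reference) {
  stopifnot(inherits(cohort, "hap_cohort"))
  hap_cohort(cohort$sites, cohort$samples, cohort$geno_a, cohort$geno_b,
             cohort$phased, cohort$region, reference)
}

# logical vector: does each site's footprint overlap interval `iv`?
site_overlaps <- function(sites, iv) {
  if (nrow(sites) == 0) return(logical(0))
  sites$pos <= iv$end & sites$end >= iv$start
}

# samples x sites logical heterozygosity matrix under the missing policy
het_matrix <- function(cohort, missing_as_het = TRUE) {
  h <- cohort$geno_a != cohort$geno_b
  if (missing_as_het) {
    h[is.na(h)] <- TRUE
  } else {
    h[is.na(h)] <- FALSE
  }
  h
}

#' Count heterozygous sites per sample within an interval
#'
#' Counts, for every sample, the variant sites whose REF footprint overlaps
#' `iv` and whose genotype is heterozygous. Missing genotypes count as
#' heterozygous by default (ambiguity is treated conservatively).
#'
#' @param cohort A [hap_cohort()].
#' @param iv A [genomic_interval()] inside the cohort region.
#' @param missing_as_het Should missing calls count as heterozygous?
#' @return A tibble with columns `sample` and `n_het`, in cohort order.
#' @export
het_counts <- function(cohort, iv, missing_as_het = TRUE) {
  stopifnot(inherits(cohort, "hap_cohort"), inherits(iv, "genomic_interval"))
  keep <- site_overlaps(cohort$sites, iv)
  h <- het_matrix(cohort, missing_as_het)
  n <- if (any(keep)) rowSums(h[, keep, drop = FALSE]) else
    rep(0L, length(cohort$samples))
  tibble(sample = cohort$samples, n_het = as.integer(n))
}

#' Count variant records overlapping a gene
#'
#' Number of retained variant records whose REF footprint overlaps the gene
#' interval (the "how many SNVs does the callset actually see in this gene"
#' figure).
#'
#' @param sites Site tibble (as held in a [hap_cohort()]).
#' @param gene A [genomic_interval()].
#' @return Integer count.
#' @export
count_gene_variants <- function(sites, gene) {
  if (inherits(sites, "hap_cohort")) sites <- sites$sites
  sum(site_overlaps(sites, gene))
}
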