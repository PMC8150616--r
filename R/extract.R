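#' Samples qualifying for unambiguous haplotype assignment
#'
#' A diploid sample qualifies when it is heterozygous at no more than one
#' variant site overlapping the focal gene: both of its chromosomes then
#' carry a haplotype that can be read directly from the genotypes, without
#' any phase inference. A sample whose single permitted "heterozygous"
#' in-gene site is actually a missing call is disqualified — its alleles
#' cannot be assigned unambiguously.
#'
#' @param cohort A [hap_cohort()].
#' @param gene [genomic_interval()] of the focal gene, within the region.
#' @param missing_as_het Should missing calls count as heterozygous for
#'   qualification and extension? Default `TRUE` (conservative).
#' @return Character vector of qualifying sample ids, in cohort order.
#' @export
qualifying_samples <- function(cohort, gene, missing_as_het = TRUE) {
  stopifnot(inherits(cohort, "hap_cohort"), inherits(gene, "genomic_interval"))
  if (!iv_contains(cohort$region, gene)) {
    stop("gene interval must lie within the cohort region", call. = FALSE)
  }
  q <- qualification_flags(cohort, gene, missing_as_het)
  cohort$samples[q]
}

# logical vector over samples; shared by the fast path
qualification_flags <- function(cohort, gene, missing_as_het = TRUE) {
  h <- het_matrix(cohort, missing_as_het)
  in_gene <- site_overlaps(cohort$sites, gene)
  n_in <- if (any(in_gene)) rowSums(h[, in_gene, drop = FALSE]) else
    rep(0L, length(cohort$samples))
  ok <- n_in <= 1
  if (missing_as_het && any(in_gene)) {
    # single "het" that is a missing call -> alleles unassignable
    miss <- is.na(cohort$geno_a) | is.na(cohort$geno_b)
    one_missing <- n_in == 1 &
      rowSums((h & miss)[, in_gene, drop = FALSE]) == 1
    ok <- ok & !one_missing
  }
  ok
}

#' Maximal unambiguous span for one sample
#'
#' Extends the gene interval in both the 5' and 3' directions until a
#' heterozygous variant is encountered; the span stops just inside the full
#' REF footprint of each terminating variant ("the region between two
#' SNVs"). With no flanking heterozygous variant on a side, the span runs to
#' the region boundary.
#'
#' @inheritParams qualifying_samples
#' @param sample A qualifying sample id.
#' @return The span as a [genomic_interval()].
#' @export
extend_span <- function(cohort, sample, gene, missing_as_het = TRUE) {
  stopifnot(inherits(cohort, "hap_cohort"))
  i <- match(sample, cohort$samples)
  if (is.na(i)) stop("sample not in cohort: ", sample, call. = FALSE)
  h <- het_matrix(cohort, missing_as_het)[i, ]
  sp <- span_limits(h, cohort$sites, gene, cohort$region)
  genomic_interval(cohort$region$contig, sp[1], sp[2])
}

# core extension rule: het flags for one sample -> c(L, R)
span_limits <- function(het, sites, gene, region) {
  left <- sites$end < gene$start   # footprint entirely 5' of the gene
  right <- sites$pos > gene$end    # footprint entirely 3' of the gene
  L <- if (any(het & left)) max(sites$end[het & left]) + 1 else region$start
  R <- if (any(het & right)) min(sites$pos[het & right]) - 1 else region$end
  c(L, R)
}

#' Extract haplotype observations from a cohort
#'
#' The core of the method. Every qualifying sample (see
#' [qualifying_samples()]) contributes exactly two chromosome observations
#' over its maximal unambiguous span: for a fully homozygous sample the two
#' are identical; for a sample heterozygous at a single in-gene site they
#' differ only there (one carries each allele). Sites whose REF footprint
#' lies within the span make up the observation's allele vector.
#'
#' @inheritParams qualifying_samples
#' @return A tibble of class `hap_observations`, samples in cohort order and
#'   chromosome 0 before 1, with columns `sample`, `chromosome`, `contig`,
#'   `start`, `end`, `site_idx` (list of row indices into `cohort$sites`)
#'   and `alleles` (list of integer allele indices).
#' @export
extract_observations <- function(cohort, gene, missing_as_het = TRUE) {
  stopifnot(inherits(cohort, "hap_cohort"), inherits(gene, "genomic_interval"))
  if (!iv_contains(cohort$region, gene)) {
    stop("gene interval must lie within the cohort region", call. = FALSE)
  }
  hmat <- het_matrix(cohort, missing_as_het)
  ok <- qualification_flags(cohort, gene, missing_as_het)
  sites <- cohort$sites
  region <- cohort$region

  out <- vector("list", sum(ok))
  k <- 0L
  for (i in which(ok)) {
    sp <- span_limits(hmat[i, ], sites, gene, region)
    in_span <- which(sites$pos >= sp[1] & sites$end <= sp[2])
    a <- cohort$geno_a[i, in_span]
    b <- cohort$geno_b[i, in_span]
    k <- k + 1L
    out[[k]] <- tibble(
      sample = cohort$samples[i],
      chromosome = c(0L, 1L),
      contig = region$contig,
      start = sp[1], end = sp[2],
      site_idx = list(in_span, in_span),
      alleles = list(as.integer(a), as.integer(b))
    )
  }
  obs <- if (k > 0) bind_rows(out) else
    tibble(sample = character(), chromosome = integer(),
           contig = character(), start = numeric(), end = numeric(),
           site_idx = list(), alleles = list())
  class(obs) <- c("hap_observations", class(obs))
  obs
}

#' Brute-force extraction oracle
#'
#' Independent re-derivation of [extract_observations()] by exhaustive
#' search, for testing: for each sample it enumerates every candidate span
#' containing the gene whose boundaries are induced by site footprints (or
#' the region limits), keeps the spans free of out-of-gene heterozygosity,
#' and returns the unique maximal one. Quadratic in the number of sites;
#' intended for small cohorts only.
#'
#' @inheritParams qualifying_samples
#' @return Same structure as [extract_observations()].
#' @export
brute_force_extract <- function(cohort, gene, missing_as_het = TRUE) {
  stopifnot(inherits(cohort, "hap_cohort"), inherits(gene, "genomic_interval"))
  sites <- cohort$sites
  region <- cohort$region
  miss <- is.na(cohort$geno_a) | is.na(cohort$geno_b)
  out <- list()
  for (i in seq_along(cohort$samples)) {
    a <- cohort$geno_a[i, ]
    b <- cohort$geno_b[i, ]
    het <- is_heterozygous(a, b)
    if (missing_as_het) het[is.na(het)] <- TRUE else het[is.na(het)] <- FALSE
    gene_ov <- site_overlaps(sites, gene)
    n_in <- sum(het & gene_ov)
    if (n_in > 1) next
    if (missing_as_het && n_in == 1 && any(het & gene_ov & miss[i, ])) next

    Ls <- unique(c(region$start, sites$end[sites$end < gene$start] + 1))
    Rs <- unique(c(region$end, sites$pos[sites$pos > gene$end] - 1))
    Ls <- Ls[Ls >= region$start & Ls <= gene$start]
    Rs <- Rs[Rs <= region$end & Rs >= gene$end]
    best <- NULL
    for (L in Ls) for (R in Rs) {
      # a span is valid iff no het site outside the gene touches it
      offending <- het & !gene_ov & sites$pos <= R & sites$end >= L
      if (!any(offending)) {
        if (is.null(best) || (R - L) > (best[2] - best[1])) best <- c(L, R)
      }
    }
    in_span <- which(sites$pos >= best[1] & sites$end <= best[2])
    out[[length(out) + 1L]] <- tibble(
      sample = cohort$samples[i],
      chromosome = c(0L, 1L),
      contig = region$contig,
      start = best[1], end = best[2],
      site_idx = list(in_span, in_span),
      alleles = list(as.integer(a[in_span]), as.integer(b[in_span]))
    )
  }
  obs <- if (length(out) > 0) bind_rows(out) else
    tibble(sample = character(), chromosome = integer(),
           contig = character(), start = numeric(), end = numeric(),
           site_idx = list(), alleles = list())
  class(obs) <- c("hap_observations", class(obs))
  obs
}
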