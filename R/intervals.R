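#' Genomic intervals, 1-based and inclusive
#'
#' All coordinates in this package follow the VCF convention: 1-based,
#' inclusive at both ends, so an interval of a single base has
#' `start == end` and length 1. Any half-open bookkeeping is confined to
#' file readers.
#'
#' @param contig Contig (chromosome or simulated sequence) name.
#' @param start,end First and last base of the interval, 1-based inclusive.
#'   `start` must be at least 1 and `end` at least `start`.
#'
#' @return An object of class `genomic_interval`: a named list with fields
#'   `contig`, `start` and `end`.
#' @examples
#' gene <- genomic_interval("NC_000001.11", 159204875, 159206500)
#' interval_length(gene) # 1626
#' @export
genomic_interval <- function(contig, start, end) {
  if (!is.character(contig) || length(contig) != 1L || is.na(contig) ||
      !nzchar(contig)) {
    stop("`contig` must be a single non-empty string", call. = FALSE)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("`start` and `end` must be single numbers", call. = FALSE)
  }
  if (start < 1) {
    stop("interval start must be >= 1 (coordinates are 1-based)", call. = FALSE)
  }
  if (end < start) {
    stop("interval end (", end, ") must be >= start (", start, ")",
         call. = FALSE)
  }
  structure(list(contig = contig, start = start, end = end),
            class = "genomic_interval")
}

#' Parse a region string
#'
#' Accepts the usual `contig:start-end` notation, with optional thousands
#' separators (commas) in the coordinates, e.g.
#' `"NC_000001.11:159,203,314-159,283,887"`.
#'
#' @param x A single region string.
#' @return A [genomic_interval()].
#' @export
parse_region <- function(x) {
  if (!is.character(x) || length(x) != 1L) {
    stop("`x` must be a single string like \"chr1:100-200\"", call. = FALSE)
  }
  m <- regmatches(x, regexec("^(.+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) {
    stop("cannot parse region string: ", x, call. = FALSE)
  }
  genomic_interval(m[2],
                   as.numeric(gsub(",", "", m[3], fixed = TRUE)),
                   as.numeric(gsub(",", "", m[4], fixed = TRUE)))
}

#' Length of a genomic interval in nucleotides
#'
#' @param iv A [genomic_interval()].
#' @return `end - start + 1`.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%s-%s", x$contig,
          format(x$start, big.mark = ",", scientific = FALSE, trim = TRUE),
          format(x$end, big.mark = ",", scientific = FALSE, trim = TRUE))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval> ", format(x), "  (",
      format(interval_length(x), big.mark = ",", trim = TRUE), " nt)\n",
      sep = "")
  invisible(x)
}

# does `inner` lie entirely within `outer`? (same contig assumed checked upstream)
iv_contains <- function(outer, inner) {
  inner$start >= outer$start && inner$end <= outer$end
}

#' Heterozygosity of a diploid genotype
#'
#' A genotype is heterozygous when its two allele indices differ; the phase
#' flag is irrelevant (that independence is the whole point of the method).
#' Missing calls are a third state and return `NA`, not `TRUE` or `FALSE`.
#'
#' @param allele_a,allele_b Integer allele indices (0 = REF), vectorised;
#'   `NA` marks a missing call.
#' @return Logical vector: `TRUE` (het), `FALSE` (hom) or `NA` (missing).
#' @examples
#' is_heterozygous(c(0, 0, 1, NA), c(0, 1, 1, 0))
#' @export
is_heterozygous <- function(allele_a, allele_b) {
  ifelse(is.na(allele_a) | is.na(allele_b), NA, allele_a != allele_b)
}
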