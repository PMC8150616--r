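#' Materialise haplotype observations as nucleotide sequences
#'
#' Splices each observation's alleles into the reference window: reference
#' bases are copied between variant footprints and each variant's chosen
#' allele string is substituted in place of its REF. The reported haplotype
#' length is the length of the realised sequence, which differs from the
#' span width exactly by the summed indel length differences — insertions
#' can make a haplotype longer than the region it sits in.
#'
#' Every record's REF field is checked against the reference window; a
#' mismatch is a hard error naming the position (it means the VCF and FASTA
#' disagree).
#'
#' @param cohort A [hap_cohort()] with a reference attached
#'   (see [set_reference()]).
#' @param obs Observations from [extract_observations()].
#' @return `obs` with `sequence` and `length` columns added.
#' @export
build_sequences <- function(cohort, obs) {
  stopifnot(inherits(cohort, "hap_cohort"))
  if (is.null(cohort$reference)) {
    stop("cohort has no reference attached; see set_reference()",
         call. = FALSE)
  }
  seqs <- pmap(list(obs$start, obs$end, obs$site_idx, obs$alleles),
               function(start, end, idx, al) {
                 splice_alleles(cohort$reference, cohort$region,
                                cohort$sites, start, end, idx, al)
               })
  obs$sequence <- map_chr(seqs, identity)
  obs$length <- nchar(obs$sequence)
  obs
}

# splice chosen allele strings over [start, end] of the reference window
splice_alleles <- function(reference, region, sites, start, end, idx, alleles) {
  o <- function(g) g - region$start + 1 # genomic -> window offset
  if (length(idx) == 0) {
    return(substr(reference, o(start), o(end)))
  }
  ord <- order(sites$pos[idx])
  idx <- idx[ord]
  alleles <- alleles[ord]
  pos <- sites$pos[idx]
  fp_end <- sites$end[idx]
  if (any(pos < start) || any(fp_end > end)) {
    stop("variant footprint outside the span", call. = FALSE)
  }
  if (length(idx) > 1 && any(pos[-1] <= fp_end[-length(fp_end)])) {
    stop("overlapping variant footprints at position ",
         pos[which(pos[-1] <= fp_end[-length(fp_end)])[1] + 1], call. = FALSE)
  }
  pieces <- character(2 * length(idx) + 1)
  cursor <- start
  for (j in seq_along(idx)) {
    s <- sites[idx[j], ]
    window_ref <- substr(reference, o(s$pos), o(s$end))
    if (window_ref != s$ref) {
      stop("REF mismatch at position ",
           format(s$pos, scientific = FALSE, trim = TRUE),
           ": VCF says '", s$ref, "', reference window has '", window_ref,
           "'", call. = FALSE)
    }
    allele_str <- if (alleles[j] == 0L) s$ref else s$alts[[1]][alleles[j]]
    if (is.na(allele_str)) {
      stop("allele index ", alleles[j], " out of range at position ", s$pos,
           call. = FALSE)
    }
    pieces[2 * j - 1] <- if (cursor <= s$pos - 1)
      substr(reference, o(cursor), o(s$pos - 1)) else ""
    pieces[2 * j] <- allele_str
    cursor <- s$end + 1
  }
  pieces[length(pieces)] <- if (cursor <= end)
    substr(reference, o(cursor), o(end)) else ""
  paste(pieces, collapse = "")
}

#' Stable identity key for a haplotype
#'
#' Two haplotypes are the same catalogue entry iff they cover the same span
#' and realise the same sequence; the key concatenates all three, so it is
#' injective (no collisions by construction).
#'
#' @param start,end Span limits.
#' @param sequence Realised nucleotide sequence.
#' @return Character key, vectorised.
#' @export
sequence_digest <- function(start, end, sequence) {
  paste(format(start, scientific = FALSE, trim = TRUE),
        format(end, scientific = FALSE, trim = TRUE),
        sequence, sep = ":")
}
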