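#' Read genotypes for a region from a VCF
#'
#' Loads all usable variant records overlapping `region` together with the
#' diploid genotype calls of every (or a chosen subset of) sample. Records
#' with symbolic alleles (`<CN0>`, breakends, ...) or any non-ACGT character
#' in REF/ALT are skipped and counted, not errors: population callsets
#' routinely carry structural-variant records the haplotype method cannot
#' use. Phase separators (`|` vs `/`) are parsed into a phase matrix that is
#' carried through but never consulted — the method is deliberately
#' independent of computational phasing.
#'
#' @param vcf_path Path to a VCF (plain or bgzipped).
#' @param region [genomic_interval()] to load; only records whose footprint
#'   lies entirely within it are kept.
#' @param keep_samples Optional character vector of sample ids to keep, in
#'   the order given (used to restrict to an unrelated panel).
#' @return A [hap_cohort()] (without reference attached). The number of
#'   skipped records is available as `attr(x, "n_skipped")`.
#' @export
read_genotype_region <- function(vcf_path, region, keep_samples = NULL) {
  stopifnot(inherits(region, "genomic_interval"))
  if (!file.exists(vcf_path)) {
    stop("VCF file not found: ", vcf_path, call. = FALSE)
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, 1:5, drop = FALSE], stringsAsFactors = FALSE)
  if (nrow(fix) > 0 && !any(fix$CHROM == region$contig)) {
    stop("contig '", region$contig, "' not present in ", vcf_path,
         call. = FALSE)
  }
  gt_field <- ncol(v@gt) >= 1 &&
    all(vapply(strsplit(v@gt[, 1], ":", fixed = TRUE),
               function(f) "GT" %in% f, logical(1)))
  if (nrow(fix) > 0 && (ncol(v@gt) < 2 || !gt_field)) {
    stop("VCF has no GT genotype field: ", vcf_path, call. = FALSE)
  }
  samples <- colnames(v@gt)[-1]

  pos <- as.numeric(fix$POS)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  on_contig <- fix$CHROM == region$contig
  clean <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+(,[ACGT]+)*$", alt)
  end <- pos + nchar(ref) - 1
  in_region <- pos >= region$start & end <= region$end
  keep <- on_contig & in_region & clean
  n_skipped <- sum(on_contig & in_region & !clean)
  if (n_skipped > 0) {
    message("read_genotype_region: skipped ", n_skipped,
            " record(s) with symbolic/non-ACGT alleles")
  }

  sites <- tibble(
    pos = pos[keep],
    id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".", "", fix$ID[keep]),
    ref = ref[keep],
    alts = strsplit(alt[keep], ",", fixed = TRUE),
    end = end[keep]
  )
  ord <- order(sites$pos)
  sites <- sites[ord, ]
  if (nrow(sites) > 1 && any(diff(sites$pos) <= 0)) {
    stop("VCF contains records at duplicated positions within the region",
         call. = FALSE)
  }

  if (sum(keep) > 0) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep, , drop = FALSE][ord, , drop = FALSE]
  } else {
    gt <- matrix(character(0), nrow = 0, ncol = length(samples))
  }
  gt <- t(gt) # samples x sites
  parsed <- parse_gt_matrix(gt)

  if (!is.null(keep_samples)) {
    missing <- setdiff(keep_samples, samples)
    if (length(missing) > 0) {
      stop("keep_samples not in VCF: ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    idx <- match(keep_samples, samples)
    samples <- samples[idx]
    parsed$a <- parsed$a[idx, , drop = FALSE]
    parsed$b <- parsed$b[idx, , drop = FALSE]
    parsed$phased <- parsed$phased[idx, , drop = FALSE]
  }

  cohort <- hap_cohort(sites, samples, parsed$a, parsed$b, parsed$phased,
                       region)
  attr(cohort, "n_skipped") <- n_skipped
  cohort
}

# character samples x sites GT matrix -> allele-index matrices + phase flags
parse_gt_matrix <- function(gt) {
  if (length(gt) == 0) {
    dims <- dim(gt)
    m <- matrix(NA_integer_, nrow = dims[1], ncol = dims[2])
    return(list(a = m, b = m, phased = matrix(FALSE, dims[1], dims[2])))
  }
  a_chr <- sub("[/|].*$", "", gt)
  has_sep <- grepl("[/|]", gt)
  b_chr <- ifelse(has_sep, sub("^[^/|]*[/|]", "", gt), gt)
  # anything beyond a simple second allele (e.g. triploid calls) -> missing
  a <- suppressWarnings(as.integer(a_chr))
  b <- suppressWarnings(as.integer(b_chr))
  phased <- grepl("|", gt, fixed = TRUE)
  phased[is.na(gt)] <- FALSE
  dim(a) <- dim(gt); dim(b) <- dim(gt); dim(phased) <- dim(gt)
  rownames(a) <- rownames(gt); rownames(b) <- rownames(gt)
  list(a = a, b = b, phased = phased)
}

#' Write a cohort to a VCF file
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT. Genotypes are written
#' unphased (`a/b`): the method never uses phase, and the simulator does not
#' pretend to know it.
#'
#' @param cohort A [hap_cohort()].
#' @param path Output file path.
#' @param extra_header Optional character vector of extra `##` header lines
#'   (e.g. a simulation seed stamp).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, extra_header = character()) {
  stopifnot(inherits(cohort, "hap_cohort"))
  region <- cohort$region
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=haplotract",
    extra_header,
    sprintf("##contig=<ID=%s,length=%s>", region$contig,
            format(region$end, scientific = FALSE, trim = TRUE)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  s <- cohort$sites
  rows <- character(nrow(s))
  if (nrow(s) > 0) {
    gt <- matrix(paste0(ifelse(is.na(cohort$geno_a), ".", cohort$geno_a), "/",
                        ifelse(is.na(cohort$geno_b), ".", cohort$geno_b)),
                 nrow = length(cohort$samples))
    for (j in seq_len(nrow(s))) {
      rows[j] <- paste(c(region$contig,
                         format(s$pos[j], scientific = FALSE, trim = TRUE),
                         if (nzchar(s$id[j])) s$id[j] else ".",
                         s$ref[j],
                         paste(s$alts[[j]], collapse = ","),
                         ".", "PASS", ".", "GT",
                         gt[, j]), collapse = "\t")
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
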