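# Shared fixture builders. Coordinates are 1-based inclusive throughout.

# A small cohort with explicit genotypes. `positions` places SNVs (or longer
# REF alleles via `ref`); genotype matrices are samples x sites.
toy_cohort <- function(positions, geno_a, geno_b, region_length = 100,
                       contig = "toy", ref = NULL, alts = NULL,
                       reference = NULL, seed = 99) {
  set.seed(seed)
  if (is.null(reference)) {
    reference <- paste(sample(c("A", "C", "G", "T"), region_length,
                              replace = TRUE), collapse = "")
  }
  n <- length(positions)
  if (is.null(ref)) {
    ref <- vapply(positions, function(p) substr(reference, p, p),
                  character(1))
  } else {
    for (j in seq_len(n)) {
      substr(reference, positions[j],
             positions[j] + nchar(ref[j]) - 1) <- ref[j]
    }
  }
  if (is.null(alts)) {
    # deterministic: first base (in ACGT order) differing from REF's first
    alts <- vapply(ref, function(r) {
      setdiff(c("A", "C", "G", "T"), substr(r, 1, 1))[1]
    }, character(1))
  }
  sites <- tibble::tibble(pos = positions,
                          id = paste0("s", seq_len(n)),
                          ref = ref,
                          alts = as.list(alts),
                          end = positions + nchar(ref) - 1)
  geno_a <- matrix(as.integer(geno_a), ncol = n)
  geno_b <- matrix(as.integer(geno_b), ncol = n)
  hap_cohort(sites, sprintf("T%02d", seq_len(nrow(geno_a))),
             geno_a, geno_b,
             region = genomic_interval(contig, 1, region_length),
             reference = reference)
}

# canonical comparable form of observations: one signature per chromosome
obs_signatures <- function(obs, sites) {
  sig <- purrr::map2_chr(obs$site_idx, obs$alleles, function(idx, al) {
    paste(sites$pos[idx], al, sep = "=", collapse = ";")
  })
  sort(paste(obs$start, obs$end, sig, sep = "|"))
}

# catalogue as comparable (start, end, signature, n) rows
catalogue_signatures <- function(catalogue, sites) {
  sig <- purrr::map2_chr(catalogue$site_idx, catalogue$alleles,
                         function(idx, al) {
    paste(sites$pos[idx], al, sep = "=", collapse = ";")
  })
  df <- tibble::tibble(start = catalogue$start, end = catalogue$end,
                       signature = sig, n = catalogue$observations)
  df[order(df$start, df$end, df$signature), ]
}
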