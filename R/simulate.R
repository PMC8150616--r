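#' Configure a synthetic diploid cohort
#'
#' Describes a simulated cohort: a uniformly random reference window, a set
#' of variant sites (placed on a spaced grid so footprints never collide,
#' or given explicitly), Hardy-Weinberg genotypes (each chromosome drawn
#' independently with the site's alternate-allele frequency), population
#' labels assigned round-robin, and optional planted samples with fully
#' specified genotype rows. Everything is driven by a single seed.
#'
#' @param contig Simulated contig name.
#' @param region_length Length of the simulated region (its coordinates are
#'   `1..region_length`).
#' @param gene Numeric `c(start, end)` of the focal gene, within the region.
#' @param sites Optional explicit site tibble with columns `pos`,
#'   `ref` (`NA` to take the reference base), `alts` (list column) and
#'   `freq` (list column of per-alt frequencies, or a numeric). When `NULL`
#'   sites are placed randomly.
#' @param n_sites,n_in_gene Total number of sites and how many fall inside
#'   the gene (random placement only).
#' @param n_indels How many of the out-of-gene sites are 3-base deletions
#'   (REF of length 3, ALT its first base).
#' @param alt_freq Alternate-allele frequency used for random sites.
#' @param n_samples Number of diploid samples (`S001`, `S002`, ...).
#' @param populations Named character vector mapping population code to
#'   super-population code.
#' @param planted Optional tibble with columns `sample`, `a`, `b` (list
#'   columns of full integer genotype rows); planted samples are appended
#'   after the random ones.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(contig = "sim1", region_length = 1000,
                       gene = c(401, 600), sites = NULL,
                       n_sites = 20, n_in_gene = 5, n_indels = 0,
                       alt_freq = 0.1, n_samples = 50,
                       populations = c(POPA = "AFR", POPB = "EUR",
                                       POPC = "EAS"),
                       planted = NULL, seed = 1L) {
  stopifnot(length(gene) == 2, gene[1] >= 1, gene[2] <= region_length,
            gene[1] <= gene[2])
  structure(list(contig = contig, region_length = region_length,
                 gene = gene, sites = sites, n_sites = n_sites,
                 n_in_gene = n_in_gene, n_indels = n_indels,
                 alt_freq = alt_freq, n_samples = n_samples,
                 populations = populations, planted = planted,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a cohort with exhaustive-search ground truth
#'
#' Generates the cohort described by a [sim_config()] and, alongside it, the
#' expected result of the haplotype method computed by an exhaustive window
#' search private to this generator — deliberately NOT by the extraction
#' code under test, so generator and extractor cannot share a bug silently.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `hap_simulation`: a list with `cohort` (a
#'   [hap_cohort()] with reference attached), `panel`, `truth` (list with
#'   `samples` — per-sample qualifying flag and expected span — and
#'   `catalogue` — expected distinct haplotypes as
#'   `start`/`end`/`signature`/`n`, where a signature is
#'   `"pos=allele;..."` over the span's sites) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  region <- genomic_interval(cfg$contig, 1, cfg$region_length)
  gene <- genomic_interval(cfg$contig, cfg$gene[1], cfg$gene[2])
  reference <- paste(sample(c("A", "C", "G", "T"), cfg$region_length,
                            replace = TRUE), collapse = "")

  sites <- cfg$sites
  if (is.null(sites)) {
    # grid spacing 6 keeps even 3-base deletion footprints apart
    grid <- seq(2, cfg$region_length - 4, by = 6)
    in_gene <- grid[grid >= gene$start & grid <= gene$end - 3]
    out_gene <- grid[grid < gene$start - 3 | grid > gene$end]
    n_out <- cfg$n_sites - cfg$n_in_gene
    stopifnot(length(in_gene) >= cfg$n_in_gene, length(out_gene) >= n_out)
    pos <- sort(c(sample(in_gene, cfg$n_in_gene),
                  sample(out_gene, n_out)))
    is_indel <- rep(FALSE, length(pos))
    if (cfg$n_indels > 0) {
      eligible <- which(pos < gene$start - 3 | pos > gene$end)
      is_indel[sample(eligible, min(cfg$n_indels, length(eligible)))] <- TRUE
    }
    sites <- tibble(pos = pos, ref = NA_character_,
                    alts = vector("list", length(pos)),
                    freq = as.list(rep(cfg$alt_freq, length(pos))))
    for (j in seq_along(pos)) {
      rb <- substr(reference, pos[j], pos[j] + if (is_indel[j]) 2 else 0)
      sites$ref[j] <- rb
      sites$alts[[j]] <- if (is_indel[j]) substr(rb, 1, 1) else
        sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    }
  } else {
    sites <- as_tibble(sites)
    if (!is.list(sites$freq)) sites$freq <- as.list(sites$freq)
    if (!is.list(sites$alts)) sites$alts <- as.list(sites$alts)
    for (j in seq_len(nrow(sites))) {
      if (is.na(sites$ref[j])) {
        sites$ref[j] <- substr(reference, sites$pos[j], sites$pos[j])
      } else {
        # force the reference window to agree with the declared REF
        substr(reference, sites$pos[j],
               sites$pos[j] + nchar(sites$ref[j]) - 1) <- sites$ref[j]
      }
    }
  }
  sites$end <- sites$pos + nchar(sites$ref) - 1
  freq <- sites$freq
  sites <- sites[c("pos", "ref", "alts", "end")]
  sites$id <- sprintf("sv%03d", seq_len(nrow(sites)))
  sites <- sites[c("pos", "id", "ref", "alts", "end")]

  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  draw <- function() {
    m <- matrix(0L, nrow = cfg$n_samples, ncol = nrow(sites))
    for (j in seq_len(nrow(sites))) {
      p <- freq[[j]]
      m[, j] <- sample.int(length(p) + 1L, cfg$n_samples, replace = TRUE,
                           prob = c(1 - sum(p), p)) - 1L
    }
    m
  }
  geno_a <- draw()
  geno_b <- draw()

  if (!is.null(cfg$planted)) {
    pl <- as_tibble(cfg$planted)
    for (i in seq_len(nrow(pl))) {
      a <- as.integer(pl$a[[i]]); b <- as.integer(pl$b[[i]])
      if (length(a) != nrow(sites) || length(b) != nrow(sites)) {
        stop("planted genotype row for '", pl$sample[i],
             "' must have one entry per site", call. = FALSE)
      }
      n_alt <- lengths(sites$alts)
      bad <- (!is.na(a) & a > n_alt) | (!is.na(b) & b > n_alt)
      if (any(bad)) {
        stop("planted allele index out of range at site ",
             sites$pos[which(bad)[1]], call. = FALSE)
      }
      samples <- c(samples, pl$sample[i])
      geno_a <- rbind(geno_a, a)
      geno_b <- rbind(geno_b, b)
    }
  }
  rownames(geno_a) <- NULL; rownames(geno_b) <- NULL

  pops <- names(cfg$populations)
  panel <- tibble(sample = samples,
                  pop = rep(pops, length.out = length(samples)),
                  super_pop = unname(cfg$populations[
                    rep(pops, length.out = length(samples))]))

  cohort <- hap_cohort(sites, samples, geno_a, geno_b,
                       phased = matrix(FALSE, length(samples), nrow(sites)),
                       region = region, reference = reference)
  truth <- truth_extract(cohort, gene)
  structure(list(cohort = cohort, panel = panel, gene = gene,
                 truth = truth, config = cfg),
            class = "hap_simulation")
}

# exhaustive ground-truth extraction, private to the generator:
# every candidate window containing the gene is tested directly.
truth_extract <- function(cohort, gene) {
  sites <- cohort$sites
  region <- cohort$region
  n <- length(cohort$samples)
  qualifying <- logical(n)
  span_s <- rep(NA_real_, n); span_e <- rep(NA_real_, n)
  sigs <- list()
  gene_ov <- site_overlaps(sites, gene)
  for (i in seq_len(n)) {
    a <- cohort$geno_a[i, ]; b <- cohort$geno_b[i, ]
    miss <- is.na(a) | is.na(b)
    het <- (a != b) | miss
    het[is.na(het)] <- TRUE
    if (sum(het & gene_ov) > 1) next
    if (sum(het & gene_ov) == 1 && any(het & gene_ov & miss)) next
    qualifying[i] <- TRUE
    cand_L <- c(region$start, sites$end[sites$end < gene$start] + 1)
    cand_R <- c(region$end, sites$pos[sites$pos > gene$end] - 1)
    valid <- function(L, R) {
      !any(het & !gene_ov & sites$pos <= R & sites$end >= L)
    }
    okL <- cand_L[vapply(cand_L, function(L) valid(L, gene$end), logical(1))]
    okR <- cand_R[vapply(cand_R, function(R) valid(gene$start, R), logical(1))]
    L <- min(okL); R <- max(okR)
    stopifnot(valid(L, R)) # left/right constraints are independent
    span_s[i] <- L; span_e[i] <- R
    in_span <- which(sites$pos >= L & sites$end <= R)
    for (al in list(a[in_span], b[in_span])) {
      sigs[[length(sigs) + 1L]] <- list(
        start = L, end = R,
        signature = paste(sites$pos[in_span], al, sep = "=",
                          collapse = ";"))
    }
  }
  cat_tab <- if (length(sigs) > 0) {
    tibble(start = map_dbl(sigs, "start"),
           end = map_dbl(sigs, "end"),
           signature = map_chr(sigs, "signature")) |>
      group_by(.data$start, .data$end, .data$signature) |>
      summarise(n = dplyr::n(), .groups = "drop") |>
      arrange(desc(.data$n), .data$start, .data$end, .data$signature)
  } else {
    tibble(start = numeric(), end = numeric(), signature = character(),
           n = integer())
  }
  list(samples = tibble(sample = cohort$samples, qualifying = qualifying,
                        start = span_s, end = span_e),
       catalogue = cat_tab)
}

#' Write a simulation to disk
#'
#' Emits exactly the formats the readers consume: a VCF (seed stamped in
#' the header), a reference FASTA, a panel TSV, plus two ground-truth TSVs.
#'
#' @param sim A `hap_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the five paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "hap_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    fasta = file.path(dir, "reference.fa"),
    panel = file.path(dir, "panel.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    truth_catalogue = file.path(dir, "truth_catalogue.tsv")
  )
  write_cohort_vcf(sim$cohort, paths$vcf,
                   extra_header = sprintf("##simulation_seed=%d",
                                          sim$config$seed))
  write_reference_fasta(sim$cohort$reference, sim$cohort$region$contig,
                        paths$fasta)
  write_panel(sim$panel, paths$panel)
  readr::write_tsv(sim$truth$samples, paths$truth_samples)
  readr::write_tsv(sim$truth$catalogue, paths$truth_catalogue)
  invisible(paths)
}

#' Bundled regression fixture
#'
#' A versioned, seed-fixed small cohort (30 HWE samples, 25 sites of which
#' one is a 3-base deletion, 3 populations) used for golden-file tests: its
#' expected catalogue and allele calls ship with the package under
#' `extdata/regression/`. Also returns a toy 3-allele configuration derived
#' deterministically from the first three in-gene SNV sites.
#'
#' @return List with `sim` (a `hap_simulation`) and `allele_config`.
#' @export
regression_fixture <- function() {
  cfg <- sim_config(contig = "regfix1", region_length = 600,
                    gene = c(251, 400), n_sites = 25, n_in_gene = 6,
                    n_indels = 1, alt_freq = 0.15, n_samples = 30,
                    populations = c(LWK = "AFR", GBR = "EUR", CHB = "EAS"),
                    seed = 4242L)
  sim <- simulate_cohort(cfg)
  sites <- sim$cohort$sites
  snv_in_gene <- which(nchar(sites$ref) == 1 &
                         sites$pos >= sim$gene$start &
                         sites$pos <= sim$gene$end)[1:3]
  posmap <- tibble(pos = sites$pos[snv_in_gene],
                   label = paste0("c.", sites$pos[snv_in_gene] -
                                    sim$gene$start + 1),
                   ref = sites$ref[snv_in_gene])
  ref_motif <- paste(posmap$ref, collapse = "")
  alt1 <- paste0(sites$alts[[snv_in_gene[1]]][1],
                 substr(ref_motif, 2, 3))
  alt2 <- paste0(substr(ref_motif, 1, 1), sites$alts[[snv_in_gene[2]]][1],
                 substr(ref_motif, 3, 3))
  cfg_alleles <- allele_config(posmap,
                               tibble(name = c("AL*01", "AL*02", "AL*03"),
                                      motif = c(ref_motif, alt1, alt2)))
  list(sim = sim, allele_config = cfg_alleles)
}
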