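#' Deduplicate observations into a haplotype catalogue
#'
#' Groups chromosome observations by identity (span + sequence) and assigns
#' ordinal ids `HAP1, HAP2, ...` by descending observation count, ties
#' broken by span start, span end, then sequence — so ids are deterministic
#' for a given input.
#'
#' @param obs Observations with sequences, from [build_sequences()].
#' @return A tibble of class `hap_catalogue` with columns `id`, `contig`,
#'   `start`, `end`, `length`, `observations`, `sequence`, `samples` (list
#'   column: one sample id per observed chromosome) and `site_idx`/`alleles`
#'   of a representative observation (used for motif extraction).
#' @export
catalogue_haplotypes <- function(obs) {
  if (!"sequence" %in% names(obs)) {
    stop("observations have no sequences; run build_sequences() first",
         call. = FALSE)
  }
  if (nrow(obs) == 0) {
    cat <- tibble(id = character(), contig = character(), start = numeric(),
                  end = numeric(), length = integer(),
                  observations = integer(), sequence = character(),
                  samples = list(), site_idx = list(), alleles = list())
    class(cat) <- c("hap_catalogue", class(cat))
    return(cat)
  }
  key <- sequence_digest(obs$start, obs$end, obs$sequence)
  first <- !duplicated(key)
  counts <- table(key)
  cat <- tibble(
    contig = obs$contig[first],
    start = obs$start[first],
    end = obs$end[first],
    length = obs$length[first],
    sequence = obs$sequence[first],
    site_idx = obs$site_idx[first],
    alleles = obs$alleles[first],
    observations = as.integer(counts[key[first]]),
    samples = map(key[first], function(k) obs$sample[key == k])
  )
  cat <- arrange(cat, desc(.data$observations), .data$start, .data$end,
                 .data$sequence)
  cat$id <- paste0("HAP", seq_len(nrow(cat)))
  cat <- cat[c("id", "contig", "start", "end", "length", "observations",
               "sequence", "samples", "site_idx", "alleles")]
  class(cat) <- c("hap_catalogue", class(cat))
  cat
}

#' Attach population breakdowns to a catalogue
#'
#' Counts, for every distinct haplotype, how many of its observed
#' chromosomes come from each population and super-population of the panel.
#'
#' @param catalogue A `hap_catalogue` from [catalogue_haplotypes()].
#' @param panel Panel tibble from [read_panel()].
#' @return The catalogue with a `pop_counts` list column (tibbles with
#'   `pop`, `super_pop`, `n` summing to `observations`).
#' @export
population_breakdown <- function(catalogue, panel) {
  absent <- setdiff(unique(unlist(catalogue$samples)), panel$sample)
  if (length(absent) > 0) {
    stop("sample absent from panel: ", absent[1], call. = FALSE)
  }
  catalogue$pop_counts <- map(catalogue$samples, function(ss) {
    hit <- panel[match(ss, panel$sample), c("pop", "super_pop")]
    hit |>
      group_by(.data$pop, .data$super_pop) |>
      summarise(n = dplyr::n(), .groups = "drop") |>
      arrange(.data$pop)
  })
  catalogue
}

#' Write a haplotype catalogue
#'
#' Writes the two files the pipeline publishes: a FASTA of the distinct
#' haplotype sequences with headers
#' `HAP<n>|<contig>:<start>-<end>|len=<L>|obs=<k>`, and a tab-separated
#' metadata table with one row per distinct haplotype (id, span, length,
#' observations, one count column per super-population, one per population,
#' and the allele call when classification has been run).
#'
#' @param catalogue A `hap_catalogue`, ideally after
#'   [population_breakdown()] (without it the count columns are omitted).
#' @param fasta_path,meta_path Output paths.
#' @param panel Optional panel tibble; when given, a column is emitted for
#'   every population in the panel (zero-filled), not only those observed.
#' @return Invisibly, a list with the two paths.
#' @export
write_catalogue <- function(catalogue, fasta_path, meta_path, panel = NULL) {
  headers <- sprintf("%s|%s:%s-%s|len=%d|obs=%d",
                     catalogue$id, catalogue$contig,
                     format(catalogue$start, scientific = FALSE, trim = TRUE),
                     format(catalogue$end, scientific = FALSE, trim = TRUE),
                     catalogue$length, catalogue$observations)
  fa <- Biostrings::DNAStringSet(
    if (nrow(catalogue) > 0) catalogue$sequence else character(0))
  names(fa) <- headers
  Biostrings::writeXStringSet(fa, fasta_path)

  meta <- catalogue[c("id", "contig", "start", "end", "length",
                      "observations")]
  if ("pop_counts" %in% names(catalogue)) {
    if (!is.null(panel)) {
      pops <- unique(panel[c("pop", "super_pop")]) |> arrange(.data$pop)
    } else {
      pops <- bind_rows(catalogue$pop_counts) |>
        select("pop", "super_pop") |> unique() |> arrange(.data$pop)
    }
    superpops <- sort(unique(pops$super_pop))
    for (sp in superpops) meta[[sp]] <- 0L
    for (p in pops$pop) meta[[paste0("pop_", p)]] <- 0L
    for (i in seq_len(nrow(catalogue))) {
      pc <- catalogue$pop_counts[[i]]
      for (j in seq_len(nrow(pc))) {
        meta[i, pc$super_pop[j]] <- meta[[pc$super_pop[j]]][i] + pc$n[j]
        meta[i, paste0("pop_", pc$pop[j])] <-
          meta[[paste0("pop_", pc$pop[j])]][i] + pc$n[j]
      }
    }
  }
  meta$allele <- if ("allele" %in% names(catalogue)) catalogue$allele else
    NA_character_
  readr::write_tsv(meta, meta_path, na = "")
  invisible(list(fasta = fasta_path, meta = meta_path))
}

#' Read a haplotype catalogue back from disk
#'
#' Inverse of [write_catalogue()] up to the columns the files carry: the
#' representative allele vectors and per-chromosome sample lists live only
#' in memory, so the reconstructed catalogue holds id, span, length,
#' observations, sequence, the population count columns and the allele call.
#'
#' @param fasta_path,meta_path Paths written by [write_catalogue()].
#' @return A tibble of class `hap_catalogue`.
#' @export
read_catalogue <- function(fasta_path, meta_path) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          na = character(),
                          col_types = readr::cols(id = "c", contig = "c",
                                                  allele = "c",
                                                  length = "i",
                                                  observations = "i",
                                                  .default = "d"))
  meta$allele[meta$allele == ""] <- NA_character_
  if (length(fa) != nrow(meta)) {
    stop("catalogue FASTA and metadata disagree on record count",
         call. = FALSE)
  }
  if (length(fa) > 0) {
    ids <- sub("\\|.*$", "", names(fa))
    meta$sequence <- unname(as.character(fa))[match(meta$id, ids)]
    meta$length <- as.integer(meta$length)
    meta$observations <- as.integer(meta$observations)
  } else {
    meta$sequence <- character(0)
  }
  cat <- as_tibble(meta)
  class(cat) <- c("hap_catalogue", class(cat))
  cat
}

#' @export
print.hap_catalogue <- function(x, ...) {
  cat("<hap_catalogue> ", nrow(x), " distinct haplotypes, ",
      sum(x$observations), " chromosome observations\n", sep = "")
  NextMethod()
}

#' @method glance hap_catalogue
#' @export
glance.hap_catalogue <- function(x, ...) {
  tibble(distinct_haplotypes = nrow(x),
         total_observations = sum(x$observations),
         min_length = if (nrow(x)) min(x$length) else NA_integer_,
         max_length = if (nrow(x)) max(x$length) else NA_integer_)
}
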