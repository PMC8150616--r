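#' Read a sample panel
#'
#' Reads a 1000GP-style panel table mapping each sample to a population and
#' super-population. The file must be tab- or whitespace-delimited with a
#' header containing at least `sample`, `pop` and `super_pop` columns
#' (additional columns such as `gender` are ignored).
#'
#' @param path Path to the panel file.
#' @return A tibble with columns `sample`, `pop`, `super_pop`.
#' @export
read_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c("sample", "pop", "super_pop")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("panel file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- as_tibble(tab[needed])
  if (anyDuplicated(tab$sample)) {
    dup <- tab$sample[duplicated(tab$sample)][1]
    stop("duplicate sample id in panel: ", dup, call. = FALSE)
  }
  # a population must not straddle super-populations
  mapping <- unique(tab[c("pop", "super_pop")])
  if (anyDuplicated(mapping$pop)) {
    bad <- mapping$pop[duplicated(mapping$pop)][1]
    stop("population '", bad, "' mapped to more than one super-population",
         call. = FALSE)
  }
  tab
}

#' Write a sample panel
#'
#' @param panel Tibble with columns `sample`, `pop`, `super_pop`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel[c("sample", "pop", "super_pop")], path)
  invisible(path)
}

#' Read a reference window from a FASTA file
#'
#' Returns the uppercase sequence of `region` from a FASTA file. The record
#' is matched by the first whitespace-delimited token of its header; if that
#' token itself has the form `name:start-end` (as produced by
#' `samtools faidx`), the embedded start is used as the genomic coordinate
#' of the record's first base, so windows cut from a chromosome keep their
#' chromosomal coordinates.
#'
#' @param fasta_path Path to a FASTA file.
#' @param region [genomic_interval()] to extract.
#' @return Uppercase nucleotide string of exactly `interval_length(region)`.
#' @export
read_reference_window <- function(fasta_path, region) {
  stopifnot(inherits(region, "genomic_interval"))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tokens <- sub("\\s.*$", "", names(seqs))
  offset <- rep(1, length(tokens))
  contigs <- tokens
  windowed <- grepl("^.+:[0-9,]+-[0-9,]+$", tokens)
  if (any(windowed)) {
    iv <- lapply(tokens[windowed], parse_region)
    contigs[windowed] <- vapply(iv, function(z) z$contig, character(1))
    offset[windowed] <- vapply(iv, function(z) z$start, numeric(1))
  }
  hit <- which(contigs == region$contig)
  if (length(hit) == 0) {
    stop("contig '", region$contig, "' not found in ", fasta_path,
         call. = FALSE)
  }
  hit <- hit[1]
  lo <- region$start - offset[hit] + 1
  hi <- region$end - offset[hit] + 1
  if (lo < 1 || hi > Biostrings::width(seqs)[hit]) {
    stop("region ", format(region), " exceeds the bounds of contig '",
         region$contig, "' in ", fasta_path, call. = FALSE)
  }
  toupper(as.character(Biostrings::subseq(seqs[[hit]], lo, hi)))
}

#' Write a reference sequence to FASTA
#'
#' @param sequence Nucleotide string.
#' @param name FASTA record name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(sequence, name, path) {
  x <- Biostrings::DNAStringSet(toupper(sequence))
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
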