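#' Allele definitions over diagnostic positions
#'
#' Blood-group alleles are named here from a motif: the ordered bases a
#' haplotype carries at a configured set of diagnostic (exonic/regulatory)
#' genomic positions, read 5' to 3'. All other variation — intronic and
#' synonymous sites — is ignored by design. Constructs and validates a
#' configuration from a diagnostic-position map and a motif table.
#'
#' @param posmap Tibble with columns `pos` (genomic position, strictly
#'   ascending), `label` (CDS-style label such as `c.-67`, unique) and
#'   `ref` (reference base).
#' @param alleles Tibble with columns `name` and `motif`; every motif must
#'   have one base per diagnostic position and motifs must be pairwise
#'   distinct.
#' @return An object of class `allele_config`.
#' @export
allele_config <- function(posmap, alleles) {
  posmap <- as_tibble(posmap)[c("pos", "label", "ref")]
  alleles <- as_tibble(alleles)[c("name", "motif")]
  if (nrow(posmap) > 1 && any(diff(posmap$pos) <= 0)) {
    stop("diagnostic positions must be strictly ascending", call. = FALSE)
  }
  if (anyDuplicated(posmap$label)) {
    stop("diagnostic position labels must be unique", call. = FALSE)
  }
  if (any(nchar(alleles$motif) != nrow(posmap))) {
    stop("every motif must have exactly one base per diagnostic position (",
         nrow(posmap), ")", call. = FALSE)
  }
  if (anyDuplicated(alleles$motif)) {
    stop("allele motifs must be pairwise distinct", call. = FALSE)
  }
  structure(list(posmap = posmap, alleles = alleles), class = "allele_config")
}

#' @export
print.allele_config <- function(x, ...) {
  cat("<allele_config> ", nrow(x$posmap), " diagnostic positions, ",
      nrow(x$alleles), " alleles: ",
      paste(x$alleles$name, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / ship allele configurations
#'
#' The configuration file is a comment-tolerant TSV with a `record` column:
#' `position` rows carry `pos`, `label`, `ref`; `allele` rows carry the
#' allele `name` and its `motif`. `fy_allele_config()` loads the bundled
#' Duffy (FY) default: the three common alleles FY*01, FY*02 and FY*02N.01
#' over 15 exonic/promoter positions. In that file the GATA-box position
#' c.-67 (rs2814778) and the Fya/Fyb position c.125 (rs12075) carry their
#' real GRCh38 coordinates; the remaining 13 positions are synthetic
#' placeholders (see the file header), which classification by motif never
#' depends on.
#'
#' @param path Path to a configuration file.
#' @return An `allele_config`.
#' @export
read_allele_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[`, character(1), 1)
  grab <- function(i) vapply(parts[kind == "position"], `[`, character(1), i)
  posmap <- tibble(pos = as.numeric(grab(2)), label = grab(3),
                   ref = toupper(grab(4)))
  grab_a <- function(i) vapply(parts[kind == "allele"], `[`, character(1), i)
  alleles <- tibble(name = grab_a(2), motif = toupper(grab_a(3)))
  if (nrow(posmap) == 0 || nrow(alleles) == 0) {
    stop("allele config needs at least one 'position' and one 'allele' row",
         call. = FALSE)
  }
  allele_config(posmap, alleles)
}

#' @rdname read_allele_config
#' @export
fy_allele_config <- function() {
  read_allele_config(system.file("extdata", "fy_alleles_synthetic.tsv",
                                 package = "haplotract", mustWork = TRUE))
}

#' Extract a haplotype's diagnostic-position motif
#'
#' Reads the base the haplotype carries at each diagnostic position,
#' walking the realised sequence through the record's applied variants so
#' indel shifts are handled. Returns `NA` (an "uncallable" motif, not an
#' error) when any diagnostic position falls outside the haplotype's span
#' or inside a deletion.
#'
#' @param record One catalogue row (or anything with `start`, `end`,
#'   `sequence`, `site_idx`, `alleles` fields).
#' @param sites Site tibble of the cohort the catalogue came from.
#' @param posmap Diagnostic-position tibble (`pos`, `label`, `ref`), e.g.
#'   `config$posmap`.
#' @return Single motif string, or `NA_character_`.
#' @export
motif_of <- function(record, sites, posmap) {
  start <- record$start[[1]]; end <- record$end[[1]]
  sequence <- record$sequence[[1]]
  idx <- record$site_idx[[1]]; al <- record$alleles[[1]]
  if (length(idx) > 0) {
    ord <- order(sites$pos[idx])
    idx <- idx[ord]; al <- al[ord]
  }
  a_str <- if (length(idx) > 0) {
    map_chr(seq_along(idx), function(j) {
      if (al[j] == 0L) sites$ref[idx[j]] else sites$alts[[idx[j]]][al[j]]
    })
  } else character(0)
  diffs <- if (length(idx) > 0) nchar(a_str) - nchar(sites$ref[idx]) else
    numeric(0)
  bases <- character(nrow(posmap))
  for (k in seq_len(nrow(posmap))) {
    g <- posmap$pos[k]
    if (g < start || g > end) return(NA_character_)
    cov <- if (length(idx) > 0)
      which(sites$pos[idx] <= g & sites$end[idx] >= g) else integer(0)
    if (length(cov) == 1) {
      rel <- g - sites$pos[idx[cov]] + 1
      if (rel > nchar(a_str[cov])) return(NA_character_) # base deleted
    }
    shift <- if (length(idx) > 0) sum(diffs[sites$end[idx] < g]) else 0
    off <- g - start + 1 + shift
    bases[k] <- substr(sequence, off, off)
  }
  paste(bases, collapse = "")
}

#' Classify a motif against allele definitions
#'
#' Exact-match lookup, no fuzzy matching: a motif either equals a defined
#' allele's motif or the haplotype is `"unclassified"` (a value, not an
#' error — rare alleles absent from the configuration land here).
#'
#' @param motif Motif string(s), vectorised; `NA` yields `"uncallable"`.
#' @param config An `allele_config`.
#' @return Character vector of allele names / `"unclassified"` /
#'   `"uncallable"`.
#' @export
classify_motif <- function(motif, config) {
  stopifnot(inherits(config, "allele_config"))
  hit <- config$alleles$name[match(toupper(motif), config$alleles$motif)]
  out <- ifelse(is.na(motif), "uncallable",
                ifelse(is.na(hit), "unclassified", hit))
  out
}

#' Classify every haplotype in a catalogue
#'
#' @param catalogue A `hap_catalogue` (in-memory, with representative
#'   allele vectors).
#' @param sites Site tibble of the originating cohort.
#' @param config An `allele_config`.
#' @return The catalogue with `motif` and `allele` columns added.
#' @export
classify_catalogue <- function(catalogue, sites, config) {
  stopifnot(inherits(config, "allele_config"))
  catalogue$motif <- map_chr(seq_len(nrow(catalogue)), function(i) {
    motif_of(catalogue[i, ], sites, config$posmap)
  })
  catalogue$allele <- classify_motif(catalogue$motif, config)
  catalogue
}

#' Per-allele length statistics
#'
#' Summarises the classified catalogue per allele over DISTINCT haplotypes:
#' how many distinct haplotypes carry each allele, their length range,
#' mean +/- sd (sample sd, n-1 denominator) and median, plus the chromosome
#' observations they account for. Unclassified and uncallable haplotypes
#' are reported as their own rows; the `Total` row covers classified
#' haplotypes only.
#'
#' @param catalogue A classified catalogue (see [classify_catalogue()]).
#' @return Tibble with one row per allele, plus special rows.
#' @export
allele_summary <- function(catalogue) {
  if (!"allele" %in% names(catalogue)) {
    stop("catalogue is not classified; run classify_catalogue() first",
         call. = FALSE)
  }
  one <- function(df, label) {
    tibble(allele = label,
           haplotypes = nrow(df),
           observations = sum(df$observations),
           min_length = if (nrow(df)) min(df$length) else NA_real_,
           max_length = if (nrow(df)) max(df$length) else NA_real_,
           mean_length = if (nrow(df)) mean(df$length) else NA_real_,
           sd_length = if (nrow(df) > 1) sd(df$length) else NA_real_,
           median_length = if (nrow(df)) median(df$length) else NA_real_)
  }
  special <- c("unclassified", "uncallable")
  named <- sort(setdiff(unique(catalogue$allele), special))
  rows <- map(named, function(a) one(catalogue[catalogue$allele == a, ], a))
  classified <- catalogue[!catalogue$allele %in% special, ]
  rows <- c(rows, list(one(classified, "Total")))
  for (s in special) {
    if (any(catalogue$allele == s)) {
      rows <- c(rows, list(one(catalogue[catalogue$allele == s, ], s)))
    }
  }
  bind_rows(rows)
}
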