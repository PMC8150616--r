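#' IUPAC-aware base compatibility
#'
#' Two (possibly ambiguous) IUPAC nucleotide codes are compatible when the
#' nucleotide sets they denote intersect — e.g. `Y` (C or T) is compatible
#' with `T`. Archaic-genome consensus bases are often reported as ambiguity
#' codes, so mismatch counting must not penalise them when a concrete base
#' is consistent.
#'
#' @param a,b Single-character IUPAC codes, vectorised (recycled).
#' @return Logical vector.
#' @examples
#' bases_compatible("Y", "T") # TRUE
#' bases_compatible("A", "C") # FALSE
#' @export
bases_compatible <- function(a, b) {
  map <- Biostrings::IUPAC_CODE_MAP
  a <- toupper(a); b <- toupper(b)
  bad <- unique(c(a, b)[!c(a, b) %in% names(map)])
  if (length(bad) > 0) {
    stop("not an IUPAC nucleotide code: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sa <- strsplit(map[a], "")
  sb <- strsplit(map[b], "")
  map2(sa, sb, function(x, y) length(intersect(x, y)) > 0) |>
    unlist(use.names = FALSE)
}

#' Count mismatches between two base profiles
#'
#' Positions where [bases_compatible()] is `FALSE`. The two strings must
#' align position-for-position (same diagnostic-position set, 5' to 3').
#'
#' @param query,motif Equal-length base strings; `query` may contain IUPAC
#'   ambiguity codes.
#' @return Integer mismatch count.
#' @export
mismatch_count <- function(query, motif) {
  if (nchar(query) != nchar(motif)) {
    stop("profiles differ in length (", nchar(query), " vs ", nchar(motif),
         ")", call. = FALSE)
  }
  if (nchar(query) == 0) return(0L)
  q <- strsplit(query, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  sum(!bases_compatible(q, m))
}

#' Rank catalogue haplotypes by closeness to a query profile
#'
#' Extracts each haplotype's bases at the comparison positions and orders
#' the catalogue by ascending mismatch count against the query, ties broken
#' by descending length then id. Haplotypes whose span does not cover every
#' comparison position are uncallable and excluded. An exact match shows up
#' as `mismatches == 0` in the first row.
#'
#' @param catalogue A `hap_catalogue` (in-memory form).
#' @param sites Site tibble of the originating cohort.
#' @param query Query base string (IUPAC codes allowed), one base per
#'   comparison position, 5' to 3'.
#' @param posmap Comparison positions (`pos`, `label`, `ref`); the set of
#'   positions compared is deliberately a parameter.
#' @return Tibble with `id`, `motif`, `mismatches`, `length`,
#'   `observations`, sorted closest-first.
#' @export
rank_closest <- function(catalogue, sites, query, posmap) {
  if (nrow(catalogue) == 0) {
    return(tibble(id = character(), motif = character(),
                  mismatches = integer(), length = integer(),
                  observations = integer()))
  }
  motifs <- map_chr(seq_len(nrow(catalogue)), function(i) {
    motif_of(catalogue[i, ], sites, posmap)
  })
  res <- tibble(id = catalogue$id, motif = motifs,
                length = catalogue$length,
                observations = catalogue$observations) |>
    filter(!is.na(.data$motif))
  res$mismatches <- map_int(res$motif, function(m)
    as.integer(mismatch_count(query, m)))
  res |>
    mutate(.rank = as.integer(sub("^HAP", "", .data$id))) |>
    arrange(.data$mismatches, desc(.data$length), .data$.rank) |>
    select("id", "motif", "mismatches", "length", "observations")
}

#' Read external query profiles
#'
#' Reads a TSV of base profiles (e.g. archaic hominin consensus bases at
#' the diagnostic positions): columns `name`, `source`, then one column per
#' diagnostic label. `neanderthal_profiles()` loads the bundled profiles of
#' the three high-coverage Neanderthal genomes (Chagyrskaya, Altai,
#' Vindija 33.19) together with the two closest modern haplotypes and the
#' gene reference, at the four GATA-box-region positions c.-67, c.21+115,
#' c.21+235 and c.125.
#'
#' @param path Path to a profile TSV.
#' @return Tibble with `name`, `source`, `bases` (concatenated profile
#'   string); the position labels are kept in the `"positions"` attribute.
#' @export
read_query_profiles <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("name", "source") %in% names(raw))) {
    stop("profile file needs 'name' and 'source' columns", call. = FALSE)
  }
  labels <- setdiff(names(raw), c("name", "source"))
  if (length(labels) == 0) {
    stop("profile file has no position columns", call. = FALSE)
  }
  bases <- apply(as.matrix(raw[labels]), 1, paste, collapse = "")
  out <- tibble(name = raw$name, source = raw$source,
                bases = toupper(bases))
  attr(out, "positions") <- labels
  out
}

#' @rdname read_query_profiles
#' @export
neanderthal_profiles <- function() {
  read_query_profiles(system.file("extdata", "ackr1_gata_profiles.tsv",
                                  package = "haplotract", mustWork = TRUE))
}
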