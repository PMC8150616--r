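#' Summarise a haplotype catalogue
#'
#' Computes the headline statistics of the catalogue. Median, quartiles and
#' combined length are taken over the DISTINCT haplotypes (each counted
#' once); the length histogram is weighted by chromosome observations, so
#' its column total equals the number of observed chromosomes. Quartiles
#' use linear interpolation on the sorted values (`stats::quantile`
#' type 7); bin percentages are rounded half-up to 2 decimals.
#'
#' @param catalogue A `hap_catalogue`.
#' @param bin_width Histogram bin width in nucleotides (default 10,000).
#' @return An object of class `hap_summary`: a list with scalar fields
#'   (`distinct_count`, `total_observations`, `min_length`, `max_length`,
#'   `combined_length`, `median_length`, `q1`, `q3`, `iqr`) and a `bins`
#'   tibble (`bin`, `lower`, `upper`, `observations`, `percent`).
#' @export
summarize_catalogue <- function(catalogue, bin_width = 10000) {
  stopifnot(bin_width > 0)
  if (nrow(catalogue) == 0) {
    out <- list(distinct_count = 0L, total_observations = 0L,
                min_length = NA_real_, max_length = NA_real_,
                combined_length = 0, median_length = NA_real_,
                q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                bin_width = bin_width,
                bins = tibble(bin = character(), lower = numeric(),
                              upper = numeric(), observations = integer(),
                              percent = numeric()))
    class(out) <- "hap_summary"
    return(out)
  }
  len <- catalogue$length
  obs <- catalogue$observations
  q <- unname(quantile(len, c(0.25, 0.5, 0.75), type = 7))
  total <- sum(obs)

  n_bins <- floor(max(len) / bin_width) + 1
  lower <- (seq_len(n_bins) - 1) * bin_width
  upper <- lower + bin_width - 1
  idx <- pmin(floor(len / bin_width) + 1, n_bins)
  counts <- vapply(seq_len(n_bins),
                   function(b) sum(obs[idx == b]), numeric(1))
  fmt <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)
  lab <- paste0(fmt(lower), " - ", fmt(upper))
  lab[1] <- paste0("< ", fmt(bin_width))
  if (n_bins > 1) lab[n_bins] <- paste0(">= ", fmt(lower[n_bins]))
  bins <- tibble(bin = lab, lower = lower, upper = upper,
                 observations = as.integer(counts),
                 percent = round_half_up(100 * counts / total, 2))

  out <- list(distinct_count = nrow(catalogue),
              total_observations = as.integer(total),
              min_length = min(len), max_length = max(len),
              combined_length = sum(as.numeric(len)),
              median_length = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
              bin_width = bin_width, bins = bins)
  class(out) <- "hap_summary"
  out
}

# round-half-up (the spreadsheet convention), unlike base R's half-to-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.hap_summary <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE, trim = TRUE)
  cat("<hap_summary>\n",
      "  distinct haplotypes: ", fmt(x$distinct_count), "\n",
      "  chromosome observations: ", fmt(x$total_observations), "\n", sep = "")
  if (x$distinct_count > 0) {
    cat("  length range: ", fmt(x$min_length), " - ", fmt(x$max_length),
        " nt\n",
        "  combined length: ", fmt(x$combined_length), " nt\n",
        "  median (Q1 - Q3): ", fmt(x$median_length), " (", fmt(x$q1), " - ",
        fmt(x$q3), "), IQR ", fmt(x$iqr), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname summarize_catalogue
#' @param x A `hap_summary`.
#' @param ... Unused.
#' @method tidy hap_summary
#' @export
tidy.hap_summary <- function(x, ...) {
  x$bins
}

#' @rdname summarize_catalogue
#' @method glance hap_summary
#' @export
glance.hap_summary <- function(x, ...) {
  tibble(distinct_count = x$distinct_count,
         total_observations = x$total_observations,
         min_length = x$min_length, max_length = x$max_length,
         combined_length = x$combined_length,
         median_length = x$median_length,
         q1 = x$q1, q3 = x$q3, iqr = x$iqr)
}

#' Write summary tables
#'
#' Exports the observation-weighted length histogram and the one-row global
#' statistics as TSV files.
#'
#' @param summary A `hap_summary`.
#' @param bins_path,stats_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_summary <- function(summary, bins_path, stats_path) {
  readr::write_tsv(tidy(summary)[c("bin", "observations", "percent")],
                   bins_path)
  readr::write_tsv(glance(summary), stats_path)
  invisible(list(bins = bins_path, stats = stats_path))
}

#' Rank correlation between haplotype length and observation count
#'
#' Long haplotypes require long homozygosity tracts, which are rarer, so
#' length and observation count are expected to be inversely related
#' (negative coefficient).
#'
#' @param catalogue A `hap_catalogue` with at least 3 records.
#' @return Spearman's rank correlation coefficient, or `NA` with a warning
#'   when either variable is constant (the coefficient is undefined).
#' @export
length_observation_correlation <- function(catalogue) {
  if (nrow(catalogue) < 3) {
    stop("need at least 3 distinct haplotypes", call. = FALSE)
  }
  if (length(unique(catalogue$length)) == 1 ||
      length(unique(catalogue$observations)) == 1) {
    warning("rank correlation undefined: a variable is constant")
    return(NA_real_)
  }
  cor(catalogue$length, catalogue$observations, method = "spearman")
}
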