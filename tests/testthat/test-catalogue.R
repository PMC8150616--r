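# Deduplication, population breakdowns, summary statistics.

make_built <- function(seed = 17, n_samples = 12, alt_freq = 0.25) {
  sim <- simulate_cohort(sim_config(region_length = 250, gene = c(81, 160),
                                    n_sites = 14, n_in_gene = 4,
                                    alt_freq = alt_freq,
                                    n_samples = n_samples, seed = seed))
  obs <- build_sequences(sim$cohort,
                         extract_observations(sim$cohort, sim$gene))
  list(sim = sim, obs = obs, cat = catalogue_haplotypes(obs))
}

test_that("identical observations collapse and counts are conserved", {
  gene <- genomic_interval("toy", 40, 60)
  # one fully homozygous sample -> 1 record with 2 observations
  co <- toy_cohort(positions = c(50), geno_a = rbind(0L), geno_b = rbind(0L))
  cat1 <- catalogue_haplotypes(build_sequences(
    co, extract_observations(co, gene)))
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$observations, 2L)
  # one single-het sample -> 2 records with 1 observation each
  co2 <- toy_cohort(positions = c(50), geno_a = rbind(0L), geno_b = rbind(1L))
  cat2 <- catalogue_haplotypes(build_sequences(
    co2, extract_observations(co2, gene)))
  expect_equal(nrow(cat2), 2)
  expect_equal(cat2$observations, c(1L, 1L))

  x <- make_built()
  expect_equal(sum(x$cat$observations), nrow(x$obs))
  expect_equal(sum(x$cat$observations),
               2 * length(qualifying_samples(x$sim$cohort, x$sim$gene)))
})

test_that("ids are deterministic and deduplication is idempotent", {
  x <- make_built()
  expect_equal(x$cat$id, paste0("HAP", seq_len(nrow(x$cat))))
  expect_true(all(diff(x$cat$observations) <= 0))
  # expand the catalogue back into observations and dedup again
  expanded <- x$cat[rep(seq_len(nrow(x$cat)), x$cat$observations), ]
  expanded$sample <- unlist(x$cat$samples)
  expanded$chromosome <- 0L
  expanded$contig <- "sim1"
  again <- catalogue_haplotypes(expanded)
  expect_equal(again[c("id", "start", "end", "sequence", "observations")],
               x$cat[c("id", "start", "end", "sequence", "observations")])
})

test_that("population breakdowns count chromosomes per (super-)population", {
  gene <- genomic_interval("toy", 40, 60)
  co <- toy_cohort(positions = c(50), geno_a = rbind(0L), geno_b = rbind(0L))
  panel <- tibble::tibble(sample = "T01", pop = "LWK", super_pop = "AFR")
  cat <- population_breakdown(catalogue_haplotypes(build_sequences(
    co, extract_observations(co, gene))), panel)
  expect_equal(cat$pop_counts[[1]]$n, 2L)  # homozygous sample -> AFR = 2
  expect_equal(cat$pop_counts[[1]]$super_pop, "AFR")

  bad_panel <- tibble::tibble(sample = "OTHER", pop = "LWK",
                              super_pop = "AFR")
  expect_error(population_breakdown(catalogue_haplotypes(build_sequences(
    co, extract_observations(co, gene))), bad_panel), "T01")

  # simulated cohort: per-population counts match planted labels
  x <- make_built()
  cat2 <- population_breakdown(x$cat, x$sim$panel)
  for (i in seq_len(nrow(cat2))) {
    expect_equal(sum(cat2$pop_counts[[i]]$n), cat2$observations[i])
    truth <- table(x$sim$panel$pop[match(cat2$samples[[i]],
                                         x$sim$panel$sample)])
    got <- setNames(cat2$pop_counts[[i]]$n, cat2$pop_counts[[i]]$pop)
    expect_equal(got[order(names(got))],
                 setNames(as.integer(truth), names(truth)),
                 ignore_attr = TRUE)
  }
})

test_that("summary statistics follow the distinct-vs-weighted convention", {
  # single record: median is its length, one bin at 100%
  cat1 <- tibble::tibble(length = 500L, observations = 2L)
  class(cat1) <- c("hap_catalogue", class(cat1))
  s1 <- summarize_catalogue(cat1)
  expect_equal(s1$median_length, 500)
  expect_equal(nrow(s1$bins), 1)
  expect_equal(s1$bins$percent, 100)
  expect_equal(s1$bins$bin, "< 10,000")

  # quartile fixture: linear-interpolation quartiles land on the values
  cat2 <- tibble::tibble(length = c(7588L, 7588L, 16014L, 30729L, 30729L),
                         observations = rep(1L, 5))
  class(cat2) <- c("hap_catalogue", class(cat2))
  s2 <- summarize_catalogue(cat2)
  expect_equal(s2$q1, 7588)
  expect_equal(s2$q3, 30729)
  expect_equal(s2$iqr, 23141)
  expect_equal(s2$median_length, 16014)
  expect_equal(s2$combined_length, sum(cat2$length))
  expect_equal(s2$bins$bin[4], ">= 30,000")

  # conservation: bin counts sum to total observations at any width
  x <- make_built(seed = 23)
  for (w in c(13, 40, 10000)) {
    s <- summarize_catalogue(x$cat, bin_width = w)
    expect_equal(sum(s$bins$observations), s$total_observations)
    expect_equal(s$bins$percent,
                 floor(100 * s$bins$observations /
                         s$total_observations * 100 + 0.5) / 100)
  }

  # empty catalogue has a defined empty summary
  s0 <- summarize_catalogue(x$cat[0, ])
  expect_equal(s0$distinct_count, 0L)
  expect_equal(nrow(s0$bins), 0)

  # tidy/glance expose bins and scalars
  expect_equal(tidy(s2)$observations, c(2L, 1L, 0L, 2L))
  expect_equal(glance(s2)$iqr, 23141)
})

test_that("length-observation rank correlation handles the documented cases", {
  mk <- function(len, obs) {
    x <- tibble::tibble(length = len, observations = obs)
    class(x) <- c("hap_catalogue", class(x))
    x
  }
  expect_equal(length_observation_correlation(mk(1:3, 3:1)), -1)
  expect_equal(length_observation_correlation(mk(1:3, 1:3)), 1)
  expect_warning(r <- length_observation_correlation(mk(1:3, c(2, 2, 2))),
                 "constant")
  expect_true(is.na(r))
  expect_error(length_observation_correlation(mk(1:2, 1:2)), "at least 3")
})

test_that("gene variant counting uses footprint overlap", {
  gene <- genomic_interval("toy", 40, 60)
  co <- toy_cohort(positions = c(10, 39, 45, 55, 80),
                   ref = c("A", "AC", "G", "T", "C"),
                   alts = c("C", "A", "A", "A", "T"),
                   geno_a = matrix(0L, 1, 5), geno_b = matrix(0L, 1, 5))
  # footprint 39-40 straddles the gene start -> overlaps
  expect_equal(count_gene_variants(co$sites, gene), 3)
  expect_equal(count_gene_variants(co$sites, genomic_interval("toy", 1, 5)),
               0)
  expect_equal(count_gene_variants(co, gene), 3) # cohort accepted directly
})

test_that("plot builders return ggplot objects", {
  x <- make_built()
  expect_s3_class(autoplot(summarize_catalogue(x$cat)), "ggplot")
  expect_s3_class(autoplot(x$cat), "ggplot")
})
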