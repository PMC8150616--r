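# Core algorithm: qualification, bidirectional extension, observation rules.

test_that("heterozygote counting matches a direct per-site recount", {
  co <- toy_cohort(positions = c(10, 30, 50, 70),
                   geno_a = rbind(c(0, 0, 0, 0), c(0, 1, 0, 1)),
                   geno_b = rbind(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  gene <- genomic_interval("toy", 40, 60)
  expect_equal(het_counts(co, gene)$n_het, c(0L, 1L))
  # hets outside the interval are ignored
  expect_equal(het_counts(co, genomic_interval("toy", 1, 100))$n_het,
               c(0L, 2L))

  # randomized recount oracle
  set.seed(42)
  for (rep in 1:5) {
    pos <- sort(sample(2:98, 20))
    a <- matrix(sample(0:1, 200, replace = TRUE), nrow = 10)
    b <- matrix(sample(0:1, 200, replace = TRUE), nrow = 10)
    co <- toy_cohort(pos, a, b)
    iv <- genomic_interval("toy", 25, 75)
    got <- het_counts(co, iv)$n_het
    manual <- integer(10)
    for (i in 1:10) {
      for (j in seq_along(pos)) {
        if (pos[j] >= 25 && pos[j] <= 75 && a[i, j] != b[i, j]) {
          manual[i] <- manual[i] + 1L
        }
      }
    }
    expect_equal(got, manual)
  }
})

test_that("qualification keeps samples with at most one in-gene het", {
  gene <- genomic_interval("toy", 40, 60)
  co <- toy_cohort(positions = c(45, 55, 80),
                   geno_a = rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
                   geno_b = rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1)))
  # sample 2 has two in-gene hets -> excluded; sample 3's het at 80 is
  # outside the gene and its in-gene het at 45 is the single permitted one
  expect_equal(qualifying_samples(co, gene), c("T01", "T03"))
})

test_that("a cohort with zero variant sites qualifies everyone over the full region", {
  sites <- tibble::tibble(pos = numeric(), id = character(),
                          ref = character(), alts = list(), end = numeric())
  co <- hap_cohort(sites, c("A1", "A2"),
                   matrix(integer(), nrow = 2, ncol = 0),
                   matrix(integer(), nrow = 2, ncol = 0),
                   region = genomic_interval("toy", 1, 100),
                   reference = strrep("A", 100))
  gene <- genomic_interval("toy", 40, 60)
  expect_equal(qualifying_samples(co, gene), c("A1", "A2"))
  obs <- extract_observations(co, gene)
  expect_equal(nrow(obs), 4)
  expect_true(all(obs$start == 1 & obs$end == 100))
})

test_that("extension stops just inside the nearest flanking het variants", {
  # region 1-100, gene 40-60, het SNVs at 20 and 85, hom-ref at 50
  co <- toy_cohort(positions = c(20, 50, 85),
                   geno_a = rbind(c(0, 0, 0)),
                   geno_b = rbind(c(1, 0, 1)))
  gene <- genomic_interval("toy", 40, 60)
  sp <- extend_span(co, "T01", gene)
  expect_equal(c(sp$start, sp$end), c(21, 84))
  # no het anywhere -> full region
  co2 <- toy_cohort(positions = c(20, 85),
                    geno_a = rbind(c(1, 0)), geno_b = rbind(c(1, 0)))
  sp2 <- extend_span(co2, "T01", gene)
  expect_equal(c(sp2$start, sp2$end), c(1, 100))
  # the terminating variant's whole REF footprint is excluded
  co3 <- toy_cohort(positions = c(18, 85), ref = c("ACGT", "A"),
                    alts = c("A", "C"),
                    geno_a = rbind(c(0, 0)), geno_b = rbind(c(1, 0)))
  sp3 <- extend_span(co3, "T01", gene)
  expect_equal(sp3$start, 22) # footprint 18-21 fully outside the span
})

test_that("each qualifying sample yields exactly two observations with the documented structure", {
  gene <- genomic_interval("toy", 40, 60)
  co <- toy_cohort(positions = c(20, 50, 85),
                   geno_a = rbind(c(0, 0, 0), c(0, 0, 0)),
                   geno_b = rbind(c(0, 0, 0), c(0, 1, 0)))
  obs <- extract_observations(co, gene)
  expect_equal(nrow(obs), 4)
  expect_equal(obs$chromosome, c(0L, 1L, 0L, 1L))
  # fully homozygous sample: the two observations are identical
  expect_identical(obs$alleles[[1]], obs$alleles[[2]])
  # single-in-gene-het sample: same span, alleles differ at exactly 1 site
  expect_equal(obs$start[3], obs$start[4])
  expect_equal(sum(obs$alleles[[3]] != obs$alleles[[4]]), 1)
})

test_that("missing genotypes act as heterozygous and disqualify when in-gene", {
  gene <- genomic_interval("toy", 40, 60)
  # missing at out-of-gene site 20 terminates extension there
  co <- toy_cohort(positions = c(20, 50, 85),
                   geno_a = rbind(c(NA, 0, 0)),
                   geno_b = rbind(c(0, 0, 0)))
  sp <- extend_span(co, "T01", gene)
  expect_equal(sp$start, 21)
  # a single in-gene "het" that is a missing call cannot be assigned
  co2 <- toy_cohort(positions = c(50,  85),
                    geno_a = rbind(c(NA, 0)), geno_b = rbind(c(0, 0)))
  expect_equal(qualifying_samples(co2, gene), character(0))
  # under the permissive policy the missing site is ignored entirely
  expect_equal(qualifying_samples(co2, gene, missing_as_het = FALSE), "T01")
})

test_that("a het variant straddling the gene boundary counts as in-gene", {
  gene <- genomic_interval("toy", 40, 60)
  # deletion footprint 38-41 overlaps gene start
  co <- toy_cohort(positions = c(38, 80), ref = c("ACGT", "G"),
                   alts = c("A", "T"),
                   geno_a = rbind(c(0, 0)), geno_b = rbind(c(1, 0)))
  expect_equal(qualifying_samples(co, gene), "T01")
  fast <- extract_observations(co, gene)
  oracle <- brute_force_extract(co, gene)
  expect_equal(obs_signatures(fast, co$sites),
               obs_signatures(oracle, co$sites))
})

test_that("extraction equals the exhaustive-window oracle across random cohorts", {
  for (seed in 1:100) {
    sim <- simulate_cohort(sim_config(region_length = 150, gene = c(61, 90),
                                      n_sites = 15, n_in_gene = 4,
                                      n_indels = 1, alt_freq = 0.25,
                                      n_samples = 10, seed = seed))
    gene <- sim$gene
    fast <- extract_observations(sim$cohort, gene)
    oracle <- brute_force_extract(sim$cohort, gene)
    expect_identical(obs_signatures(fast, sim$cohort$sites),
                     obs_signatures(oracle, sim$cohort$sites))
    # |observations| = 2 x qualifying, always
    expect_equal(nrow(fast),
                 2 * length(qualifying_samples(sim$cohort, gene)))
  }
})

test_that("spans are maximal: widening to the next site admits a het", {
  sim <- simulate_cohort(sim_config(region_length = 200, gene = c(81, 120),
                                    n_sites = 18, n_in_gene = 4,
                                    alt_freq = 0.3, n_samples = 15,
                                    seed = 11))
  co <- sim$cohort
  gene <- sim$gene
  obs <- extract_observations(co, gene)
  h <- co$geno_a != co$geno_b
  for (k in seq_len(nrow(obs))) {
    i <- match(obs$sample[k], co$samples)
    if (obs$start[k] > co$region$start) {
      # the nearest site strictly left of the span must be het
      left <- which(co$sites$end < obs$start[k])
      expect_true(h[i, left[which.max(co$sites$end[left])]])
    }
    if (obs$end[k] < co$region$end) {
      right <- which(co$sites$pos > obs$end[k])
      expect_true(h[i, right[which.min(co$sites$pos[right])]])
    }
  }
})

test_that("swapping allele order per genotype changes nothing (phase independence)", {
  sim <- simulate_cohort(sim_config(region_length = 150, gene = c(61, 90),
                                    n_sites = 12, n_in_gene = 3,
                                    alt_freq = 0.3, n_samples = 12,
                                    seed = 5))
  co <- sim$cohort
  gene <- sim$gene
  set.seed(99)
  swap <- matrix(sample(c(TRUE, FALSE), length(co$geno_a), replace = TRUE),
                 nrow = nrow(co$geno_a))
  a2 <- ifelse(swap, co$geno_b, co$geno_a)
  b2 <- ifelse(swap, co$geno_a, co$geno_b)
  co2 <- hap_cohort(co$sites, co$samples, a2, b2, region = co$region,
                    reference = co$reference)
  o1 <- extract_observations(co, gene)
  o2 <- extract_observations(co2, gene)
  expect_identical(unique(o1[c("sample", "start", "end")]),
                   unique(o2[c("sample", "start", "end")]))
  expect_identical(obs_signatures(o1, co$sites),
                   obs_signatures(o2, co$sites))
})
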