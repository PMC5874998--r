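test_that("inclusion rate follows (I/2)/((I/2)+E) with NA on no data", {
  expect_equal(inclusion_rate(147944, 63724), (147944 / 2) / (147944 / 2 + 63724))
  expect_equal(percent_round(inclusion_rate(147944, 63724)), 54L)
  expect_equal(inclusion_rate(1000, 0), 1)
  expect_equal(inclusion_rate(0, 500), 0)
  expect_true(is.na(inclusion_rate(0, 0)))
  # terminal exons use a single flank
  expect_equal(inclusion_rate(100, 100, divisor = 1), 0.5)
  expect_error(inclusion_rate(-1, 5))
})

test_that("rate is monotone in I and E", {
  I <- seq(100, 5000, by = 100)
  expect_true(all(diff(inclusion_rate(I, 1000)) > 0))
  E <- seq(100, 5000, by = 100)
  expect_true(all(diff(inclusion_rate(1000, E)) < 0))
})

test_that("the statistic is unbiased under proportional junction counts", {
  # I ~ two Poisson(p*d) flanks, E ~ Poisson((1-p)*d): mean estimate
  # within 3 standard errors of p
  n_rep <- 200L
  set.seed(53)
  for (d in c(1e2, 1e4)) {
    for (p in c(0.05, 0.5, 0.95)) {
      I <- stats::rpois(n_rep, p * d) + stats::rpois(n_rep, p * d)
      E <- stats::rpois(n_rep, (1 - p) * d)
      r <- inclusion_rate(I, E)
      r <- r[!is.na(r)]
      se <- stats::sd(r) / sqrt(length(r))
      expect_lt(abs(mean(r) - p), max(3 * se, 1e-6) + p * (1 - p) / d,
                label = sprintf("bias at d=%g p=%g", d, p))
    }
  }
})

test_that("exon_support splits counts into inclusion and spanning reads", {
  cfg <- sim_config(n_exons = 5, seed = 61)
  m <- make_toy_gene(cfg)
  j <- function(d, a, aoff = 0L) {
    co <- exonusage:::junction_between(m, d, a, acceptor_offset = aoff)
    data.frame(chrom = m$chromosome, intron_start = co[[1]],
               intron_end = co[[2]], strand = m$strand)
  }
  juncs <- rbind(j(2, 3), j(3, 4), j(2, 4), j(2, 5))
  events <- classify_junctions(juncs, m)
  counts <- c(500, 520, 100, 40)
  s3 <- exon_support(3L, events, counts, m)
  expect_equal(s3$I, 1020)
  expect_equal(s3$E, 140)
  expect_setequal(s3$supporting_skip_events, c("2-4", "2-5"))
  # the multi-exon skip contributes its full count to every spanned exon
  s4 <- exon_support(4L, events, counts, m)
  expect_equal(s4$E, 40)
  # alternative-site junction landing inside an exon counts toward its I
  ev_alt <- classify_junctions(rbind(juncs, j(2, 3, aoff = 5L)), m)
  s3b <- exon_support(3L, ev_alt, c(counts, 60), m)
  expect_equal(s3b$I, 1080)
})

test_that("usage_table categorises exons and honours the repeat exclusion", {
  cfg <- sim_config(
    n_exons = 8, seed = 67, n_samples = 20, depth = 2000,
    isoforms = list(full = 1:8, skip4 = c(1:3, 5:8), no6 = c(1:5, 7:8)),
    proportions = c(0.6, 0.3, 0.1),
    repeat_block_spec = list(blocks = c("B1", "B2"), copies = 1,
                             start_exon = 7L))
  m <- make_toy_gene(cfg)
  sim <- simulate_junction_counts(m, cfg)
  u <- usage_table(m, sim$matrix, config = filter_config(100L, 10L))
  expect_s3_class(u, "exon_usage")
  # repeat-block exons 7 and 8 are excluded by default
  expect_false(any(u$exon_id %in% c(7L, 8L)))
  expect_true(all(c(7L, 8L) %in%
                    usage_table(m, sim$matrix,
                                config = filter_config(100L, 10L),
                                include_repeats = TRUE)$exon_id))
  expect_equal(u$category[u$exon_id == 4L], "variable")
  expect_equal(u$category[u$exon_id == 6L], "variable")
  expect_equal(u$category[u$exon_id == 2L], "constitutively_expressed")
  # rates recover the mixing proportions to simulation accuracy
  expect_lt(abs(u$inclusion_rate[u$exon_id == 4L] - 0.7), 0.05)
  expect_lt(abs(u$inclusion_rate[u$exon_id == 6L] - 0.9), 0.05)
})

test_that("exons whose inclusion evidence fails QC are spliced out", {
  # inclusion junctions for exon 4 exist but stay under the read
  # threshold; the skip junction passes
  cfg <- sim_config(n_exons = 5, seed = 71, n_samples = 20, depth = 2000,
                    isoforms = list(full = 1:5, skip4 = c(1:3, 5)),
                    proportions = c(0.005, 0.995))
  m <- make_toy_gene(cfg)
  sim <- simulate_junction_counts(m, cfg)
  u <- usage_table(m, sim$matrix, config = filter_config(1000L, 14L))
  expect_equal(u$category[u$exon_id == 4L], "constitutively_spliced_out")
  # with filtering disabled the same exon shows a (low) variable rate
  u2 <- usage_table(m, sim$matrix, apply_filter = FALSE)
  expect_equal(u2$category[u2$exon_id == 4L], "variable")
  expect_lt(u2$inclusion_rate[u2$exon_id == 4L], 0.05)
})

test_that("every QC-passing junction lands in some exon's I or E", {
  cfg <- sim_config(n_exons = 8, seed = 73, n_samples = 20, depth = 2000,
                    proportions = c(0.5, 0.5))
  m <- make_toy_gene(cfg)
  sim <- simulate_junction_counts(m, cfg)
  events <- classify_junctions(sim$matrix, m)
  pass <- qc_filter(sim$matrix, filter_config(100L, 10L))$pass
  ev <- events[pass, ]
  accounted <- vapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    e$category != "unassigned" || e$in_repeated_region
  }, logical(1))
  expect_true(all(accounted))
  u <- usage_table(m, sim$matrix, events, config = filter_config(100L, 10L))
  expect_true(all(u$inclusion_reads + u$exclusion_reads > 0))
})

test_that("compare_cohorts stacks per-cohort inclusion values", {
  base <- sim_config(n_exons = 6, seed = 79, n_samples = 12, depth = 5000,
                     meta_only_ids = 4L,
                     isoforms = list(meta = 1:6, adult = c(1:3, 5:6)),
                     proportions = c(0.9, 0.1))
  m <- make_toy_gene(base)
  fetal <- simulate_junction_counts(m, base)
  adult_cfg <- base
  adult_cfg$proportions[] <- matrix(c(0.45, 0.55), 12, 2, byrow = TRUE)
  adult_cfg$seed <- 80L
  adult <- simulate_junction_counts(m, adult_cfg)
  cfgf <- filter_config(100L, 10L)
  tabs <- list(fetal = usage_table(m, fetal$matrix, config = cfgf),
               adult = usage_table(m, adult$matrix, config = cfgf))
  cmp <- compare_cohorts(tabs)
  expect_setequal(unique(cmp$cohort), c("fetal", "adult"))
  # the meta-only exon's inclusion halves between the cohorts
  f4 <- cmp$inclusion_rate[cmp$cohort == "fetal" & cmp$exon_id == 4L]
  a4 <- cmp$inclusion_rate[cmp$cohort == "adult" & cmp$exon_id == 4L]
  expect_lt(abs(f4 - 0.9), 0.05)
  expect_lt(abs(a4 - 0.45), 0.05)

  # identical cohorts give identical columns
  cmp2 <- compare_cohorts(list(a = tabs$fetal, b = tabs$fetal))
  expect_equal(cmp2$inclusion_rate[cmp2$cohort == "a"],
               cmp2$inclusion_rate[cmp2$cohort == "b"])

  # mismatched exon sets are an error
  other <- usage_table(make_toy_gene(sim_config(n_exons = 4, seed = 81,
                                                n_samples = 12)),
                       simulate_junction_counts(
                         make_toy_gene(sim_config(n_exons = 4, seed = 81,
                                                  n_samples = 12)),
                         sim_config(n_exons = 4, seed = 81,
                                    n_samples = 12))$matrix,
                       config = cfgf)
  expect_error(compare_cohorts(list(a = tabs$fetal, b = other)),
               "same gene model")
})

test_that("published worked examples reproduce from the packaged counts", {
  u <- ttn_usage_counts()
  rows <- !is.na(u$exclusion_reads)
  pct <- percent_round(inclusion_rate(u$inclusion_reads[rows],
                                      u$exclusion_reads[rows]))
  expect_equal(pct, u$inclusion_pct[rows])
})
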