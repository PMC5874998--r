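# builds the junction (data.frame) joining two exon boundaries of a model,
# via the package's coordinate helper
jx <- function(model, donor, acceptor, doff = 0L, aoff = 0L) {
  co <- exonusage:::junction_between(model, donor, acceptor, doff, aoff)
  data.frame(chrom = model$chromosome, intron_start = co[[1]],
             intron_end = co[[2]], strand = model$strand)
}

test_that("canonical, skipping and alternative-site junctions classify", {
  m <- synthetic_ttn_model()
  ev <- classify_junction(jx(m, 10, 11), m)
  expect_equal(ev$category, "canonical_consecutive")
  expect_equal(length(ev$skipped_exons[[1]]), 0L)

  ev <- classify_junction(jx(m, 10, 12), m)
  expect_equal(ev$category, "exon_skipping")
  expect_equal(ev$skipped_exons[[1]], 11L)
  expect_equal(ev$donor_offset_nt, 0L)

  ev <- classify_junction(jx(m, 212, 218), m)
  expect_equal(ev$category, "exon_skipping")
  expect_equal(ev$skipped_exons[[1]], 213:217)
  expect_true(ev$involves_meta_only)

  # acceptor 4 nt inside exon 6 relative to its canonical acceptor
  ev <- classify_junction(jx(m, 5, 6, aoff = 4L), m)
  expect_equal(ev$category, "alt_acceptor")
  expect_equal(ev$acceptor_offset_nt, 4L)
  expect_equal(ev$donor_offset_nt, 0L)

  ev <- classify_junction(jx(m, 5, 6, doff = -3L, aoff = 7L), m)
  expect_equal(ev$category, "alt_both")

  # repeated-region flag follows the block labels on the ends
  ev <- classify_junction(jx(m, 175, 209), m)
  expect_true(ev$in_repeated_region)
  ev <- classify_junction(jx(m, 10, 13), m)
  expect_false(ev$in_repeated_region)
})

test_that("junctions outside the gene or beyond max_offset are unassigned", {
  m <- toy_model_90_120_60("+")
  far <- data.frame(chrom = "chrT", intron_start = 50000L,
                    intron_end = 60000L, strand = "+")
  ev <- classify_junction(far, m)
  expect_equal(ev$category, "unassigned")
  expect_match(ev$note, "outside")

  other <- data.frame(chrom = "chrZ", intron_start = 1090L,
                      intron_end = 1290L, strand = "+")
  expect_equal(classify_junction(other, m)$category, "unassigned")

  shifted <- data.frame(chrom = "chrT", intron_start = 1090L + 40L,
                        intron_end = 1290L, strand = "+")
  expect_equal(classify_junction(shifted, m, max_offset = 10L)$category,
               "unassigned")
  expect_equal(classify_junction(shifted, m, max_offset = 500L)$category,
               "alt_donor")
})

test_that("equidistant boundaries tie-break to the upstream exon", {
  ex <- data.frame(exon_id = 1:3,
                   genomic_start = c(0L, 300L, 600L),
                   genomic_end = c(100L, 400L, 700L))
  m <- gene_model("tie", "chrT", "+", ex, list(metatranscript = 1:3))
  # 250 is 150 nt from exon 1's donor (100) and from exon 2's donor (400)
  ev <- classify_junction(
    data.frame(chrom = "chrT", intron_start = 250L, intron_end = 600L),
    m, max_offset = 500L)
  expect_equal(ev$donor_exon, 1L)
  expect_equal(ev$donor_offset_nt, 150L)
})

test_that("frame effect follows the net coding-sequence change", {
  cfg <- sim_config(n_exons = 6, seed = 5)
  m <- make_toy_gene(cfg, frameshift_exons = 4L)
  len <- m$exons$coding_length

  ev <- classify_junction(jx(m, 2, 4), m)  # skips exon 3 (multiple of 3)
  expect_equal(ev$frame_delta_nt, -len[3])
  expect_equal(ev$frame_preserving, "yes")

  ev <- classify_junction(jx(m, 3, 5), m)  # skips exon 4 (3k + 1)
  expect_equal(ev$frame_delta_nt, -len[4])
  expect_equal(ev$frame_preserving, "no")

  # alt acceptor 3 nt downstream of canonical: delta -3, in frame
  ev <- classify_junction(jx(m, 2, 3, aoff = 3L), m)
  expect_equal(ev$frame_delta_nt, -3L)
  expect_equal(ev$frame_preserving, "yes")

  # alt donor into the intron inserts bases
  ev <- classify_junction(jx(m, 2, 3, doff = 6L), m)
  expect_equal(ev$frame_delta_nt, 6L)

  # distant alternative site accumulates the spanned exons
  ev <- classify_junction(jx(m, 2, 5, aoff = 4L), m)
  expect_equal(ev$frame_delta_nt, -(len[3] + len[4] + 4L))

  # events touching the non-coding first exon are not_applicable
  mt <- toy_model_90_120_60("+", noncoding_first = TRUE)
  ev <- classify_junction(jx(mt, 1, 3), mt)
  expect_equal(ev$frame_preserving, "not_applicable")
})

test_that("frame deltas of disjoint skips are additive", {
  cfg <- sim_config(n_exons = 8, seed = 9)
  m <- make_toy_gene(cfg, frameshift_exons = c(3L, 6L))
  d_a <- classify_junction(jx(m, 2, 4), m)$frame_delta_nt   # skips 3
  d_b <- classify_junction(jx(m, 5, 7), m)$frame_delta_nt   # skips 6
  both <- -sum(m$exons$coding_length[c(3, 6)])
  expect_equal(d_a + d_b, both)
})

test_that("previously_reported reflects the isoform junction set", {
  m <- synthetic_ttn_model()
  evs <- classify_junctions(rbind(jx(m, 47, 50), jx(m, 10, 12)), m)
  # 47-50 is the junction unique to the skeletal N2A isoform
  expect_true(evs$previously_reported[1])
  expect_false(evs$previously_reported[2])

  m_empty <- m
  m_empty$isoforms <- list()
  evs2 <- classify_junctions(rbind(jx(m, 47, 50), jx(m, 10, 12)), m_empty)
  expect_false(any(evs2$previously_reported))
})

test_that("classification is total, deterministic, and offset-monotone", {
  cfg <- sim_config(n_exons = 7, seed = 13)
  m <- make_toy_gene(cfg)
  b <- boundary_index(m)
  set.seed(31)
  pos <- sort(unique(c(b$position,
                       as.vector(outer(b$position, sample(-60:60, 6), "+")))))
  pairs <- expand.grid(s = pos, e = pos)
  pairs <- pairs[pairs$s < pairs$e, ]
  pairs <- pairs[sample(nrow(pairs), 300), ]
  for (i in seq_len(nrow(pairs))) {
    j <- data.frame(chrom = m$chromosome, intron_start = pairs$s[i],
                    intron_end = pairs$e[i])
    e1 <- classify_junction(j, m, max_offset = 40L)
    e2 <- classify_junction(j, m, max_offset = 40L)
    expect_equal(e1$category, e2$category)
    expect_true(e1$category %in% c("canonical_consecutive", "exon_skipping",
                                   "alt_donor", "alt_acceptor", "alt_both",
                                   "unassigned"))
    # enlarging max_offset never demotes an alt_* event to unassigned
    if (startsWith(e1$category, "alt")) {
      e3 <- classify_junction(j, m, max_offset = 400L)
      expect_false(e3$category == "unassigned")
    }
  }
})

test_that("classifier agrees with the exhaustive oracle on a grid", {
  for (strand in c("+", "-")) {
    cfg <- sim_config(n_exons = 9, seed = 17, strand = strand)
    m <- make_toy_gene(cfg)
    b <- boundary_index(m)
    offs <- c(-507L, -43L, -3L, -1L, 0L, 2L, 4L, 41L, 503L)
    pos <- sort(unique(as.vector(outer(b$position, offs, `+`))))
    pairs <- expand.grid(s = pos, e = pos)
    pairs <- pairs[pairs$s < pairs$e, ]
    set.seed(19)
    pairs <- pairs[sample(nrow(pairs), 700), ]
    for (i in seq_len(nrow(pairs))) {
      s <- pairs$s[i]; e <- pairs$e[i]
      got <- classify_junction(
        data.frame(chrom = m$chromosome, intron_start = s, intron_end = e),
        m, max_offset = 500L)
      want <- bf_classify(s, e, m, max_offset = 500L)
      expect_equal(got$category, want$category,
                   info = sprintf("%s strand junction [%d,%d)", strand, s, e))
      if (want$category != "unassigned") {
        expect_equal(got$donor_exon, want$donor)
        expect_equal(got$acceptor_exon, want$acceptor)
        expect_equal(got$donor_offset_nt, want$doff)
        expect_equal(got$acceptor_offset_nt, want$aoff)
        expect_equal(got$skipped_exons[[1]], want$skipped)
      }
    }
  }
})
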