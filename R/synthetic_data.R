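# Synthetic data with known ground truth: toy gene models, isoform
# mixtures, junction count matrices, and spliced SAM records. Every
# pipeline stage can be exercised end-to-end without external data.

#' Simulation configuration
#'
#' Defaults emulate the study design the analysis was built for: a
#' 42-sample skeletal-muscle-style cohort, Poisson junction counts at an
#' expected depth of 1e4 junction-spanning reads per transcript unit,
#' and 86 bp single-end reads for SAM emission.
#'
#' @param n_exons number of exons in the toy gene.
#' @param meta_only_ids exon ids flagged meta-only.
#' @param repeat_block_spec optional `list(blocks = <labels>, copies =
#'   <k>, start_exon = <id>)`; labels are cycled over
#'   `length(blocks) * copies` consecutive exons.
#' @param isoforms named list of exon-id vectors; default two isoforms
#'   (full gene plus a single-exon skip).
#' @param proportions isoform mixing proportions: a numeric vector
#'   (shared by all samples) or an `n_samples x n_isoforms` matrix; each
#'   sample's proportions must sum to 1.
#' @param depth expected junction-spanning reads per transcript unit per
#'   sample.
#' @param n_samples number of samples.
#' @param count_noise `"poisson"` or `"negative_binomial"`.
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); ignored for Poisson.
#' @param alt_site_spec optional data.frame with columns `exon`, `side`
#'   (`"donor"`/`"acceptor"`), `offset` (signed, transcript orientation,
#'   non-zero), `fraction` (expected usage relative to depth).
#' @param read_length read length for [emit_spliced_sam()].
#' @param strand `"+"` (default) or `"-"` to exercise strand
#'   normalisation.
#' @param seed mandatory integer seed; there is no hidden global
#'   randomness.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_exons = 8L, meta_only_ids = integer(),
                       repeat_block_spec = NULL, isoforms = NULL,
                       proportions = NULL, depth = 1e4, n_samples = 42L,
                       count_noise = c("poisson", "negative_binomial"),
                       dispersion = 0.1, alt_site_spec = NULL,
                       read_length = 86L, strand = "+", seed) {
  count_noise <- match.arg(count_noise)
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(depth > 0, n_samples >= 1, n_exons >= 2)
  if (is.null(isoforms)) {
    skip_target <- max(2L, n_exons %/% 2L)
    isoforms <- list(full = seq_len(n_exons),
                     skip = setdiff(seq_len(n_exons), skip_target))
  }
  if (is.null(proportions)) {
    proportions <- rep(1 / length(isoforms), length(isoforms))
  }
  if (is.matrix(proportions)) {
    stopifnot(nrow(proportions) == n_samples,
              ncol(proportions) == length(isoforms))
    prop <- proportions
  } else {
    stopifnot(length(proportions) == length(isoforms))
    prop <- matrix(proportions, n_samples, length(isoforms), byrow = TRUE)
  }
  if (any(abs(rowSums(prop) - 1) > 1e-8)) {
    stop("isoform proportions must sum to 1 in every sample")
  }
  colnames(prop) <- names(isoforms)
  if (!is.null(alt_site_spec)) {
    stopifnot(all(c("exon", "side", "offset", "fraction") %in%
                    names(alt_site_spec)),
              all(alt_site_spec$offset != 0))
  }
  structure(list(n_exons = as.integer(n_exons),
                 meta_only_ids = as.integer(meta_only_ids),
                 repeat_block_spec = repeat_block_spec,
                 isoforms = isoforms, proportions = prop,
                 depth = depth, n_samples = as.integer(n_samples),
                 count_noise = count_noise, dispersion = dispersion,
                 alt_site_spec = alt_site_spec,
                 read_length = as.integer(read_length),
                 strand = strand, seed = as.integer(seed)),
            class = "sim_config")
}

#' Build a toy gene model from a simulation configuration
#'
#' Deterministic given the seed: exon lengths are drawn once (multiples
#' of 3 by default so single-exon skips are frame-preserving;
#' `frameshift_exons` selects exons given a length of `3k+1` instead),
#' intron lengths are drawn in 200-2000 nt, classes and repeat blocks
#' are applied as configured.
#'
#' @param config a `sim_config`.
#' @param frameshift_exons exon ids whose coding length is made
#'   non-divisible by 3.
#' @return a `gene_model` named `toy`.
#' @export
make_toy_gene <- function(config, frameshift_exons = integer()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_exons
  if (length(config$meta_only_ids) &&
      any(!config$meta_only_ids %in% seq_len(n))) {
    stop("meta_only_ids outside 1..n_exons")
  }
  set.seed(config$seed)
  len <- 3L * sample(30:100, n, replace = TRUE)
  len[frameshift_exons] <- len[frameshift_exons] + 1L
  intron <- sample(200:2000, n, replace = TRUE)
  cls <- rep("canonical", n)
  cls[config$meta_only_ids] <- "meta_only"
  blocks <- rep(NA_character_, n)
  rbs <- config$repeat_block_spec
  if (!is.null(rbs)) {
    span <- length(rbs$blocks) * rbs$copies
    start <- if (is.null(rbs$start_exon)) 1L else rbs$start_exon
    ids <- start:(start + span - 1L)
    if (any(!ids %in% seq_len(n))) {
      stop("repeat_block_spec does not fit within the gene")
    }
    blocks[ids] <- rep(rbs$blocks, rbs$copies)
  }
  starts <- integer(n); ends <- integer(n)
  if (config$strand == "+") {
    g <- 1000L
    for (i in seq_len(n)) {
      starts[i] <- g; ends[i] <- g + len[i]; g <- ends[i] + intron[i]
    }
  } else {
    g <- 1000L
    for (i in rev(seq_len(n))) {
      starts[i] <- g; ends[i] <- g + len[i]; g <- ends[i] + intron[i]
    }
  }
  exons <- data.frame(exon_id = seq_len(n), genomic_start = starts,
                      genomic_end = ends, exon_class = cls,
                      repeat_block = blocks, coding_length = len,
                      stringsAsFactors = FALSE)
  gene_model("toy", "chrS", config$strand, exons, config$isoforms,
             reference_isoform = names(config$isoforms)[1])
}

# intron interval of the junction joining exon i's donor to exon j's
# acceptor, 0-based half-open genomic coordinates
junction_between <- function(model, donor_exon, acceptor_exon,
                             donor_offset = 0L, acceptor_offset = 0L) {
  b <- model_boundaries(model)
  d <- b$donor[as.character(donor_exon)]
  a <- b$acceptor[as.character(acceptor_exon)]
  if (model$strand == "+") {
    c(intron_start = unname(d + donor_offset),
      intron_end = unname(a + acceptor_offset))
  } else {
    c(intron_start = unname(a - acceptor_offset),
      intron_end = unname(d - donor_offset))
  }
}

draw_counts <- function(mu, config) {
  if (config$count_noise == "poisson") {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
}

#' Simulate a junction count matrix with known truth
#'
#' Each isoform contributes its consecutive-exon junctions; in every
#' sample a junction's count is drawn from the configured noise model
#' with mean `depth x` (summed proportion of the isoforms carrying it).
#' Alternative-site junctions from `alt_site_spec` are added with mean
#' `depth x fraction`. The truth records, per sample, each exon's
#' inclusion probability `p` (the summed proportion of isoforms
#' containing it) and each junction's expected count.
#'
#' @param model a `gene_model` (typically [make_toy_gene()]).
#' @param config the same `sim_config`.
#' @return list with `matrix` (a `junction_counts`) and `truth` (class
#'   `sim_truth`: `p` exon x sample matrix, `expected` junction x sample
#'   matrix, `events` data.frame of the generating junctions).
#' @export
simulate_junction_counts <- function(model, config) {
  stopifnot(inherits(model, "gene_model"), inherits(config, "sim_config"))
  iso <- config$isoforms
  prop <- config$proportions
  n_s <- config$n_samples
  # generating junctions: union over isoforms, plus alt-site junctions
  jmap <- list()
  add_j <- function(key, row) {
    if (is.null(jmap[[key]])) jmap[[key]] <<- row else {
      jmap[[key]]$isoforms <<- union(jmap[[key]]$isoforms, row$isoforms)
    }
  }
  for (nm in names(iso)) {
    ids <- iso[[nm]]
    if (length(ids) < 2) next
    for (k in seq_len(length(ids) - 1L)) {
      co <- junction_between(model, ids[k], ids[k + 1L])
      key <- paste0(co[1], "_", co[2])
      add_j(key, list(intron_start = co[[1]], intron_end = co[[2]],
                      donor_exon = ids[k], acceptor_exon = ids[k + 1L],
                      donor_offset = 0L, acceptor_offset = 0L,
                      isoforms = nm, fraction = NA_real_))
    }
  }
  ass <- config$alt_site_spec
  if (!is.null(ass)) {
    for (i in seq_len(nrow(ass))) {
      e <- ass$exon[i]
      if (ass$side[i] == "donor") {
        co <- junction_between(model, e, e + 1L,
                               donor_offset = ass$offset[i])
        row <- list(intron_start = co[[1]], intron_end = co[[2]],
                    donor_exon = e, acceptor_exon = e + 1L,
                    donor_offset = as.integer(ass$offset[i]),
                    acceptor_offset = 0L,
                    isoforms = character(), fraction = ass$fraction[i])
      } else {
        co <- junction_between(model, e - 1L, e,
                               acceptor_offset = ass$offset[i])
        row <- list(intron_start = co[[1]], intron_end = co[[2]],
                    donor_exon = e - 1L, acceptor_exon = e,
                    donor_offset = 0L,
                    acceptor_offset = as.integer(ass$offset[i]),
                    isoforms = character(), fraction = ass$fraction[i])
      }
      add_j(paste0(co[1], "_", co[2]), row)
    }
  }
  jl <- jmap[order(vapply(jmap, function(r) r$intron_start, numeric(1)))]
  events <- do.call(rbind, lapply(jl, function(r) {
    data.frame(intron_start = r$intron_start, intron_end = r$intron_end,
               donor_exon = r$donor_exon, acceptor_exon = r$acceptor_exon,
               donor_offset = r$donor_offset,
               acceptor_offset = r$acceptor_offset,
               fraction = r$fraction, stringsAsFactors = FALSE)
  }))
  events$isoforms <- vapply(jl, function(r) paste(r$isoforms, collapse = ","),
                            character(1))
  rownames(events) <- NULL
  # expected counts: junction x sample
  expected <- matrix(0, nrow(events), n_s)
  for (k in seq_along(jl)) {
    r <- jl[[k]]
    if (length(r$isoforms)) {
      expected[k, ] <- expected[k, ] + config$depth *
        rowSums(prop[, r$isoforms, drop = FALSE])
    }
    if (!is.na(r$fraction)) {
      expected[k, ] <- expected[k, ] + config$depth * r$fraction
    }
  }
  set.seed(config$seed + 1L)
  counts <- matrix(as.integer(draw_counts(as.vector(expected), config)),
                   nrow(events), n_s)
  sample_ids <- sprintf("sample_%02d", seq_len(n_s))
  per_sample <- lapply(seq_len(n_s), function(s) {
    data.frame(chrom = model$chromosome,
               intron_start = events$intron_start,
               intron_end = events$intron_end,
               strand = model$strand, count = counts[, s],
               stringsAsFactors = FALSE)
  })
  names(per_sample) <- sample_ids
  jcm <- merge_samples(per_sample)
  # truth: per-exon inclusion probability per sample
  p <- matrix(0, config$n_exons, n_s,
              dimnames = list(seq_len(config$n_exons), sample_ids))
  for (nm in names(iso)) {
    p[iso[[nm]], ] <- p[iso[[nm]], ] +
      matrix(prop[, nm], length(iso[[nm]]), n_s, byrow = TRUE)
  }
  # align expected-count rows with the merged matrix ordering
  ekey <- paste0(events$intron_start, "_", events$intron_end)
  mkey <- paste0(jcm$junctions$intron_start, "_", jcm$junctions$intron_end)
  ord <- match(mkey, ekey)
  truth <- structure(
    list(p = p, expected = expected[ord, , drop = FALSE],
         events = events[ord, , drop = FALSE]),
    class = "sim_truth")
  list(matrix = jcm, truth = truth)
}

#' Emit spliced SAM records encoding a junction count matrix
#'
#' For every junction count, emits that many 86 bp (configurable)
#' single-end reads whose CIGAR encodes the junction as
#' `<a>M<intron>N<b>M`, with the anchor split `a` drawn uniformly in
#' `[min_anchor, read_length - min_anchor]`. By construction,
#' [extract_junctions()] on the emitted text reproduces the input counts
#' exactly. Reads carry an `XS:A:` strand tag.
#'
#' @param model a `gene_model` (supplies chromosome name and strand).
#' @param jcm a `junction_counts`, or a single sample's junction counts
#'   data.frame.
#' @param read_length read length in nt (must exceed `2 * min_anchor`).
#' @param min_anchor minimum anchor the reads are built to satisfy.
#' @param seed integer seed for the anchor splits.
#' @return for a `junction_counts`, a named list (per sample) of
#'   character vectors of SAM lines; for a single-sample data.frame, one
#'   character vector.
#' @export
emit_spliced_sam <- function(model, jcm, read_length = 86L, min_anchor = 8L,
                             seed = 1L) {
  if (read_length <= 2L * min_anchor) {
    stop("read_length must exceed 2 * min_anchor")
  }
  set.seed(seed)
  max_end <- max(model$exons$genomic_end) + 10000L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", model$chromosome, "\tLN:", max_end))
  one_sample <- function(df, tag) {
    df <- df[df$count > 0, , drop = FALSE]
    if (!nrow(df)) return(header)
    idx <- rep(seq_len(nrow(df)), df$count)
    a <- sample(min_anchor:(read_length - min_anchor), length(idx),
                replace = TRUE)
    st <- df$intron_start[idx]; en <- df$intron_end[idx]
    strand <- df$strand[idx]
    strand[!strand %in% c("+", "-")] <- model$strand
    pos <- st - a + 1L                      # 1-based SAM POS
    cig <- sprintf("%dM%dN%dM", a, en - st, read_length - a)
    reads <- sprintf(
      "%s_read%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tXS:A:%s",
      tag, seq_along(idx), model$chromosome, pos, cig,
      strrep("A", read_length), strand)
    c(header, reads)
  }
  if (inherits(jcm, "junction_counts")) {
    out <- lapply(seq_along(jcm$samples), function(s) {
      df <- jcm$junctions
      df$count <- jcm$counts[, s]
      one_sample(df, jcm$samples[s])
    })
    names(out) <- jcm$samples
    out
  } else {
    one_sample(jcm, "sim")
  }
}

#' Write a full simulated data set to disk
#'
#' Writes the gene-model TSV, one junction tab file per sample, one SAM
#' text per sample, and the ground truth as JSON — the on-disk shape of
#' a complete synthetic cohort.
#'
#' @param model a `gene_model`.
#' @param sim output of [simulate_junction_counts()].
#' @param dir output directory (created if needed).
#' @param sam also write SAM files (default `FALSE`; they are large).
#' @param ... passed to [emit_spliced_sam()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(model, sim, dir, sam = FALSE, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_model(model, file.path(dir, "gene_model.tsv"))
  jcm <- sim$matrix
  for (s in seq_along(jcm$samples)) {
    df <- jcm$junctions
    df$count <- jcm$counts[, s]
    write_junction_file(df[df$count > 0, , drop = FALSE],
                        file.path(dir, paste0(jcm$samples[s],
                                              ".junctions.tab")))
  }
  truth <- list(p = sim$truth$p, expected = sim$truth$expected,
                events = sim$truth$events)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  if (sam) {
    sams <- emit_spliced_sam(model, jcm, ...)
    for (s in names(sams)) {
      writeLines(sams[[s]], file.path(dir, paste0(s, ".sam")))
    }
  }
  invisible(dir)
}
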