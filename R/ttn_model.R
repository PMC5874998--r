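# Synthetic stand-in for the titin (TTN) metatranscript exon model.
# Real hg19 coordinates are deliberately not shipped; the structure
# (exon count, non-coding first exon, meta-only set, repeat region,
# isoform membership) follows the published metatranscript organisation
# while coordinates and lengths are deterministic synthetic values.

#' Meta-only exon ids of the TTN metatranscript
#'
#' Exons present in the inferred complete metatranscript but absent from
#' the canonical adult skeletal (N2A) and cardiac isoforms: 148, 150,
#' 159-171 and 213-217.
#'
#' @return integer vector of exon ordinals.
#' @export
ttn_meta_only_exons <- function() {
  sort(c(148L, 150L, 159:171, 213:217))
}

#' Synthetic TTN-like gene model
#'
#' A 364-exon minus-strand model emulating the TTN metatranscript
#' organisation: exon 1 non-coding, 363 coding exons, meta-only exons
#' per [ttn_meta_only_exons()], the repeated region spanning exons
#' 172-205 with block labels B1-B9 cycled across it, isoform-specific
#' exons 45/46/48, and isoform definitions for the metatranscript
#' (reference), the skeletal N2A isoform (lacking exons 48, 49 and all
#' meta-only exons) and the truncated Novex-3 isoform (exons 1-48).
#' Coordinates are synthetic: deterministic exon lengths (all coding
#' lengths multiples of 3) and intron sizes, so the model is identical
#' across sessions.
#'
#' @return a `gene_model`.
#' @export
synthetic_ttn_model <- function() {
  n <- 364L
  ids <- seq_len(n)
  len <- 90L + 3L * ((ids * 7L) %% 71L)
  len[1] <- 300L
  intron <- 100L + ((ids * 37L) %% 901L)
  # minus strand: transcript exon 364 sits at the lowest genomic coordinates
  starts <- integer(n); ends <- integer(n)
  g <- 10000L
  for (i in rev(ids)) {
    starts[i] <- g
    ends[i] <- g + len[i]
    g <- ends[i] + intron[i]
  }
  meta <- ttn_meta_only_exons()
  cls <- rep("canonical", n)
  cls[meta] <- "meta_only"
  cls[c(45L, 46L, 48L)] <- "isoform_specific"
  cls[1L] <- "noncoding"
  blocks <- rep(NA_character_, n)
  rep_ids <- 172:205
  blocks[rep_ids] <- paste0("B", ((seq_along(rep_ids) - 1L) %% 9L) + 1L)
  exons <- data.frame(
    exon_id = ids, genomic_start = starts, genomic_end = ends,
    exon_class = cls, repeat_block = blocks,
    coding_length = ifelse(cls == "noncoding", 0L, len),
    stringsAsFactors = FALSE)
  isoforms <- list(
    metatranscript = ids,
    N2A = setdiff(ids, c(48L, 49L, meta)),
    Novex3 = 1:48)
  gene_model("TTN", "chr2", "-", exons, isoforms,
             reference_isoform = "metatranscript")
}

#' Published per-exon inclusion/exclusion read counts for TTN
#'
#' The per-exon inclusion (I) and exclusion (E) junction read totals
#' reported for variable TTN exons in adult human skeletal muscle,
#' together with the printed integer inclusion percentages and the
#' supporting skipping-event labels. Rows sharing an exclusion figure
#' with a neighbouring block in the published table carry `NA` exclusion
#' reads here. These serve as worked-example inputs for the
#' inclusion-rate statistic (I/2)/((I/2)+E).
#'
#' @return data.frame with columns `exon`, `inclusion_pct`,
#'   `inclusion_reads`, `exclusion_reads`, `skipping_events`.
#' @export
ttn_usage_counts <- function() {
  path <- system.file("extdata", "ttn_exon_usage_counts.tsv",
                      package = "exonusage", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}
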