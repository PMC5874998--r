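# Independent brute-force oracles and small fixture builders. Each oracle
# re-derives the expected result by direct enumeration, deliberately
# sharing no code with the implementation it checks.

# --- fixture: a hand-laid plus-strand model with exon lengths 90/120/60 ---
toy_model_90_120_60 <- function(strand = "+", noncoding_first = FALSE) {
  len <- c(90L, 120L, 60L)
  starts <- if (strand == "+") c(1000L, 1290L, 1500L) else
    c(1500L, 1290L, 1000L)  # transcript exon 1 at the top coordinates
  ex <- data.frame(
    exon_id = 1:3, genomic_start = starts,
    genomic_end = starts + len,
    exon_class = c(if (noncoding_first) "noncoding" else "canonical",
                   "canonical", "canonical"),
    repeat_block = NA_character_,
    coding_length = ifelse(
      c(noncoding_first, FALSE, FALSE), 0L, len),
    stringsAsFactors = FALSE)
  gene_model("toy3", "chrT", strand, ex,
             isoforms = list(metatranscript = 1:3))
}

# --- oracle: character-walking CIGAR re-parser ------------------------------
# Returns a data.frame(intron_start, intron_end) per read, applying the
# same anchor rule by explicit block bookkeeping.
bf_cigar_junctions <- function(cigar, pos_1based, min_anchor) {
  chars <- strsplit(cigar, "")[[1]]
  num <- 0L
  ref <- pos_1based - 1L
  blocks_aligned <- 0L     # aligned bases since last N (or read start)
  pending <- list()        # junctions waiting for their right anchor
  done <- list()
  for (ch in chars) {
    if (ch >= "0" && ch <= "9") {
      num <- num * 10L + as.integer(ch)
      next
    }
    if (ch %in% c("M", "=", "X")) {
      blocks_aligned <- blocks_aligned + num
      ref <- ref + num
    } else if (ch == "D") {
      ref <- ref + num
    } else if (ch == "N") {
      for (p in pending) {
        if (p$left >= min_anchor && blocks_aligned >= min_anchor) {
          done[[length(done) + 1L]] <- p[c("intron_start", "intron_end")]
        }
      }
      pending <- list(list(intron_start = ref, intron_end = ref + num,
                           left = blocks_aligned))
      blocks_aligned <- 0L
      ref <- ref + num
    }
    # I, S, H, P consume no reference
    num <- 0L
  }
  for (p in pending) {
    if (p$left >= min_anchor && blocks_aligned >= min_anchor) {
      done[[length(done) + 1L]] <- p[c("intron_start", "intron_end")]
    }
  }
  if (!length(done)) {
    return(data.frame(intron_start = integer(), intron_end = integer()))
  }
  data.frame(intron_start = vapply(done, `[[`, numeric(1), "intron_start"),
             intron_end = vapply(done, `[[`, numeric(1), "intron_end"))
}

# tally junctions from raw SAM lines with the brute-force parser
bf_extract <- function(sam_lines, min_anchor = 8L) {
  body <- sam_lines[!startsWith(sam_lines, "@")]
  tab <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (bitwAnd(as.integer(f[2]), 4L) > 0L || f[6] == "*") next
    jx <- bf_cigar_junctions(f[6], as.integer(f[4]), min_anchor)
    if (!nrow(jx)) next
    for (k in seq_len(nrow(jx))) {
      key <- paste0(f[3], ":", jx$intron_start[k], "-", jx$intron_end[k])
      tab[[key]] <- (if (is.null(tab[[key]])) 0L else tab[[key]]) + 1L
    }
  }
  unlist(tab)
}

# --- oracle: exhaustive junction classifier --------------------------------
# Tests every (end, boundary) pairing explicitly and re-states the
# decision rules independently of the package implementation.
bf_classify <- function(s, e, model, max_offset = 500L) {
  ex <- model$exons
  plus <- model$strand == "+"
  span <- range(c(ex$genomic_start, ex$genomic_end))
  if (e <= span[1] || s >= span[2]) return(list(category = "unassigned"))
  dpos <- if (plus) s else e
  apos <- if (plus) e else s
  best <- function(pos, side) {
    hit_id <- NA_integer_; hit_off <- NA_integer_
    for (i in order(ex$exon_id)) {
      b <- if (side == "donor") {
        if (plus) ex$genomic_end[i] else ex$genomic_start[i]
      } else {
        if (plus) ex$genomic_start[i] else ex$genomic_end[i]
      }
      off <- if (plus) pos - b else b - pos
      if (is.na(hit_off) || abs(off) < abs(hit_off)) {
        hit_id <- ex$exon_id[i]; hit_off <- off
      }
    }
    list(id = hit_id, off = as.integer(hit_off))
  }
  d <- best(dpos, "donor"); a <- best(apos, "acceptor")
  if (abs(d$off) > max_offset || abs(a$off) > max_offset) {
    return(list(category = "unassigned"))
  }
  if (d$off == 0L && a$off == 0L) {
    if (a$id <= d$id) return(list(category = "unassigned"))
    ref <- model$isoforms[[model$reference_isoform]]
    pd <- match(d$id, ref); pa <- match(a$id, ref)
    consec <- (!is.na(pd) && !is.na(pa) && pa == pd + 1L) ||
      a$id == d$id + 1L
    if (consec) {
      return(list(category = "canonical_consecutive", donor = d$id,
                  acceptor = a$id, doff = 0L, aoff = 0L,
                  skipped = integer()))
    }
    return(list(category = "exon_skipping", donor = d$id, acceptor = a$id,
                doff = 0L, aoff = 0L,
                skipped = ex$exon_id[ex$exon_id > d$id & ex$exon_id < a$id]))
  }
  cat_ <- if (d$off != 0L && a$off != 0L) "alt_both"
    else if (d$off != 0L) "alt_donor" else "alt_acceptor"
  list(category = cat_, donor = d$id, acceptor = a$id,
       doff = d$off, aoff = a$off, skipped = integer())
}

# --- oracle: consensus-value scorer ----------------------------------------
# Loop-based evaluation of the min-max-normalised position-frequency sum.
bf_consensus <- function(sequence, freq) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  raw <- 0; raw_min <- 0; raw_max <- 0
  for (i in seq_len(nrow(freq))) {
    b <- bases[i]
    if (!b %in% c("A", "C", "G", "T")) return(NA_real_)
    raw <- raw + freq[i, b]
    raw_min <- raw_min + min(freq[i, ])
    raw_max <- raw_max + max(freq[i, ])
  }
  100 * (raw - raw_min) / (raw_max - raw_min)
}

# --- fixture: a junction_counts matrix with prescribed totals ---------------
# row i carries the given total spread over the given number of samples
matrix_with <- function(totals, detected, n_samples = 42L) {
  per_sample <- lapply(seq_len(n_samples), function(s) {
    rows <- lapply(seq_along(totals), function(i) {
      if (s > detected[i]) return(NULL)
      base <- totals[i] %/% detected[i]
      extra <- if (s <= totals[i] %% detected[i]) 1L else 0L
      data.frame(chrom = "chr2", intron_start = 100L * i,
                 intron_end = 100L * i + 50L, strand = "+",
                 count = base + extra)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) {
      return(data.frame(chrom = character(), intron_start = integer(),
                        intron_end = integer(), strand = character(),
                        count = integer()))
    }
    do.call(rbind, rows)
  })
  names(per_sample) <- sprintf("s%02d", seq_len(n_samples))
  merge_samples(per_sample)
}

# random nucleotide window
random_window <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
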