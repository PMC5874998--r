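# Junction extraction from spliced alignments, junction-file I/O, and
# merging per-sample counts into a junction x sample matrix.
#
# A junction is the intron excised by a splicing event, stored as a
# 0-based half-open genomic interval [intron_start, intron_end).

junction_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d(%s)", chrom, start, end, strand)
}

empty_junction_counts <- function() {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(),
             count = integer(), stringsAsFactors = FALSE)
}

# aggregate duplicate (chrom,start,end,strand) rows by summing counts
aggregate_junctions <- function(df, warn_duplicates = FALSE) {
  if (!nrow(df)) return(empty_junction_counts())
  key <- junction_key(df$chrom, df$intron_start, df$intron_end, df$strand)
  if (anyDuplicated(key)) {
    if (warn_duplicates) {
      warning("duplicate junction entries summed (",
              sum(duplicated(key)), " line(s))")
    }
    agg <- rowsum(df$count, key)
    first <- df[!duplicated(key), , drop = FALSE]
    first$count <- as.integer(agg[junction_key(first$chrom,
                                               first$intron_start,
                                               first$intron_end,
                                               first$strand), 1])
    df <- first
  }
  df <- df[order(df$chrom, df$intron_start, df$intron_end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract splice junctions from spliced SAM alignments
#'
#' Each `N` operation in a read's CIGAR yields one junction whose intron
#' interval is obtained by walking the reference-consuming operations
#' (`M`, `D`, `N`, `=`, `X`) from the 1-based alignment position;
#' insertions and clips do not advance the reference. A read supports a
#' junction only when the aligned blocks (`M`/`=`/`X` bases) immediately
#' flanking the `N` span at least `min_anchor` nucleotides on both sides;
#' reads with several `N` operations contribute one junction per gap.
#' Junction strand is taken from an `XS:A:` tag when present, `*`
#' otherwise (the gene model supplies strand at classification time).
#'
#' @param sam character vector of SAM lines, or a path to a SAM text file.
#'   Header lines (`@`) and unmapped records (flag 0x4, or `*` reference)
#'   are skipped.
#' @param min_anchor minimum aligned overhang on each side of a gap
#'   (default 8 nt).
#' @return per-sample junction counts: data.frame with columns `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `count`, plus attribute
#'   `diagnostics` (records seen / unmapped / malformed-CIGAR tallies).
#'   Malformed CIGARs are skipped with a warning.
#' @export
extract_junctions <- function(sam, min_anchor = 8L) {
  if (length(sam) == 1 && !grepl("\t", sam) && file.exists(sam)) {
    sam <- readLines(sam)
  }
  lines <- sam[!startsWith(sam, "@") & nzchar(sam)]
  diag <- c(records = length(lines), unmapped = 0L, malformed_cigar = 0L)
  rows <- vector("list", length(lines))
  n_bad <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) {
      n_bad <- n_bad + 1L
      next
    }
    flag <- suppressWarnings(as.integer(f[2]))
    rname <- f[3]
    pos <- suppressWarnings(as.integer(f[4]))
    cigar <- f[6]
    if (is.na(flag) || rname == "*" || bitwAnd(flag, 4L) > 0L ||
        cigar == "*") {
      diag["unmapped"] <- diag["unmapped"] + 1L
      next
    }
    if (is.na(pos) || pos < 1L) stop("negative or missing POS at record ", i)
    strand <- "*"
    xs <- grep("^XS:A:", f[-(1:11)], value = TRUE)
    if (length(xs)) strand <- substring(xs[1], 6, 6)
    jx <- cigar_junctions(cigar, pos, min_anchor)
    if (is.null(jx)) {
      diag["malformed_cigar"] <- diag["malformed_cigar"] + 1L
      warning("malformed CIGAR '", cigar, "' at record ", i, "; skipped")
      next
    }
    if (nrow(jx)) {
      jx$chrom <- rname
      jx$strand <- strand
      rows[[i]] <- jx
    }
  }
  if (n_bad) warning(n_bad, " truncated SAM record(s) skipped")
  diag["malformed_cigar"] <- diag["malformed_cigar"] + n_bad
  all <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- if (is.null(all)) empty_junction_counts() else {
    all$count <- 1L
    aggregate_junctions(all[, c("chrom", "intron_start", "intron_end",
                                "strand", "count")])
  }
  attr(out, "diagnostics") <- diag
  out
}

# Walk one CIGAR; returns data.frame(intron_start, intron_end) in 0-based
# half-open coordinates for every N gap passing the anchor rule, or NULL
# when the CIGAR is malformed.
cigar_junctions <- function(cigar, pos_1based, min_anchor) {
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) return(NULL)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  ref_consuming <- kinds %in% c("M", "D", "N", "=", "X")
  aligned <- kinds %in% c("M", "=", "X")
  n_idx <- which(kinds == "N")
  if (!length(n_idx)) {
    return(data.frame(intron_start = integer(), intron_end = integer()))
  }
  # aligned bases in each segment between consecutive N ops
  seg <- cumsum(c(0L, (kinds == "N")[-length(kinds)]))  # segment index per op
  seg_aligned <- vapply(split(lens[aligned], seg[aligned]), sum, integer(1))
  seg_levels <- as.integer(names(seg_aligned))
  aligned_in_seg <- function(s) {
    hit <- match(s, seg_levels)
    if (is.na(hit)) 0L else seg_aligned[hit]
  }
  ref_pos <- pos_1based - 1L + cumsum(c(0L, ifelse(ref_consuming, lens, 0L)))
  out <- lapply(n_idx, function(k) {
    left <- aligned_in_seg(seg[k])
    right <- aligned_in_seg(seg[k] + 1L)
    if (left < min_anchor || right < min_anchor) return(NULL)
    data.frame(intron_start = ref_pos[k], intron_end = ref_pos[k] + lens[k])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(intron_start = integer(), intron_end = integer()))
  }
  do.call(rbind, out)
}

#' Read a junction count file
#'
#' Two dialects are supported. `"tab"` is the regtools-style table
#' `chrom  intron_start  intron_end  strand  count` (0-based half-open
#' intron coordinates, header optional). `"bed"` is BED12, where each
#' line's blocks are converted to intron intervals (consecutive blocks
#' `[s1,e1)`, `[s2,e2)` yield the intron `[e1, s2)`) and the score column
#' carries the read count.
#'
#' @param path input path.
#' @param dialect `"tab"` or `"bed"`.
#' @return junction counts data.frame as in [extract_junctions()].
#'   Duplicate junction lines are summed with a warning; coordinate order
#'   violations raise an error naming the offending line.
#' @export
read_junction_file <- function(path, dialect = c("tab", "bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (dialect == "tab") {
    if (length(lines) && grepl("^chrom\t", lines[1])) lines <- lines[-1]
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 5) stop("line ", i, ": expected 5 tab fields")
      s <- as.integer(f[2]); e <- as.integer(f[3])
      if (is.na(s) || is.na(e) || s >= e) {
        stop("line ", i, ": intron_start must be < intron_end")
      }
      data.frame(chrom = f[1], intron_start = s, intron_end = e,
                 strand = f[4], count = as.integer(f[5]),
                 stringsAsFactors = FALSE)
    })
  } else {
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 12) stop("line ", i, ": expected BED12 (12 fields)")
      chrom_start <- as.integer(f[2])
      count <- as.integer(f[5])
      strand <- f[6]
      nblk <- as.integer(f[10])
      sizes <- as.integer(strsplit(f[11], ",")[[1]])[seq_len(nblk)]
      offs <- as.integer(strsplit(f[12], ",")[[1]])[seq_len(nblk)]
      if (nblk < 2) return(NULL)
      if (any(diff(offs) <= 0)) stop("line ", i, ": block starts not increasing")
      starts <- chrom_start + offs
      ends <- starts + sizes
      if (any(ends[-nblk] >= starts[-1])) {
        stop("line ", i, ": BED blocks overlap or touch")
      }
      data.frame(chrom = f[1], intron_start = ends[-nblk],
                 intron_end = starts[-1], strand = strand, count = count,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
  }
  df <- if (length(rows)) do.call(rbind, rows) else empty_junction_counts()
  aggregate_junctions(df, warn_duplicates = TRUE)
}

#' Write junction counts in the tab dialect
#'
#' Round-trips exactly with `read_junction_file(path, "tab")`.
#'
#' @param counts junction counts data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_file <- function(counts, path) {
  utils::write.table(
    counts[, c("chrom", "intron_start", "intron_end", "strand", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Merge per-sample junction counts into a junction x sample matrix
#'
#' Takes the union of junctions over all samples, filling absent counts
#' with zero. A junction's "samples detected" is the number of samples
#' with a non-zero count; together with the row total these back the
#' multi-sample QC filter.
#'
#' @param per_sample named list of junction counts data.frames (names are
#'   sample ids; unnamed lists get `sample_1 ...`). Empty samples are
#'   retained as all-zero columns.
#' @return an object of class `junction_counts`: list with `junctions`
#'   (data.frame chrom/intron_start/intron_end/strand), `samples`,
#'   and `counts` (integer matrix, junctions x samples).
#' @export
merge_samples <- function(per_sample) {
  stopifnot(length(per_sample) >= 1)
  if (is.null(names(per_sample)) || any(!nzchar(names(per_sample)))) {
    names(per_sample) <- paste0("sample_", seq_along(per_sample))
  }
  if (anyDuplicated(names(per_sample))) {
    stop("duplicate sample id(s): ",
         paste(unique(names(per_sample)[duplicated(names(per_sample))]),
               collapse = ", "))
  }
  keyed <- lapply(per_sample, function(df) {
    if (!nrow(df)) return(stats::setNames(integer(), character()))
    stats::setNames(df$count, junction_key(df$chrom, df$intron_start,
                                           df$intron_end, df$strand))
  })
  all_rows <- do.call(rbind, lapply(per_sample, function(df) {
    df[, c("chrom", "intron_start", "intron_end", "strand"), drop = FALSE]
  }))
  if (is.null(all_rows) || !nrow(all_rows)) {
    junctions <- empty_junction_counts()[, 1:4]
  } else {
    key <- junction_key(all_rows$chrom, all_rows$intron_start,
                        all_rows$intron_end, all_rows$strand)
    junctions <- all_rows[!duplicated(key), , drop = FALSE]
    junctions <- junctions[order(junctions$chrom, junctions$intron_start,
                                 junctions$intron_end), , drop = FALSE]
    rownames(junctions) <- NULL
  }
  keys <- junction_key(junctions$chrom, junctions$intron_start,
                       junctions$intron_end, junctions$strand)
  counts <- matrix(0L, nrow = nrow(junctions), ncol = length(per_sample),
                   dimnames = list(keys, names(per_sample)))
  for (s in names(per_sample)) {
    v <- keyed[[s]]
    if (length(v)) counts[names(v), s] <- as.integer(v)
  }
  structure(list(junctions = junctions, samples = names(per_sample),
                 counts = counts),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat("junction_counts:", nrow(x$junctions), "junctions x",
      length(x$samples), "samples; total reads",
      format(sum(x$counts), big.mark = ","), "\n")
  invisible(x)
}

#' Row totals and detection counts of a junction matrix
#'
#' @param jcm a `junction_counts` object.
#' @return data.frame: junction columns plus `total_reads` and
#'   `samples_detected`.
#' @export
junction_totals <- function(jcm) {
  out <- jcm$junctions
  out$total_reads <- as.integer(rowSums(jcm$counts))
  out$samples_detected <- as.integer(rowSums(jcm$counts > 0))
  out
}

#' Write a junction x sample count matrix as TSV
#'
#' Junction key columns followed by one column per sample.
#'
#' @param jcm a `junction_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_matrix <- function(jcm, path) {
  out <- cbind(jcm$junctions, as.data.frame(jcm$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
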