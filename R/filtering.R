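# Two-stage QC of splicing events: discovery-cohort read-support and
# sample-recurrence thresholds, then cross-cohort validation against an
# independent data set.

#' QC filter configuration
#'
#' Defaults follow the published thresholds for a 42-sample discovery
#' cohort: a splicing event is kept when supported by at least 1000 reads
#' in total and detected (count > 0) in at least 14 samples; a kept event
#' is validated when the validation cohort supplies strictly more than 10
#' reads (i.e. at least `validation_min_reads = 11`).
#'
#' @param min_total_reads minimum pooled read support (inclusive).
#' @param min_samples minimum number of samples with a non-zero count
#'   (inclusive).
#' @param validation_min_reads minimum pooled validation-cohort reads
#'   (inclusive; 11 encodes "more than 10").
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_total_reads = 1000L, min_samples = 14L,
                          validation_min_reads = 11L) {
  stopifnot(min_total_reads >= 0, min_samples >= 0,
            validation_min_reads >= 0)
  structure(list(min_total_reads = as.integer(min_total_reads),
                 min_samples = as.integer(min_samples),
                 validation_min_reads = as.integer(validation_min_reads)),
            class = "filter_config")
}

#' Read a QC filter configuration from a key-value file
#'
#' Plain `key = value` or `key: value` lines; recognised keys are the
#' fields of [filter_config()]. Unknown keys raise an error.
#'
#' @param path file path.
#' @return a `filter_config`.
#' @export
read_filter_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "[:=]")
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- as.integer(trimws(vapply(kv, `[`, character(1), 2)))
  allowed <- c("min_total_reads", "min_samples", "validation_min_reads")
  bad <- setdiff(keys, allowed)
  if (length(bad)) stop("unknown filter config key(s): ",
                        paste(bad, collapse = ", "))
  cfg <- filter_config()
  cfg[keys] <- vals
  do.call(filter_config, unclass(cfg))
}

#' Discovery-cohort QC filter
#'
#' A junction passes when its pooled read total is at least
#' `min_total_reads` AND it is detected in at least `min_samples`
#' samples. Diagnostics are emitted for every junction, failures
#' included.
#'
#' @param jcm a `junction_counts` matrix.
#' @param config a `filter_config`.
#' @return list with `pass` (logical vector aligned with the matrix
#'   rows) and `diagnostics` (junction columns + `total_reads`,
#'   `samples_detected`, `pass`). Warns (without erroring) when
#'   `min_samples` exceeds the number of samples, in which case nothing
#'   can pass.
#' @export
qc_filter <- function(jcm, config = filter_config()) {
  stopifnot(inherits(jcm, "junction_counts"))
  if (config$min_samples > length(jcm$samples)) {
    warning("min_samples (", config$min_samples,
            ") exceeds the number of samples (", length(jcm$samples),
            "); no junction can pass")
  }
  d <- junction_totals(jcm)
  d$pass <- d$total_reads >= config$min_total_reads &
    d$samples_detected >= config$min_samples
  list(pass = d$pass, diagnostics = d)
}

#' Cross-cohort validation of QC-passing junctions
#'
#' A passing junction is validated when the validation cohort supports
#' it with at least `validation_min_reads` pooled reads (strictly more
#' than 10 under the defaults); junctions absent from the validation
#' data, or below the cut, are preserved in the `unvalidated` remainder
#' rather than discarded. Validated and unvalidated sets partition the
#' QC-passing set.
#'
#' @param passing data.frame of QC-passing junctions (columns `chrom`,
#'   `intron_start`, `intron_end`, `strand`), e.g. the passing rows of
#'   [qc_filter()] diagnostics.
#' @param validation_counts validation-cohort junction totals: either a
#'   junction counts data.frame (counts pooled over its samples) or a
#'   `junction_counts` object.
#' @param config a `filter_config`.
#' @return list with data.frames `validated` and `unvalidated`, each the
#'   input rows plus a `validation_reads` column.
#' @export
cross_cohort_validate <- function(passing, validation_counts,
                                  config = filter_config()) {
  if (inherits(validation_counts, "junction_counts")) {
    validation_counts <- junction_totals(validation_counts)
    validation_counts$count <- validation_counts$total_reads
  }
  if (!nrow(validation_counts)) {
    warning("empty validation set; no junction can be validated")
  }
  # match on coordinates only: discovery junctions extracted from SAM may
  # carry '*' strand while validation files are stranded
  coord_key <- function(df) {
    sprintf("%s:%d-%d", df$chrom, df$intron_start, df$intron_end)
  }
  vkey <- if (nrow(validation_counts)) {
    tapply(validation_counts$count, coord_key(validation_counts), sum)
  } else stats::setNames(integer(), character())
  keys <- coord_key(passing)
  vr <- vkey[keys]
  vr[is.na(vr)] <- 0L
  passing$validation_reads <- as.integer(vr)
  ok <- passing$validation_reads >= config$validation_min_reads
  list(validated = passing[ok, , drop = FALSE],
       unvalidated = passing[!ok, , drop = FALSE])
}
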