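# Per-exon inclusion/exclusion read support and the inclusion-rate
# statistic (a PSI-like value), with constitutive/variable categorisation
# and cross-cohort comparison.

#' Exon inclusion rate
#'
#' The inclusion rate is `(I/d) / ((I/d) + E)`, where `I` is the number
#' of reads supporting the exon's inclusion (all junctions going into
#' and exiting the exon), `E` the number of reads from junctions
#' spanning over it, and `d` the number of flanks the exon can have
#' (`divisor = 2` for internal exons; terminal exons, which can only
#' ever collect inclusion reads on one side, use `divisor = 1` so the
#' estimator stays unbiased).
#'
#' With `I = E = 0` the rate is undefined and `NA` is returned — never
#' 0 or 1.
#'
#' @param I inclusion reads (non-negative).
#' @param E exclusion reads (non-negative).
#' @param divisor number of available flanks (1 or 2; default 2).
#' @return numeric in `[0, 1]`, or `NA` when there is no data.
#'   Vectorised over `I`, `E` and `divisor`.
#' @export
inclusion_rate <- function(I, E, divisor = 2) {
  stopifnot(all(I >= 0, na.rm = TRUE), all(E >= 0, na.rm = TRUE),
            all(divisor %in% c(1, 2)))
  half <- I / divisor
  out <- half / (half + E)
  out[I + E == 0] <- NA_real_
  out
}

#' Round a rate to an integer percentage
#'
#' Half-away-from-zero rounding to the nearest integer percent, matching
#' the published presentation of inclusion values.
#'
#' @param rate numeric rate(s) in `[0, 1]`.
#' @return integer percent(s); `NA` propagates.
#' @export
percent_round <- function(rate) {
  as.integer(floor(rate * 100 + 0.5))
}

#' Inclusion and exclusion read support of one exon
#'
#' `I` sums the counts of junctions whose donor or acceptor lies at or
#' within the exon (alternative-site junctions landing inside the exon
#' support its partial inclusion and count toward `I`); `E` sums the
#' counts of junctions strictly spanning the exon in transcript
#' orientation — a multi-exon skipping junction contributes its full
#' count to the `E` of every exon it spans.
#'
#' @param exon_id exon ordinal.
#' @param events classified events data.frame ([classify_junctions()]),
#'   row-aligned with `counts`.
#' @param counts per-junction read totals (numeric vector).
#' @param model a `gene_model` (for event labels).
#' @return list with `I`, `E`, and `supporting_skip_events` (labels of
#'   the spanning junctions).
#' @export
exon_support <- function(exon_id, events, counts, model) {
  assigned <- events$category != "unassigned"
  touches <- assigned &
    ((!is.na(events$donor_exon) & events$donor_exon == exon_id) |
       (!is.na(events$acceptor_exon) & events$acceptor_exon == exon_id))
  spans <- assigned &
    !is.na(events$donor_exon) & !is.na(events$acceptor_exon) &
    events$donor_exon < exon_id & events$acceptor_exon > exon_id
  list(I = sum(counts[touches]),
       E = sum(counts[spans]),
       supporting_skip_events =
         if (any(spans)) event_labels(events[spans, , drop = FALSE], model)
         else character())
}

#' Per-exon usage table
#'
#' For every coding exon (by default excluding exons carrying a
#' repeat-block label, where short-read support is ambiguous) computes
#' inclusion/exclusion read support over the QC-passing junctions and
#' the inclusion rate, and assigns a category:
#'
#' * `constitutively_expressed` — inclusion junctions detected and no
#'   passing junction spans the exon;
#' * `constitutively_spliced_out` — no passing junction touches the
#'   exon, but spanning evidence exists;
#' * `variable` — both kinds of evidence pass QC; the rate quantifies
#'   the balance;
#' * `no_data` — no passing junction evidence at all (rate `NA`).
#'
#' The constitutive labels are structural (absence of passing contrary
#' evidence), not rate cut-offs.
#'
#' @param model a `gene_model`.
#' @param jcm a `junction_counts` matrix.
#' @param events classified events row-aligned with `jcm`
#'   (default: computed here).
#' @param config a `filter_config`; set `apply_filter = FALSE` to use
#'   all junctions regardless of QC.
#' @param include_repeats include exons with a repeat-block label
#'   (default `FALSE`; their values are biased by ambiguous mapping).
#' @param apply_filter apply [qc_filter()] before counting
#'   (default `TRUE`).
#' @return data.frame of class `exon_usage`: `exon_id`, `exon_class`,
#'   `inclusion_reads`, `exclusion_reads`, `inclusion_rate`,
#'   `inclusion_pct`, `category`, `skipping_events`.
#' @export
usage_table <- function(model, jcm, events = NULL,
                        config = filter_config(),
                        include_repeats = FALSE, apply_filter = TRUE) {
  if (is.null(events)) events <- classify_junctions(jcm, model)
  stopifnot(nrow(events) == nrow(jcm$junctions))
  totals <- as.numeric(rowSums(jcm$counts))
  keep <- if (apply_filter) qc_filter(jcm, config)$pass else
    rep(TRUE, nrow(events))
  ev <- events[keep, , drop = FALSE]
  cnt <- totals[keep]
  ex <- model$exons
  sel <- ex$coding_length > 0
  if (!include_repeats) sel <- sel & is.na(ex$repeat_block)
  ids <- ex$exon_id[sel]
  n_model <- nrow(ex)
  rows <- lapply(ids, function(e) {
    s <- exon_support(e, ev, cnt, model)
    divisor <- if (e == ex$exon_id[1] || e == ex$exon_id[n_model]) 1 else 2
    rate <- inclusion_rate(s$I, s$E, divisor)
    category <- if (s$I == 0 && s$E == 0) "no_data"
      else if (s$E == 0) "constitutively_expressed"
      else if (s$I == 0) "constitutively_spliced_out"
      else "variable"
    data.frame(exon_id = e,
               exon_class = ex$exon_class[match(e, ex$exon_id)],
               inclusion_reads = s$I, exclusion_reads = s$E,
               inclusion_rate = rate,
               inclusion_pct = percent_round(rate),
               category = category,
               skipping_events = paste(s$supporting_skip_events,
                                       collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exon_usage", "data.frame")
  out
}

#' Compare exon usage across cohorts
#'
#' Stacks per-cohort usage tables (computed against the same gene model)
#' into a long-format table of per-exon inclusion values, suitable for
#' heatmap rendering or reporting. Exons without data in a cohort
#' propagate `NA`.
#'
#' @param usage_tables named list of `exon_usage` tables.
#' @return data.frame with columns `cohort`, `exon_id`, `exon_class`,
#'   `inclusion_rate`, `inclusion_pct`, `category`.
#' @export
compare_cohorts <- function(usage_tables) {
  stopifnot(length(usage_tables) >= 1, !is.null(names(usage_tables)))
  ids <- lapply(usage_tables, function(u) u$exon_id)
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("usage tables cover different exon sets; ",
         "cohorts must be computed against the same gene model")
  }
  out <- do.call(rbind, lapply(names(usage_tables), function(nm) {
    u <- usage_tables[[nm]]
    data.frame(cohort = nm, exon_id = u$exon_id,
               exon_class = u$exon_class,
               inclusion_rate = u$inclusion_rate,
               inclusion_pct = u$inclusion_pct,
               category = u$category, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot a cohort-by-exon inclusion heatmap
#'
#' Base-graphics image of inclusion rates (exons on the x axis, cohorts
#' on the y axis); a light convenience around [compare_cohorts()].
#'
#' @param comparison output of [compare_cohorts()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the rate matrix drawn.
#' @export
plot_usage_heatmap <- function(comparison, ...) {
  cohorts <- unique(comparison$cohort)
  exons <- sort(unique(comparison$exon_id))
  m <- matrix(NA_real_, length(exons), length(cohorts),
              dimnames = list(exons, cohorts))
  m[cbind(match(comparison$exon_id, exons),
          match(comparison$cohort, cohorts))] <- comparison$inclusion_rate
  graphics::image(x = seq_along(exons), y = seq_along(cohorts), z = m,
                  xlab = "exon", ylab = "", axes = FALSE, zlim = c(0, 1),
                  ...)
  graphics::axis(1, at = pretty(seq_along(exons)))
  graphics::axis(2, at = seq_along(cohorts), labels = cohorts, las = 2)
  invisible(m)
}

#' Write a usage table as TSV
#'
#' @param usage an `exon_usage` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(usage, path) {
  utils::write.table(usage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
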