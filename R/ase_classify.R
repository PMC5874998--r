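# Classification of observed junctions against a gene model: canonical
# junctions, exon skipping, alternative donor/acceptor usage, plus
# reading-frame prediction and known-isoform annotation.

EVENT_CATEGORIES <- c("canonical_consecutive", "exon_skipping", "alt_donor",
                      "alt_acceptor", "alt_both", "unassigned")

# donor/acceptor boundary coordinates per exon, transcript orientation
model_boundaries <- function(model) {
  ex <- model$exons
  if (model$strand == "+") {
    list(donor = stats::setNames(ex$genomic_end, ex$exon_id),
         acceptor = stats::setNames(ex$genomic_start, ex$exon_id))
  } else {
    list(donor = stats::setNames(ex$genomic_start, ex$exon_id),
         acceptor = stats::setNames(ex$genomic_end, ex$exon_id))
  }
}

# signed transcript-orientation offset from position to each boundary:
# positive = downstream of the boundary in transcript direction
signed_offsets <- function(pos, boundaries, strand) {
  if (strand == "+") pos - boundaries else boundaries - pos
}

# nearest boundary by absolute offset; ties go to the upstream
# (smaller-ordinal) exon
nearest_boundary <- function(pos, boundaries, strand) {
  off <- signed_offsets(pos, boundaries, strand)
  ids <- as.integer(names(boundaries))
  ord <- order(abs(off), ids)
  k <- ord[1]
  list(exon_id = ids[k], offset = as.integer(off[k]))
}

#' Classify one junction against a gene model
#'
#' The junction's intron endpoints are mapped to transcript orientation
#' (its donor side is the intron start on the plus strand, the intron end
#' on the minus strand) and compared against the model's canonical
#' donor/acceptor boundaries:
#'
#' * both ends match canonical boundaries of exons i < j: consecutive in
#'   the reference isoform -> `canonical_consecutive`, otherwise
#'   `exon_skipping` with `skipped_exons` = every model exon strictly
#'   between i and j (meta-only exons included);
#' * an end within `max_offset` of its nearest boundary but not on it ->
#'   `alt_donor` / `alt_acceptor` / `alt_both`, with signed offsets
#'   (positive = downstream of the canonical boundary in transcript
#'   direction, e.g. +4 for an acceptor 4 nt inside the exon);
#' * an end farther than `max_offset` from every boundary, or a junction
#'   outside the gene span or on another chromosome -> `unassigned`
#'   (with a `note`, never an error).
#'
#' Ties between equidistant boundaries resolve to the upstream
#' (smaller-ordinal) exon.
#'
#' @param junction one-row data.frame (or list) with `chrom`,
#'   `intron_start`, `intron_end` (0-based half-open), `strand` optional.
#' @param model a `gene_model`.
#' @param max_offset maximum distance (nt) from a canonical boundary for
#'   an alternative-site call (default 500).
#' @return a one-row data.frame of class `splice_event` with fields
#'   `category`, `donor_exon`, `acceptor_exon`, `skipped_exons`
#'   (list column), `donor_offset_nt`, `acceptor_offset_nt`,
#'   `frame_preserving`, `frame_delta_nt`, `involves_meta_only`,
#'   `in_repeated_region`, `previously_reported`, `note`.
#' @export
classify_junction <- function(junction, model, max_offset = 500L) {
  j <- as.list(junction)
  ev <- data.frame(
    chrom = j$chrom, intron_start = as.integer(j$intron_start),
    intron_end = as.integer(j$intron_end),
    strand = if (is.null(j$strand)) model$strand else j$strand,
    category = "unassigned",
    donor_exon = NA_integer_, acceptor_exon = NA_integer_,
    donor_offset_nt = NA_integer_, acceptor_offset_nt = NA_integer_,
    frame_preserving = "not_applicable", frame_delta_nt = NA_integer_,
    involves_meta_only = FALSE, in_repeated_region = FALSE,
    previously_reported = FALSE, note = NA_character_,
    stringsAsFactors = FALSE)
  ev$skipped_exons <- list(integer())
  ev <- structure(ev, class = c("splice_event", "data.frame"))

  if (!is.null(j$chrom) && !is.na(j$chrom) && j$chrom != model$chromosome) {
    ev$note <- "junction on a different chromosome"
    return(ev)
  }
  ex <- model$exons
  span <- range(c(ex$genomic_start, ex$genomic_end))
  if (ev$intron_end <= span[1] || ev$intron_start >= span[2]) {
    ev$note <- "junction outside the gene span"
    return(ev)
  }
  b <- model_boundaries(model)
  if (model$strand == "+") {
    donor_pos <- ev$intron_start; acceptor_pos <- ev$intron_end
  } else {
    donor_pos <- ev$intron_end; acceptor_pos <- ev$intron_start
  }
  don <- nearest_boundary(donor_pos, b$donor, model$strand)
  acc <- nearest_boundary(acceptor_pos, b$acceptor, model$strand)
  if (abs(don$offset) > max_offset || abs(acc$offset) > max_offset) {
    ev$note <- "end(s) farther than max_offset from any canonical boundary"
    return(ev)
  }
  ev$donor_exon <- don$exon_id
  ev$acceptor_exon <- acc$exon_id
  ev$donor_offset_nt <- don$offset
  ev$acceptor_offset_nt <- acc$offset
  if (don$offset == 0L && acc$offset == 0L) {
    if (acc$exon_id <= don$exon_id) {
      ev$category <- "unassigned"
      ev$donor_exon <- NA_integer_; ev$acceptor_exon <- NA_integer_
      ev$donor_offset_nt <- NA_integer_; ev$acceptor_offset_nt <- NA_integer_
      ev$note <- "acceptor not downstream of donor in transcript orientation"
      return(ev)
    }
    ref <- model$isoforms[[model$reference_isoform]]
    pos_d <- match(don$exon_id, ref); pos_a <- match(acc$exon_id, ref)
    consecutive <- (!is.na(pos_d) && !is.na(pos_a) && pos_a == pos_d + 1L) ||
      acc$exon_id == don$exon_id + 1L
    if (consecutive) {
      ev$category <- "canonical_consecutive"
    } else {
      ev$category <- "exon_skipping"
      ev$skipped_exons <- list(
        ex$exon_id[ex$exon_id > don$exon_id & ex$exon_id < acc$exon_id])
    }
  } else if (don$offset != 0L && acc$offset != 0L) {
    ev$category <- "alt_both"
  } else if (don$offset != 0L) {
    ev$category <- "alt_donor"
  } else {
    ev$category <- "alt_acceptor"
  }
  touched <- c(ev$donor_exon, ev$acceptor_exon, ev$skipped_exons[[1]])
  cls <- ex$exon_class[match(touched, ex$exon_id)]
  ev$involves_meta_only <- any(cls == "meta_only", na.rm = TRUE)
  ends_blocks <- ex$repeat_block[match(c(ev$donor_exon, ev$acceptor_exon),
                                       ex$exon_id)]
  ev$in_repeated_region <- any(!is.na(ends_blocks))
  fr <- frame_effect(ev, model)
  ev$frame_preserving <- fr$frame_preserving
  ev$frame_delta_nt <- fr$delta_nt
  ev
}

#' Classify every junction of a set
#'
#' Vectorised wrapper over [classify_junction()]; rows align with the
#' input order (and hence with the rows of a `junction_counts` matrix).
#'
#' @param junctions data.frame with `chrom`, `intron_start`, `intron_end`
#'   (and optionally `strand`), or a `junction_counts` object.
#' @param model a `gene_model`.
#' @param max_offset see [classify_junction()].
#' @return data.frame of splice events, one row per junction, with the
#'   reference-isoform annotation of [annotate_reported()] applied.
#' @export
classify_junctions <- function(junctions, model, max_offset = 500L) {
  if (inherits(junctions, "junction_counts")) junctions <- junctions$junctions
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    classify_junction(junctions[i, , drop = FALSE], model, max_offset)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  annotate_reported(out, model)
}

#' Reading-frame consequence of a splice event
#'
#' The net change in included coding sequence, in transcript coordinates:
#' `delta_nt = donor_offset - acceptor_offset - sum(coding_length of exons
#' strictly between donor and acceptor exon)`. For pure skipping events
#' this reduces to minus the summed coding length of the skipped exons; a
#' donor extended into the intron (positive offset) inserts bases, an
#' acceptor shifted into its exon (positive offset) removes them, and an
#' alternative site in a distant exon accumulates every fully-spanned
#' exon's coding length. The event is frame-preserving iff
#' `delta_nt %% 3 == 0`.
#'
#' Events touching a non-coding exon, and unassigned events, return
#' `not_applicable`.
#'
#' @param event a `splice_event` row (from [classify_junction()]).
#' @param model a `gene_model`.
#' @return list with `frame_preserving` (`"yes"`, `"no"`,
#'   `"not_applicable"`) and `delta_nt` (signed integer or `NA`).
#' @export
frame_effect <- function(event, model) {
  if (event$category[1] == "unassigned") {
    return(list(frame_preserving = "not_applicable",
                delta_nt = NA_integer_))
  }
  ex <- model$exons
  ends <- c(event$donor_exon[1], event$acceptor_exon[1])
  if (any(ex$exon_class[match(ends, ex$exon_id)] == "noncoding")) {
    return(list(frame_preserving = "not_applicable",
                delta_nt = NA_integer_))
  }
  between <- ex$exon_id[ex$exon_id > event$donor_exon[1] &
                          ex$exon_id < event$acceptor_exon[1]]
  delta <- event$donor_offset_nt[1] - event$acceptor_offset_nt[1] -
    sum(ex$coding_length[match(between, ex$exon_id)])
  list(frame_preserving = if (delta %% 3L == 0L) "yes" else "no",
       delta_nt = as.integer(delta))
}

#' Flag events already present in known isoforms
#'
#' The known junction set is every consecutive exon pair within each
#' isoform definition of the model; an event is `previously_reported`
#' when its (donor exon, acceptor exon) pair, with both offsets zero,
#' appears in that set. With no isoforms defined all events are novel.
#'
#' @param events splice-event data.frame.
#' @param model a `gene_model`.
#' @return the events with `previously_reported` set.
#' @export
annotate_reported <- function(events, model) {
  known <- character()
  for (iso in model$isoforms) {
    if (length(iso) >= 2) {
      known <- c(known, paste(iso[-length(iso)], iso[-1], sep = ">"))
    }
  }
  known <- unique(known)
  zero_off <- !is.na(events$donor_offset_nt) &
    events$donor_offset_nt == 0L &
    !is.na(events$acceptor_offset_nt) & events$acceptor_offset_nt == 0L
  pair <- paste(events$donor_exon, events$acceptor_exon, sep = ">")
  events$previously_reported <- zero_off & pair %in% known
  events
}

#' Human-readable event label
#'
#' Canonical-boundary events are labelled `donor-acceptor` by exon
#' ordinal (e.g. `"10-12"`); events using an alternative site are
#' labelled by the c.-positions of the two splice sites (e.g.
#' `"c.669-c.673"`), mirroring the published notation.
#'
#' @param events splice-event data.frame.
#' @param model a `gene_model`.
#' @return character vector of labels.
#' @export
event_labels <- function(events, model) {
  vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (e$category == "unassigned") return("unassigned")
    if (e$donor_offset_nt == 0L && e$acceptor_offset_nt == 0L) {
      return(paste0(e$donor_exon, "-", e$acceptor_exon))
    }
    if (model$strand == "+") {
      donor_base <- e$intron_start - 1L; acc_base <- e$intron_end
    } else {
      donor_base <- e$intron_end; acc_base <- e$intron_start - 1L
    }
    paste0(sub("^c\\.", "c.", genomic_to_cds(model, donor_base)$label), "-",
           genomic_to_cds(model, acc_base)$label)
  }, character(1))
}

#' Event table in reporting form
#'
#' One row per junction with read totals, per-cohort validation reads
#' when supplied, category, offsets, frame call and flags — the package's
#' analogue of a published event table.
#'
#' @param events classified events (from [classify_junctions()]).
#' @param jcm the `junction_counts` the events were classified from.
#' @param model a `gene_model`.
#' @param validation_totals optional named numeric vector of validation
#'   cohort read totals keyed by junction key.
#' @return data.frame ready for `write.table`.
#' @export
event_table <- function(events, jcm, model, validation_totals = NULL) {
  tot <- junction_totals(jcm)
  out <- data.frame(
    label = event_labels(events, model),
    donor_exon = events$donor_exon, acceptor_exon = events$acceptor_exon,
    category = events$category,
    donor_offset_nt = events$donor_offset_nt,
    acceptor_offset_nt = events$acceptor_offset_nt,
    skipped_exons = vapply(events$skipped_exons, paste, character(1),
                           collapse = ","),
    frame_preserving = events$frame_preserving,
    frame_delta_nt = events$frame_delta_nt,
    involves_meta_only = events$involves_meta_only,
    in_repeated_region = events$in_repeated_region,
    previously_reported = events$previously_reported,
    total_reads = tot$total_reads,
    samples_detected = tot$samples_detected,
    stringsAsFactors = FALSE)
  if (!is.null(validation_totals)) {
    keys <- junction_key(jcm$junctions$chrom, jcm$junctions$intron_start,
                         jcm$junctions$intron_end, jcm$junctions$strand)
    out$validation_reads <- as.integer(validation_totals[keys])
    out$validation_reads[is.na(out$validation_reads)] <- 0L
  }
  out
}
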