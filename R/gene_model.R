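EXON_CLASSES <- c("canonical", "meta_only", "isoform_specific", "noncoding")

#' Construct a gene model
#'
#' A gene model bundles the exon table and the isoform definitions of one
#' gene. Exon coordinates are 0-based half-open genomic intervals; exon ids
#' are 1-based ordinals in transcript orientation (exon 1 is the 5'-most
#' exon of the transcript, i.e. the exon with the largest genomic
#' coordinates on the minus strand). All classification downstream operates
#' in transcript orientation, so callers never need to reason about strand
#' again after construction.
#'
#' @param gene_name gene symbol or identifier.
#' @param chromosome reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `exon_id`, `genomic_start`,
#'   `genomic_end`, `exon_class` (one of canonical, meta_only,
#'   isoform_specific, noncoding), `repeat_block` (label such as `"B1"` or
#'   `NA`), `coding_length` (nucleotides contributed to the CDS).
#' @param isoforms named list; each element is an increasing integer vector
#'   of exon ids included in that isoform.
#' @param reference_isoform name of the isoform whose consecutive exon
#'   pairs define canonical junctions (default: the first isoform, by
#'   convention the full metatranscript ordering).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_name, chromosome, strand, exons, isoforms,
                       reference_isoform = names(isoforms)[1]) {
  stopifnot(is.data.frame(exons))
  required <- c("exon_id", "genomic_start", "genomic_end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols)) {
    stop("exon table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(exons$exon_class)) exons$exon_class <- "canonical"
  exons$exon_class[is.na(exons$exon_class) | exons$exon_class == ""] <-
    "canonical"
  if (is.null(exons$repeat_block)) exons$repeat_block <- NA_character_
  exons$repeat_block[!is.na(exons$repeat_block) &
                       exons$repeat_block %in% c("", ".")] <- NA_character_
  if (is.null(exons$coding_length)) {
    exons$coding_length <- ifelse(exons$exon_class == "noncoding", 0L,
                                  exons$genomic_end - exons$genomic_start)
  }
  exons <- exons[order(exons$exon_id), , drop = FALSE]
  rownames(exons) <- NULL
  exons$exon_id <- as.integer(exons$exon_id)
  exons$genomic_start <- as.integer(exons$genomic_start)
  exons$genomic_end <- as.integer(exons$genomic_end)
  exons$coding_length <- as.integer(exons$coding_length)
  model <- structure(
    list(gene_name = gene_name, chromosome = chromosome, strand = strand,
         exons = exons, isoforms = isoforms,
         reference_isoform = reference_isoform),
    class = "gene_model")
  validate_gene_model(model)
  model
}

#' Validate a gene model
#'
#' Checks the structural invariants: coordinates ordered, exon ids unique
#' and strictly ordered 5'->3' in transcript orientation, exons
#' non-overlapping, coding lengths within exon bounds, isoforms referring
#' only to existing exons with strictly increasing ids, and the reference
#' isoform present.
#'
#' @param model a `gene_model`.
#' @return the model, invisibly; stops with an informative error otherwise.
#' @export
validate_gene_model <- function(model) {
  ex <- model$exons
  if (!model$strand %in% c("+", "-")) {
    stop("strand must be '+' or '-'")
  }
  if (any(ex$genomic_start >= ex$genomic_end)) {
    bad <- ex$exon_id[ex$genomic_start >= ex$genomic_end][1]
    stop("exon ", bad, ": genomic_start must be < genomic_end")
  }
  if (anyDuplicated(ex$exon_id)) {
    stop("duplicated exon ids: ",
         paste(unique(ex$exon_id[duplicated(ex$exon_id)]), collapse = ", "))
  }
  bad_class <- setdiff(unique(ex$exon_class), EXON_CLASSES)
  if (length(bad_class)) {
    stop("unknown exon_class: ", paste(bad_class, collapse = ", "))
  }
  # transcript orientation: ids must increase along the transcript
  ord <- order(ex$genomic_start, decreasing = model$strand == "-")
  if (!identical(ex$exon_id[ord], sort(ex$exon_id))) {
    stop("exon ids are not ordered 5'->3' in transcript orientation")
  }
  # non-overlap: in genomic order each exon must end before the next starts
  gord <- order(ex$genomic_start)
  gs <- ex$genomic_start[gord]; ge <- ex$genomic_end[gord]
  ov <- which(ge[-length(ge)] > gs[-1])
  if (length(ov)) {
    i <- gord[ov[1]]; j <- gord[ov[1] + 1]
    stop("overlapping exons: ", ex$exon_id[i], " and ", ex$exon_id[j])
  }
  if (any(ex$coding_length < 0 |
          ex$coding_length > ex$genomic_end - ex$genomic_start)) {
    bad <- ex$exon_id[ex$coding_length < 0 |
                        ex$coding_length > ex$genomic_end - ex$genomic_start][1]
    stop("exon ", bad, ": coding_length outside [0, exon length]")
  }
  if (length(model$isoforms)) {
    if (is.null(names(model$isoforms)) || any(names(model$isoforms) == "")) {
      stop("isoforms must be a named list")
    }
    for (nm in names(model$isoforms)) {
      ids <- model$isoforms[[nm]]
      if (any(diff(ids) <= 0)) {
        stop("isoform ", nm, ": exon ids must be strictly increasing")
      }
      unknown <- setdiff(ids, ex$exon_id)
      if (length(unknown)) {
        stop("isoform ", nm, " references unknown exon(s): ",
             paste(unknown, collapse = ", "))
      }
    }
    if (!model$reference_isoform %in% names(model$isoforms)) {
      stop("reference_isoform '", model$reference_isoform,
           "' is not among the isoform definitions")
    }
  }
  invisible(model)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$gene_name, " (", x$chromosome, x$strand, ")\n")
  cat("  exons:", nrow(x$exons),
      "| coding:", sum(x$exons$coding_length > 0),
      "| meta-only:", sum(x$exons$exon_class == "meta_only"),
      "| repeat-block:", sum(!is.na(x$exons$repeat_block)), "\n")
  cat("  isoforms:", paste(names(x$isoforms), collapse = ", "),
      "(reference:", x$reference_isoform, ")\n")
  invisible(x)
}

#' Load a gene model from an exon table or a GTF/GFF annotation
#'
#' The native interchange format is a tab-separated exon table with columns
#' `exon_id`, `chrom`, `start`, `end`, `strand`, `class`, `repeat_block`,
#' `coding_length` (0-based half-open coordinates; `class` defaults to
#' `canonical` when empty; `repeat_block` empty or `.` for none). Files
#' ending in `.gtf`, `.gff` or `.gff3` are read through rtracklayer and
#' exon ordinals are assigned in transcript orientation (1-based GTF
#' coordinates are converted to 0-based half-open).
#'
#' @param path path to the annotation.
#' @param gene_name gene to extract. For the TSV dialect it names the
#'   resulting model; for GTF/GFF it selects records whose `gene_name` or
#'   `gene_id` attribute matches (an error is raised when absent).
#' @param isoforms optional named list of isoform exon-id vectors to attach.
#' @param reference_isoform see [gene_model()].
#' @return a validated `gene_model`.
#' @export
load_gene_model <- function(path, gene_name, isoforms = NULL,
                            reference_isoform = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.(gtf|gff|gff3)$", path, ignore.case = TRUE)) {
    exdf <- read_gff_exons(path, gene_name)
  } else {
    exdf <- read_exon_table(path)
  }
  if (is.null(isoforms)) {
    isoforms <- list(metatranscript = sort(exdf$exons$exon_id))
  }
  if (is.null(reference_isoform)) reference_isoform <- names(isoforms)[1]
  gene_model(gene_name, exdf$chrom, exdf$strand, exdf$exons,
             isoforms, reference_isoform)
}

read_exon_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ".", ""))
  need <- c("exon_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("exon table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  chrom <- unique(tab$chrom); strand <- unique(tab$strand)
  if (length(chrom) != 1 || length(strand) != 1) {
    stop("exon table must describe a single chromosome and strand")
  }
  exons <- data.frame(
    exon_id = as.integer(tab$exon_id),
    genomic_start = as.integer(tab$start),
    genomic_end = as.integer(tab$end),
    exon_class = if (is.null(tab$class)) "canonical" else
      ifelse(is.na(tab$class), "canonical", tab$class),
    repeat_block = if (is.null(tab$repeat_block)) NA_character_ else
      as.character(tab$repeat_block),
    coding_length = if (is.null(tab$coding_length)) NA_integer_ else
      as.integer(tab$coding_length),
    stringsAsFactors = FALSE)
  if (all(is.na(exons$coding_length))) exons$coding_length <- NULL
  list(chrom = chrom, strand = strand, exons = exons)
}

read_gff_exons <- function(path, gene_name) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF/GFF requires the rtracklayer package; ",
         "use the TSV exon-table format otherwise")
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  is_exon <- !is.null(md$type) & md$type == "exon"
  hit <- rep(FALSE, nrow(md))
  for (col in c("gene_name", "gene_id", "gene")) {
    if (!is.null(md[[col]])) hit <- hit | (!is.na(md[[col]]) & md[[col]] == gene_name)
  }
  keep <- is_exon & hit
  if (!any(keep)) stop("gene '", gene_name, "' not found in ", path)
  md <- md[keep, , drop = FALSE]
  md <- md[!duplicated(md[, c("start", "end")]), , drop = FALSE]
  strand <- as.character(md$strand[1])
  ord <- order(md$start, decreasing = strand == "-")
  md <- md[ord, , drop = FALSE]
  exons <- data.frame(
    exon_id = seq_len(nrow(md)),
    genomic_start = md$start - 1L,   # GFF is 1-based inclusive
    genomic_end = md$end,
    exon_class = "canonical",
    repeat_block = NA_character_,
    stringsAsFactors = FALSE)
  list(chrom = as.character(md$seqnames[1]), strand = strand, exons = exons)
}

#' Write a gene model to the TSV exon-table format
#'
#' Round-trips with [load_gene_model()]: reloading the written file yields
#' a field-identical model.
#'
#' @param model a `gene_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  ex <- model$exons
  out <- data.frame(
    exon_id = ex$exon_id, chrom = model$chromosome,
    start = ex$genomic_start, end = ex$genomic_end,
    strand = model$strand, class = ex$exon_class,
    repeat_block = ifelse(is.na(ex$repeat_block), ".", ex$repeat_block),
    coding_length = ex$coding_length, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Splice-boundary index of a gene model
#'
#' Every exon contributes exactly one donor and one acceptor entry,
#' expressed in transcript orientation: the donor is the exon's 3'
#' boundary in transcript direction (the coordinate where a downstream
#' intron starts), the acceptor its 5' boundary (where an upstream intron
#' ends). On the minus strand the donor therefore maps to the exon's
#' *lower* genomic coordinate.
#'
#' Positions are the 0-based half-open intron endpoints a junction carries:
#' a junction's intron_start is compared against donor positions on the
#' plus strand (acceptor positions on the minus strand), and vice versa.
#'
#' @param model a `gene_model`.
#' @return data.frame with columns `position`, `exon_id`,
#'   `side` (`"donor_end"` / `"acceptor_start"`).
#' @export
boundary_index <- function(model) {
  ex <- model$exons
  if (model$strand == "+") {
    donor <- ex$genomic_end       # intron starts where the exon ends
    acceptor <- ex$genomic_start  # intron ends where the exon starts
  } else {
    donor <- ex$genomic_start
    acceptor <- ex$genomic_end
  }
  idx <- rbind(
    data.frame(position = donor, exon_id = ex$exon_id, side = "donor_end",
               stringsAsFactors = FALSE),
    data.frame(position = acceptor, exon_id = ex$exon_id,
               side = "acceptor_start", stringsAsFactors = FALSE))
  if (anyDuplicated(idx$position[idx$side == "donor_end"]) ||
      anyDuplicated(idx$position[idx$side == "acceptor_start"])) {
    stop("two exons share a splice boundary coordinate; model is invalid")
  }
  idx[order(idx$position), , drop = FALSE]
}

#' Map a genomic position to a CDS (c.) position
#'
#' Exonic positions are reported as `c.N` where N is the cumulative coding
#' offset across preceding exons (transcript orientation) plus the 1-based
#' offset within the containing exon. Positions in non-coding exons return
#' type `"non-coding"`. Intronic positions are reported HGVS-style
#' relative to the nearest exon boundary: `c.N+k` downstream of a donor,
#' `c.M-k` upstream of an acceptor (ties go to the donor side).
#'
#' The mapping assumes each coding exon contributes its first
#' `coding_length` bases (transcript orientation) to the CDS; models where
#' coding exons are fully coding satisfy this trivially.
#'
#' @param model a `gene_model`.
#' @param genomic_pos 0-based genomic position of a base.
#' @return a list of class `cds_position` with fields `type`
#'   (`"coding"`, `"non-coding"`, `"intronic"`, `"outside"`), `label`,
#'   `cds_pos`, `offset`, `exon_id`.
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  ex <- model$exons
  minus <- model$strand == "-"
  cum_before <- cumsum(c(0L, ex$coding_length))[seq_len(nrow(ex))]
  res <- function(type, label, cds_pos = NA_integer_, offset = NA_integer_,
                  exon_id = NA_integer_) {
    structure(list(type = type, label = label, cds_pos = cds_pos,
                   offset = offset, exon_id = exon_id),
              class = "cds_position")
  }
  inside <- which(genomic_pos >= ex$genomic_start &
                    genomic_pos < ex$genomic_end)
  if (length(inside) == 1) {
    e <- inside
    off <- if (minus) ex$genomic_end[e] - genomic_pos else
      genomic_pos - ex$genomic_start[e] + 1L
    if (ex$coding_length[e] == 0L) {
      return(res("non-coding", "non-coding", exon_id = ex$exon_id[e],
                 offset = off))
    }
    cds <- cum_before[e] + min(off, ex$coding_length[e])
    return(res("coding", paste0("c.", cds), cds_pos = cds, offset = off,
               exon_id = ex$exon_id[e]))
  }
  span <- range(c(ex$genomic_start, ex$genomic_end))
  if (genomic_pos < span[1] || genomic_pos >= span[2]) {
    return(res("outside", "outside gene span"))
  }
  # intronic: distance to flanking exons in transcript orientation
  if (minus) {
    up <- which(ex$genomic_start > genomic_pos)   # transcript-upstream exon
    up <- up[which.min(ex$genomic_start[up])]
    dn <- which(ex$genomic_end <= genomic_pos)
    dn <- dn[which.max(ex$genomic_end[dn])]
    d_donor <- ex$genomic_start[up] - genomic_pos            # >= 1
    d_acc <- genomic_pos - ex$genomic_end[dn] + 1L
  } else {
    up <- which(ex$genomic_end <= genomic_pos)
    up <- up[which.max(ex$genomic_end[up])]
    dn <- which(ex$genomic_start > genomic_pos)
    dn <- dn[which.min(ex$genomic_start[dn])]
    d_donor <- genomic_pos - ex$genomic_end[up] + 1L
    d_acc <- ex$genomic_start[dn] - genomic_pos
  }
  cds_donor <- cum_before[up] + ex$coding_length[up]  # last coding base upstream
  cds_acc <- cum_before[dn] + 1L                      # first coding base downstream
  if (d_donor <= d_acc) {
    res("intronic", paste0("c.", cds_donor, "+", d_donor),
        cds_pos = cds_donor, offset = d_donor, exon_id = ex$exon_id[up])
  } else {
    res("intronic", paste0("c.", cds_acc, "-", d_acc),
        cds_pos = cds_acc, offset = -d_acc, exon_id = ex$exon_id[dn])
  }
}

#' @export
print.cds_position <- function(x, ...) {
  cat(x$label, "\n")
  invisible(x)
}
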