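# Position-frequency consensus scoring of donor/acceptor splice sites on
# a 0-100 scale (the Shapiro-Senapathy consensus-value scheme also
# underlying the Human Splicing Finder scores).

#' Construct a splice-site frequency matrix
#'
#' @param site_type `"donor"` or `"acceptor"`.
#' @param positions integer positions relative to the splice junction
#'   (negative = exonic side for donors / intronic side for acceptors,
#'   following the usual -3..+6 donor and -14..+1 acceptor windows;
#'   position 0 does not exist).
#' @param frequencies numeric matrix, one row per position, columns
#'   `A`, `C`, `G`, `T`; rows are normalised to sum to 1.
#' @return a list of class `splice_site_matrix` with `site_type`,
#'   `positions` and `frequencies` (row-stochastic).
#' @export
splice_site_matrix <- function(site_type = c("donor", "acceptor"),
                               positions, frequencies) {
  site_type <- match.arg(site_type)
  frequencies <- as.matrix(frequencies[, c("A", "C", "G", "T")])
  if (nrow(frequencies) != length(positions)) {
    stop("window length does not match the frequency table")
  }
  if (any(positions == 0)) stop("position 0 is not a valid window position")
  sums <- rowSums(frequencies)
  if (any(sums <= 0)) stop("each position needs a positive frequency total")
  frequencies <- frequencies / sums
  if (any(abs(rowSums(frequencies) - 1) > 1e-9)) {
    stop("per-position frequencies failed to normalise")
  }
  rownames(frequencies) <- positions
  structure(list(site_type = site_type, positions = as.integer(positions),
                 frequencies = frequencies),
            class = "splice_site_matrix")
}

#' Read a splice-site frequency matrix from TSV
#'
#' Columns `position`, `A`, `C`, `G`, `T` (counts, percentages or
#' proportions; rows are normalised on load).
#'
#' @param path TSV path.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return a `splice_site_matrix`.
#' @export
read_splice_site_matrix <- function(path, site_type = c("donor", "acceptor")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  splice_site_matrix(site_type, tab$position,
                     as.matrix(tab[, c("A", "C", "G", "T")]))
}

#' Packaged default donor matrix (9-mer window)
#'
#' The classic donor position-frequency table (last 3 exonic plus first
#' 6 intronic nucleotides) with the invariant GT dinucleotide at
#' intronic positions +1/+2. The invariant is asserted on load: any
#' window lacking GT there scores through a zero-frequency path.
#'
#' @return a `splice_site_matrix`.
#' @export
default_donor_matrix <- function() {
  m <- read_splice_site_matrix(
    system.file("extdata", "donor_pfm.tsv", package = "exonusage",
                mustWork = TRUE), "donor")
  f <- m$frequencies
  p1 <- match(1L, m$positions); p2 <- match(2L, m$positions)
  if (!isTRUE(all.equal(unname(f[p1, ]), c(0, 0, 1, 0))) ||
      !isTRUE(all.equal(unname(f[p2, ]), c(0, 0, 0, 1)))) {
    stop("packaged donor matrix lost its invariant GT dinucleotide")
  }
  m
}

#' Packaged default acceptor matrix (15-position window)
#'
#' Consensus-derived acceptor frequencies covering the pyrimidine tract
#' (-14..-5), the branch-adjacent positions, the invariant AG at -2/-1,
#' and the first exonic base. The AG invariant is asserted on load.
#'
#' @return a `splice_site_matrix`.
#' @export
default_acceptor_matrix <- function() {
  m <- read_splice_site_matrix(
    system.file("extdata", "acceptor_pfm.tsv", package = "exonusage",
                mustWork = TRUE), "acceptor")
  f <- m$frequencies
  pa <- match(-2L, m$positions); pg <- match(-1L, m$positions)
  if (!isTRUE(all.equal(unname(f[pa, ]), c(1, 0, 0, 0))) ||
      !isTRUE(all.equal(unname(f[pg, ]), c(0, 0, 1, 0)))) {
    stop("packaged acceptor matrix lost its invariant AG dinucleotide")
  }
  m
}

#' Consensus value of a splice-site window
#'
#' The raw score combines the per-position frequencies of the observed
#' nucleotides — as a sum by default, or as a product (`method =
#' "product"`, the geometric variant used by some consensus-value
#' implementations). The reported value min–max-normalises the raw score
#' to 0–100 against the worst and best windows attainable under the
#' matrix: the per-position argmax sequence scores exactly 100, the
#' argmin sequence exactly 0.
#'
#' A window containing `N` or any non-ACGT symbol yields an
#' "unpredicted" result (value `NA`) — never a numeric score. Case is
#' ignored.
#'
#' @param sequence nucleotide window, same length as the matrix window.
#' @param matrix a `splice_site_matrix`.
#' @param method `"sum"` (default) or `"product"`.
#' @return a list of class `consensus_score`: `value` (0-100 or `NA`),
#'   `unpredicted`, `site_sequence`, `site_type`, `method`.
#' @export
consensus_value <- function(sequence, matrix, method = c("sum", "product")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "splice_site_matrix"))
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  L <- nrow(matrix$frequencies)
  if (length(bases) != L) {
    stop("sequence length ", length(bases),
         " does not match the ", L, "-position window")
  }
  score <- structure(list(value = NA_real_, unpredicted = TRUE,
                          site_sequence = sequence,
                          site_type = matrix$site_type, method = method),
                     class = "consensus_score")
  col <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(col)) return(score)
  f <- matrix$frequencies[cbind(seq_len(L), col)]
  fmax <- apply(matrix$frequencies, 1, max)
  fmin <- apply(matrix$frequencies, 1, min)
  if (method == "sum") {
    raw <- sum(f); raw_max <- sum(fmax); raw_min <- sum(fmin)
  } else {
    # product variant: zero-frequency positions floor at a pseudo-count
    eps <- 1e-4
    raw <- sum(log(pmax(f, eps)))
    raw_max <- sum(log(pmax(fmax, eps)))
    raw_min <- sum(log(pmax(fmin, eps)))
  }
  score$value <- 100 * (raw - raw_min) / (raw_max - raw_min)
  score$unpredicted <- FALSE
  score
}

#' @export
print.consensus_score <- function(x, ...) {
  if (x$unpredicted) {
    cat("consensus_score:", x$site_type, "Unpredicted (", x$site_sequence,
        ")\n")
  } else {
    cat(sprintf("consensus_score: %s %.2f (%s)\n", x$site_type, x$value,
                x$site_sequence))
  }
  invisible(x)
}

#' Compare an alternative splice site against its canonical counterpart
#'
#' Scores both windows with the same matrix and reports the paired
#' values and their difference (alternative minus canonical);
#' "unpredicted" propagates into an `NA` delta.
#'
#' @param alt_sequence alternative-site window.
#' @param canonical_sequence canonical-site window.
#' @param matrix a `splice_site_matrix` (both windows must be of its
#'   site type).
#' @param method see [consensus_value()].
#' @return list with `alt`, `canonical` (both `consensus_score`) and
#'   `delta`.
#' @export
compare_sites <- function(alt_sequence, canonical_sequence, matrix,
                          method = c("sum", "product")) {
  method <- match.arg(method)
  alt <- consensus_value(alt_sequence, matrix, method)
  can <- consensus_value(canonical_sequence, matrix, method)
  delta <- if (alt$unpredicted || can$unpredicted) NA_real_ else
    alt$value - can$value
  list(alt = alt, canonical = can, delta = delta)
}

#' Read splice-site windows from a FASTA file
#'
#' Sequence names of the form `name|donor` or `name|acceptor` declare the
#' site type (defaulting to `default_type` when absent). Parsing goes
#' through Biostrings.
#'
#' @param path FASTA path.
#' @param default_type site type for unannotated records.
#' @return data.frame with `name`, `site_type`, `sequence`, ready for
#'   [score_sites()].
#' @export
read_site_windows <- function(path, default_type = "donor") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA site windows requires the Biostrings package")
  }
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  parts <- strsplit(nm, "|", fixed = TRUE)
  data.frame(
    name = vapply(parts, `[`, character(1), 1),
    site_type = vapply(parts, function(p) {
      if (length(p) >= 2 && p[2] %in% c("donor", "acceptor")) p[2]
      else default_type
    }, character(1)),
    sequence = as.character(ss), stringsAsFactors = FALSE)
}

#' Score a table of splice-site windows
#'
#' Convenience for scoring many `(site_type, sequence)` pairs, e.g. read
#' from a FASTA of site windows.
#'
#' @param sites data.frame with columns `site_type` and `sequence`.
#' @param donor_matrix,acceptor_matrix matrices to use (packaged
#'   defaults).
#' @param method see [consensus_value()].
#' @return the input with `value` and `unpredicted` columns appended.
#' @export
score_sites <- function(sites, donor_matrix = default_donor_matrix(),
                        acceptor_matrix = default_acceptor_matrix(),
                        method = c("sum", "product")) {
  method <- match.arg(method)
  res <- lapply(seq_len(nrow(sites)), function(i) {
    m <- if (sites$site_type[i] == "donor") donor_matrix else acceptor_matrix
    consensus_value(sites$sequence[i], m, method)
  })
  sites$value <- vapply(res, function(s) s$value, numeric(1))
  sites$unpredicted <- vapply(res, function(s) s$unpredicted, logical(1))
  sites
}
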