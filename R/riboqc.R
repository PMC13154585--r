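# Ribo-seq quality control: P-site offset calibration by metagene,
# 3-nt periodicity, and read-length / transcript-region metrics.
#
# Coordinates are 0-based half-open in transcript space throughout; GTF
# input (1-based closed, genomic) is converted at the boundary (see io.R).

check_reads <- function(reads) {
  need <- c("transcript_id", "pos5", "length")
  if (!all(need %in% names(reads)))
    stop("reads must have columns: ", paste(need, collapse = ", "))
  invisible(reads)
}

coding_annotation <- function(annotation) {
  ann <- annotation[!is.na(annotation$cds_start), ]
  if (!nrow(ann)) stop("annotation contains no CDS")
  ann
}

#' Calibrate P-site offsets from a start-codon metagene
#'
#' For each read length, counts read 5' ends at every candidate distance
#' `d` upstream of annotated start codons and returns the `d` maximizing the
#' metagene count (ties broken toward the smaller offset). The P-site of a
#' read is its 5' end plus this per-length offset.
#'
#' @param reads Data frame with `transcript_id`, `pos5` (0-based transcript
#'   coordinate of the 5' end), `length`.
#' @param annotation Annotation data frame with `transcript_id`,
#'   `cds_start` (0-based).
#' @param max_offset Largest candidate offset considered.
#' @return List with `offsets` (named integer vector, one per read length)
#'   and `metagene` (data frame `length`, `offset`, `count`).
#' @export
calibrate_psite_offsets <- function(reads, annotation, max_offset = 18L) {
  check_reads(reads)
  ann <- coding_annotation(annotation)
  cds_start <- ann$cds_start[match(reads$transcript_id, ann$transcript_id)]
  keep <- !is.na(cds_start)
  d <- cds_start[keep] - reads$pos5[keep]
  len <- reads$length[keep]
  ok <- d >= 0L & d <= max_offset
  lengths <- sort(unique(reads$length))
  offsets <- integer(0)
  meta <- list()
  for (L in lengths) {
    di <- d[ok & len == L]
    if (!length(di))
      stop("no reads near any start codon for read length ", L)
    tab <- table(factor(di, levels = 0:max_offset))
    cnt <- as.integer(tab)
    best <- which.max(cnt) - 1L  # which.max returns the first (smallest) max
    offsets[as.character(L)] <- best
    meta[[as.character(L)]] <- data.frame(length = L, offset = 0:max_offset,
                                          count = cnt)
  }
  list(offsets = offsets, metagene = do.call(rbind, c(meta, list(
    make.row.names = FALSE))))
}

# Resolve per-read P-site coordinates from 5' ends and per-length offsets.
psite_positions <- function(reads, offsets = 12L) {
  check_reads(reads)
  off <- if (length(offsets) == 1L && is.null(names(offsets))) {
    rep(as.integer(offsets), nrow(reads))
  } else {
    o <- offsets[as.character(reads$length)]
    if (anyNA(o)) stop("no offset provided for some read lengths")
    as.integer(o)
  }
  data.frame(transcript_id = reads$transcript_id,
             psite = reads$pos5 + off,
             length = reads$length,
             stringsAsFactors = FALSE)
}

#' Frame fractions of in-CDS P-sites (3-nt periodicity)
#'
#' Fractions of P-sites falling in each reading frame relative to the
#' annotated CDS start: frame `k` means `(psite - cds_start) mod 3 == k`.
#' Only P-sites inside an annotated CDS are counted.
#'
#' @param psites Data frame with `transcript_id`, `psite` (0-based),
#'   e.g. from [psite_positions()].
#' @param annotation Annotation with `cds_start`, `cds_end`.
#' @return Named numeric vector `c(f0, f1, f2)` summing to 1.
#' @export
frame_periodicity <- function(psites, annotation) {
  ann <- coding_annotation(annotation)
  i <- match(psites$transcript_id, ann$transcript_id)
  cs <- ann$cds_start[i]; ce <- ann$cds_end[i]
  in_cds <- !is.na(cs) & psites$psite >= cs & psites$psite < ce
  if (!any(in_cds)) stop("no P-sites fall inside an annotated CDS")
  fr <- (psites$psite[in_cds] - cs[in_cds]) %% 3L
  f <- as.numeric(table(factor(fr, levels = 0:2))) / sum(in_cds)
  stats::setNames(f, c("f0", "f1", "f2"))
}

#' Read-length histogram and transcript-region partition
#'
#' Assigns each P-site to exactly one region of its transcript (5'UTR, CDS
#' or 3'UTR, by the P-site position alone) and tabulates read lengths.
#'
#' @inheritParams frame_periodicity
#' @return List with `region_fractions` (named `cds`, `utr5`, `utr3`,
#'   summing to 1 over assigned reads), `region_counts`, and
#'   `length_histogram` (data frame `length`, `count`).
#' @export
region_and_length_metrics <- function(psites, annotation) {
  ann <- coding_annotation(annotation)
  i <- match(psites$transcript_id, ann$transcript_id)
  keep <- !is.na(i)
  cs <- ann$cds_start[i[keep]]; ce <- ann$cds_end[i[keep]]
  tl <- ann$tx_len[i[keep]]
  p <- psites$psite[keep]
  if (any(p < 0 | p >= tl))
    stop("P-site coordinate outside transcript bounds")
  region <- ifelse(p < cs, "utr5", ifelse(p < ce, "cds", "utr3"))
  cnt <- table(factor(region, levels = c("cds", "utr5", "utr3")))
  lh <- as.data.frame(table(psites$length), stringsAsFactors = FALSE)
  names(lh) <- c("length", "count")
  lh$length <- as.integer(lh$length)
  list(region_fractions = stats::setNames(as.numeric(cnt) / sum(cnt),
                                          c("cds", "utr5", "utr3")),
       region_counts = stats::setNames(as.integer(cnt),
                                       c("cds", "utr5", "utr3")),
       length_histogram = lh)
}

#' One-call Ribo-seq QC report
#'
#' Runs offset calibration (unless a fixed offset is supplied), 3-nt
#' periodicity and region/length metrics, and returns a consolidated report.
#' The retained read-length window defaults to 25-50 nt.
#'
#' @param reads Read table (`transcript_id`, `pos5`, `length`).
#' @param annotation Annotation data frame.
#' @param offset Fixed P-site offset, or `NULL` to calibrate per length.
#' @param min_len,max_len Inclusive read-length retention window.
#' @return List of class `"ribo_qc"` with elements `offsets`,
#'   `frame_fractions`, `region_fractions`, `length_histogram`,
#'   `n_reads_used`.
#' @export
ribo_qc <- function(reads, annotation, offset = NULL,
                    min_len = 25L, max_len = 50L) {
  check_reads(reads)
  reads <- reads[reads$length >= min_len & reads$length <= max_len, ]
  if (!nrow(reads)) stop("no reads within the retained length window")
  offsets <- if (is.null(offset)) {
    calibrate_psite_offsets(reads, annotation)$offsets
  } else {
    stats::setNames(rep(as.integer(offset), length(unique(reads$length))),
                    sort(unique(reads$length)))
  }
  ps <- psite_positions(reads, offsets)
  rl <- region_and_length_metrics(ps, annotation)
  structure(list(offsets = offsets,
                 frame_fractions = frame_periodicity(ps, annotation),
                 region_fractions = rl$region_fractions,
                 length_histogram = rl$length_histogram,
                 n_reads_used = nrow(reads)),
            class = "ribo_qc")
}

#' @export
print.ribo_qc <- function(x, ...) {
  cat("Ribo-seq QC report\n")
  cat("  reads used:      ", x$n_reads_used, "\n")
  cat("  P-site offsets:  ",
      paste(sprintf("%s nt: %d", names(x$offsets), x$offsets),
            collapse = ", "), "\n")
  cat("  frame fractions: ",
      paste(sprintf("%.3f", x$frame_fractions), collapse = " / "), "\n")
  cat("  region fractions:",
      paste(sprintf("%s %.3f", names(x$region_fractions),
                    x$region_fractions), collapse = ", "), "\n")
  invisible(x)
}
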