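# Readers and writers for the tabular dialects used across the pipeline.
# Counts are TSV with genes in rows and a header of sample ids; annotation
# travels as GTF (1-based closed, converted to 0-based half-open transcript
# coordinates at this boundary) or as the equivalent TSV dialect.

#' Write / read a count matrix as TSV
#'
#' @param counts Matrix, features x samples.
#' @param path File path.
#' @return `read_counts_tsv` returns an integer matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a transcript annotation as GTF
#'
#' Lays transcripts head-to-tail on one contig (single-exon models) and
#' emits `exon` and `CDS` features with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes. The inverse, [read_annotation_gtf()], accepts
#' any GTF with exon/CDS features (multi-exon, both strands) and returns
#' the transcript-space annotation used internally.
#'
#' @param annotation Annotation data frame (see [simulate_annotation()]).
#' @param path Output GTF path.
#' @param gap Genomic gap between consecutive transcripts.
#' @export
write_annotation_gtf <- function(annotation, path, gap = 100L) {
  n <- nrow(annotation)
  starts <- cumsum(c(1L, utils::head(annotation$tx_len + gap, -1L)))
  feats <- list()
  for (i in seq_len(n)) {
    a <- annotation[i, ]
    g0 <- starts[i]
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = "chr1", start = g0, end = g0 + a$tx_len - 1L,
      strand = "+", type = "exon", gene_id = a$gene_id,
      transcript_id = a$transcript_id, gene_biotype = a$gene_biotype,
      stringsAsFactors = FALSE)
    if (!is.na(a$cds_start)) {
      feats[[length(feats) + 1L]] <- data.frame(
        seqnames = "chr1", start = g0 + a$cds_start,
        end = g0 + a$cds_end - 1L,
        strand = "+", type = "CDS", gene_id = a$gene_id,
        transcript_id = a$transcript_id, gene_biotype = a$gene_biotype,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::makeGRangesFromDataFrame(df, keep.extra.columns = TRUE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @param path GTF path to read.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  exons <- gr[md$type == "exon"]
  cds <- gr[md$type == "CDS"]
  ex_by_tx <- split(exons, S4Vectors::mcols(exons)$transcript_id)
  tx_ids <- names(ex_by_tx)
  out <- lapply(tx_ids, function(tx) {
    ex <- ex_by_tx[[tx]]
    strand <- as.character(BiocGenerics::strand(ex))[1]
    ord <- order(BiocGenerics::start(ex),
                 decreasing = identical(strand, "-"))
    ex <- ex[ord]
    widths <- BiocGenerics::width(ex)
    tx_len <- sum(widths)
    ci <- cds[S4Vectors::mcols(cds)$transcript_id == tx]
    cds_start <- cds_end <- NA_integer_
    if (length(ci)) {
      # genomic -> transcript coordinate of the CDS 5' end and 3' end + 1
      cum <- cumsum(c(0L, utils::head(widths, -1L)))
      g5 <- if (strand == "-") max(BiocGenerics::end(ci)) else
        min(BiocGenerics::start(ci))
      g3 <- if (strand == "-") min(BiocGenerics::start(ci)) else
        max(BiocGenerics::end(ci))
      to_tx <- function(gpos) {
        for (k in seq_along(widths)) {
          s <- BiocGenerics::start(ex)[k]; e <- BiocGenerics::end(ex)[k]
          if (gpos >= s && gpos <= e) {
            return(cum[k] + if (strand == "-") e - gpos else gpos - s)
          }
        }
        stop("CDS coordinate outside exons for transcript ", tx)
      }
      cds_start <- to_tx(g5)
      cds_end <- to_tx(g3) + 1L
    }
    md1 <- S4Vectors::mcols(ex)[1, ]
    data.frame(transcript_id = tx,
               gene_id = md1$gene_id,
               gene_biotype = if ("gene_biotype" %in% names(md1))
                 md1$gene_biotype else NA_character_,
               tx_len = tx_len, cds_start = cds_start, cds_end = cds_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$transcript_id), ]
}

#' Write amino-acid sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a protein FASTA into a named character vector
#'
#' @param path FASTA path.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
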