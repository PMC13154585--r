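# Published cohort-level summary counts of the emulated CRC translatome
# study, carried as reference metadata. The raw sequencing data behind them
# are controlled-access, so these partitioned totals serve as internal
# arithmetic-consistency checks (each total must equal the sum of its
# printed parts) and as documentation of the scale of the original cohort.

#' Published cohort count partitions
#'
#' Each row states one printed total and the printed subtotals that
#' partition it: the ORF catalog (total, annotated + de novo; de novo,
#' coding-gene-derived + lncORF; coding-gene-derived, in-frame +
#' out-of-frame), differentially expressed genes (up + down),
#' differential-TE genes (up + down), the Exclusive regulatory class
#' (up + down), and the prioritized tumour-specific neoantigen candidates
#' (coding-ORF-derived + lncORF-derived).
#'
#' @return Data frame with columns `quantity`, `total` and `parts`
#'   (comma-separated subtotals).
#' @export
cohort_count_partitions <- function() {
  data.frame(
    quantity = c("orf_catalog", "de_novo_orfs", "coding_gene_orfs",
                 "degs", "dtegs", "exclusive_class",
                 "neoantigen_candidates"),
    total = c(25771L, 5166L, 4134L, 3795L, 1257L, 449L, 54L),
    parts = c("20605,5166", "4134,1032", "3882,252", "2237,1558",
              "668,589", "302,147", "38,16"),
    stringsAsFactors = FALSE)
}

#' Check that each published total equals the sum of its parts
#'
#' @param partitions Data frame in the format of
#'   [cohort_count_partitions()].
#' @return Named logical vector, one entry per partition.
#' @export
check_count_partitions <- function(partitions = cohort_count_partitions()) {
  ok <- vapply(seq_len(nrow(partitions)), function(i) {
    parts <- as.integer(strsplit(partitions$parts[i], ",")[[1]])
    sum(parts) == partitions$total[i]
  }, logical(1))
  stats::setNames(ok, partitions$quantity)
}
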