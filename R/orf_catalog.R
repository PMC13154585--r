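# ORF catalog consolidation and classification.
#
# Per-sample ORF call sets are merged into one catalog: an ORF is retained
# when detected in >= min_samples samples of at least one group (the
# thresholds are per group, 2/19 tumour OR 2/15 normal in the emulated
# design); among ORFs sharing a start coordinate, then among those sharing
# an end coordinate (same transcript and strand), only the longest is kept.

#' Consolidate per-sample ORF call sets into a catalog
#'
#' @param callsets Named list of per-sample data frames with columns
#'   `orf_id`, `transcript_id`, `strand`, `start`, `end` (0-based
#'   half-open) and optionally `gene_id`, `caller`.
#' @param groups Named character vector mapping sample ids to `"tumour"` or
#'   `"normal"`; every sample in `callsets` must be labelled.
#' @param min_samples Detection threshold applied within each group.
#' @return Data frame of class `"orf_catalog"`: one row per retained ORF
#'   with detection counts per group, retention flags and caller provenance.
#' @export
consolidate_orfs <- function(callsets, groups, min_samples = 2L) {
  if (is.null(names(callsets))) stop("callsets must be a named list")
  if (!all(names(callsets) %in% names(groups)))
    stop("unlabelled sample(s): ",
         paste(setdiff(names(callsets), names(groups)), collapse = ", "))
  if (!all(groups[names(callsets)] %in% c("tumour", "normal")))
    stop("groups must be 'tumour' or 'normal'")

  # detection matrix: an ORF is detected in a sample if any caller reports it
  all_rows <- do.call(rbind, lapply(names(callsets), function(s) {
    cs <- callsets[[s]]
    if (!nrow(cs)) return(NULL)
    cs$sample_id <- s
    cs
  }))
  if (is.null(all_rows) || !nrow(all_rows)) stop("no ORF calls provided")
  det <- unique(all_rows[, c("orf_id", "sample_id")])
  det$group <- groups[det$sample_id]
  n_t <- vapply(split(det$sample_id, det$orf_id), function(s)
    sum(groups[unique(s)] == "tumour"), integer(1))
  n_n <- vapply(split(det$sample_id, det$orf_id), function(s)
    sum(groups[unique(s)] == "normal"), integer(1))

  first <- all_rows[!duplicated(all_rows$orf_id), , drop = FALSE]
  first <- first[order(first$orf_id), ]
  cat_df <- data.frame(
    orf_id = first$orf_id,
    transcript_id = first$transcript_id,
    gene_id = if ("gene_id" %in% names(first)) first$gene_id else NA,
    strand = first$strand,
    start = first$start, end = first$end,
    length = first$end - first$start,
    stringsAsFactors = FALSE)
  cat_df$callers <- vapply(split(all_rows$caller %||%
                                   rep("unknown", nrow(all_rows)),
                                 all_rows$orf_id)[cat_df$orf_id],
                           function(x) paste(sort(unique(x)), collapse = ","),
                           character(1))
  cat_df$n_tumour <- as.integer(n_t[cat_df$orf_id])
  cat_df$n_normal <- as.integer(n_n[cat_df$orf_id])
  cat_df$tumour_retained <- cat_df$n_tumour >= min_samples
  cat_df$normal_retained <- cat_df$n_normal >= min_samples
  cat_df <- cat_df[cat_df$tumour_retained | cat_df$normal_retained, ,
                   drop = FALSE]
  if (!nrow(cat_df)) stop("no ORF passes the detection threshold")

  cat_df <- dedup_longest(cat_df, "start")
  cat_df <- dedup_longest(cat_df, "end")
  cat_df <- cat_df[order(cat_df$orf_id), ]
  rownames(cat_df) <- NULL
  class(cat_df) <- c("orf_catalog", "data.frame")
  cat_df
}

# Within groups sharing `key` (plus transcript and strand), keep the
# longest ORF; ties broken by smallest start, then lexicographic id.
dedup_longest <- function(df, key) {
  grp <- paste(df$transcript_id, df$strand, df[[key]], sep = "\r")
  ord <- order(grp, -df$length, df$start, df$orf_id)
  df <- df[ord, , drop = FALSE]
  df[!duplicated(grp[ord]), , drop = FALSE]
}

#' Categorize ORFs against the annotation
#'
#' `annotated` when the ORF coordinates match an annotated CDS exactly;
#' on coding transcripts, `in_frame` when the ORF start is a multiple of 3
#' from the CDS start, else `out_of_frame`; `lncORF` when the host gene
#' biotype is lncRNA.
#'
#' @param catalog ORF catalog (or any data frame with `transcript_id`,
#'   `start`, `end`).
#' @param annotation Annotation data frame (`transcript_id`,
#'   `gene_biotype`, `cds_start`, `cds_end`).
#' @return The catalog with a `category` column added.
#' @export
categorize_orfs <- function(catalog, annotation) {
  i <- match(catalog$transcript_id, annotation$transcript_id)
  if (anyNA(i))
    stop("host transcript(s) missing from annotation: ",
         paste(unique(catalog$transcript_id[is.na(i)]), collapse = ", "))
  biotype <- annotation$gene_biotype[i]
  cs <- annotation$cds_start[i]; ce <- annotation$cds_end[i]
  category <- ifelse(biotype == "lncRNA", "lncORF",
              ifelse(catalog$start == cs & catalog$end == ce, "annotated",
              ifelse((catalog$start - cs) %% 3L == 0L, "in_frame",
                     "out_of_frame")))
  catalog$category <- category
  catalog
}

#' Transcripts-per-million normalization
#'
#' `TPM_i = (count_i / length_i) / sum_j (count_j / length_j) * 1e6`
#' per sample; column sums equal 1e6 (up to float error).
#'
#' @param counts Count matrix, features x samples.
#' @param lengths Feature lengths (> 0), recycled along rows.
#' @return Matrix of TPM values with the dimensions of `counts`.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample with zero total rate cannot be normalized")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Tumour/normal specificity classes from per-group TPM ranks
#'
#' Each ORF's group-mean TPM is percentile-ranked among all catalog ORFs
#' within that group (ties take the maximum rank). An ORF is
#' `tumour_specific` when its tumour rank is at or above the `q_low`
#' percentile and its normal rank below it ("expressed in tumours, absent
#' in normals"); `normal_specific` is symmetric; `both` when at or above in
#' both groups; `neither` otherwise.
#'
#' @param catalog ORF catalog.
#' @param tpm_mat TPM matrix (ORFs x samples) covering the catalog ORFs.
#' @param groups Named vector mapping sample ids to groups.
#' @param q_low Percentile boundary (default 0.10: "top 90%" versus
#'   "bottom 10%").
#' @return The catalog with `mean_tpm_tumour`, `mean_tpm_normal` and
#'   `spec_class` columns added.
#' @export
specificity_classify <- function(catalog, tpm_mat, groups, q_low = 0.10) {
  if (!nrow(catalog)) stop("empty catalog")
  i <- match(catalog$orf_id, rownames(tpm_mat))
  if (anyNA(i)) stop("TPM matrix does not cover all catalog ORFs")
  tum <- colnames(tpm_mat)[groups[colnames(tpm_mat)] == "tumour"]
  nor <- colnames(tpm_mat)[groups[colnames(tpm_mat)] == "normal"]
  mt <- rowMeans(tpm_mat[i, tum, drop = FALSE])
  mn <- rowMeans(tpm_mat[i, nor, drop = FALSE])
  # percentile rank in [0, 1): (rank - 1)/n with ties taking the maximum
  # rank, so the lowest ORF of a group sits below any positive q_low and a
  # fully tied group sits above it
  pr <- function(x) (rank(x, ties.method = "max") - 1) / length(x)
  rt <- pr(mt); rn <- pr(mn)
  cls <- ifelse(rt >= q_low & rn < q_low, "tumour_specific",
         ifelse(rn >= q_low & rt < q_low, "normal_specific",
         ifelse(rt >= q_low & rn >= q_low, "both", "neither")))
  catalog$mean_tpm_tumour <- unname(mt)
  catalog$mean_tpm_normal <- unname(mn)
  catalog$spec_class <- cls
  catalog
}

#' Upregulated-ORF union
#'
#' The union of (a) tumour-specific ORFs and (b) `both`-class ORFs
#' significantly upregulated in tumours (`p < alpha` and `log2fc > 0`) at
#' the Ribo-seq level.
#'
#' @param catalog Catalog with a `spec_class` column.
#' @param ribo_de Data frame with `gene_id` (ORF ids), `log2fc`, `p`
#'   covering at least every `both` ORF.
#' @param alpha Significance threshold.
#' @return Character vector of ORF ids.
#' @export
upregulated_orfs <- function(catalog, ribo_de, alpha = 0.05) {
  ts <- catalog$orf_id[catalog$spec_class == "tumour_specific"]
  both <- catalog$orf_id[catalog$spec_class == "both"]
  i <- match(both, ribo_de$gene_id)
  if (anyNA(i))
    stop("missing DE record for 'both' ORF(s): ",
         paste(both[is.na(i)], collapse = ", "))
  up <- both[ribo_de$p[i] < alpha & ribo_de$log2fc[i] > 0]
  sort(union(ts, up))
}

#' C1-C4 expression clusters of de novo ORFs
#'
#' `C1`: upregulated only at the transcript (RNA) level; `C2`: upregulated
#' only at the translational (RIBO) level; `C3`: downregulated only at the
#' RNA level; `C4`: downregulated only at the RIBO level; `none` when
#' neither or both levels are significant.
#'
#' @param rna_de,ribo_de Data frames with `gene_id`, `log2fc`, `p` covering
#'   the ORFs.
#' @param orf_ids ORF ids to classify.
#' @param alpha Significance threshold.
#' @return Character vector of cluster labels along `orf_ids`.
#' @export
expression_cluster <- function(orf_ids, rna_de, ribo_de, alpha = 0.05) {
  ir <- match(orf_ids, rna_de$gene_id)
  ib <- match(orf_ids, ribo_de$gene_id)
  if (anyNA(ir) || anyNA(ib))
    stop("DE results must cover every ORF at both levels")
  sig_r <- rna_de$p[ir] < alpha
  sig_b <- ribo_de$p[ib] < alpha
  up_r <- sig_r & rna_de$log2fc[ir] > 0
  dn_r <- sig_r & rna_de$log2fc[ir] < 0
  up_b <- sig_b & ribo_de$log2fc[ib] > 0
  dn_b <- sig_b & ribo_de$log2fc[ib] < 0
  ifelse(up_r & !sig_b, "C1",
  ifelse(up_b & !sig_r, "C2",
  ifelse(dn_r & !sig_b, "C3",
  ifelse(dn_b & !sig_r, "C4", "none"))))
}
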