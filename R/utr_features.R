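# 5'UTR regulatory-feature comparison between gene sets.
#
# Binary features (uORF, TOP element, predicted IRES, m6A-site presence)
# are compared as gene ratios with a two-sided Fisher exact test; continuous
# features (AU content, IRES probability, cumulative m6A motif score) as
# group means with a two-sided Wilcoxon rank-sum test.

#' Cumulative m6A motif score
#'
#' Arithmetic sum of per-site scores; 0 for a gene with no sites.
#'
#' @param scores Numeric vector of non-negative site scores.
#' @return Single numeric score.
#' @export
cumulative_m6a_score <- function(scores) {
  if (length(scores) && any(scores < 0))
    stop("m6A site scores must be non-negative")
  if (!length(scores)) return(0)
  sum(scores)
}

# Wilcoxon rank-sum with the documented exactness policy: exact null for
# combined n <= 25 and tie-free data, otherwise normal approximation with
# tie and continuity correction.
wilcox_p <- function(x, y) {
  if (stats::var(c(x, y)) == 0) return(1)  # fully tied: no evidence
  exact <- (length(x) + length(y)) <= 25L && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Compare 5'UTR features between a target and a control gene set
#'
#' @param target_genes,control_genes Disjoint character vectors of gene ids
#'   (e.g. translationally upregulated genes versus genes with no TE shift).
#' @param features Data frame with columns `gene_id`, `has_uorf`,
#'   `has_top`, `au_content`, `ires_prob`, `n_m6a_sites`, `cumulative_m6a`.
#'   Genes absent from the table are excluded and reported in the coverage
#'   attribute.
#' @param ires_threshold Probability at or above which a gene counts as
#'   IRES-positive for the ratio panel (the probability itself is also
#'   compared as a continuous feature).
#' @param max_missing Error when more than this fraction of a gene set has
#'   no feature record.
#' @return Data frame of class `"utr_comparison"`: one row per feature with
#'   `feature`, `type`, `target`, `control` (ratios or means), `test`, `p`.
#' @export
compare_utr_features <- function(target_genes, control_genes, features,
                                 ires_threshold = 0.5, max_missing = 0.5) {
  if (!length(target_genes) || !length(control_genes))
    stop("gene sets must be non-empty")
  if (length(intersect(target_genes, control_genes)))
    stop("gene sets must be disjoint")
  ft <- features[match(target_genes, features$gene_id), ]
  fc <- features[match(control_genes, features$gene_id), ]
  miss_t <- mean(is.na(ft$gene_id)); miss_c <- mean(is.na(fc$gene_id))
  if (miss_t > max_missing || miss_c > max_missing)
    stop("feature coverage below ", 1 - max_missing,
         " for one of the gene sets")
  ft <- ft[!is.na(ft$gene_id), ]; fc <- fc[!is.na(fc$gene_id), ]

  binary <- list(uORF = "has_uorf", TOP = "has_top")
  rows <- list()
  add_binary <- function(name, xt, xc) {
    tab <- matrix(c(sum(xt), sum(!xt), sum(xc), sum(!xc)), 2,
                  dimnames = list(c("with", "without"),
                                  c("target", "control")))
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(feature = name, type = "ratio",
               target = mean(xt), control = mean(xc),
               test = "fisher", p = p, stringsAsFactors = FALSE)
  }
  add_cont <- function(name, xt, xc) {
    data.frame(feature = name, type = "mean",
               target = mean(xt), control = mean(xc),
               test = "wilcoxon", p = wilcox_p(xt, xc),
               stringsAsFactors = FALSE)
  }
  rows$uorf <- add_binary("uORF", ft$has_uorf, fc$has_uorf)
  rows$top <- add_binary("TOP", ft$has_top, fc$has_top)
  rows$au <- add_cont("AU_content", ft$au_content, fc$au_content)
  rows$ires_r <- add_binary("IRES_predicted",
                            ft$ires_prob >= ires_threshold,
                            fc$ires_prob >= ires_threshold)
  rows$ires_m <- add_cont("prob_IRES", ft$ires_prob, fc$ires_prob)
  rows$m6a_r <- add_binary("m6A_site", ft$n_m6a_sites > 0,
                           fc$n_m6a_sites > 0)
  rows$m6a_m <- add_cont("cumulative_m6A", ft$cumulative_m6a,
                         fc$cumulative_m6a)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "coverage") <- c(target_missing = miss_t,
                             control_missing = miss_c)
  class(out) <- c("utr_comparison", "data.frame")
  out
}

#' A+U fraction of sequences (convenience helper)
#'
#' Computes the A+U (A+T) base fraction of 5'UTR sequences, for users who
#' have sequence but no precomputed AU-content column. The comparison
#' functions themselves consume AU content as an input feature.
#'
#' @param seqs Character vector (or `Biostrings::DNAStringSet`) of
#'   sequences.
#' @return Numeric vector of A+U fractions.
#' @export
au_content <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  vapply(strsplit(seqs, ""), function(b)
    mean(b %in% c("A", "T", "U")), numeric(1))
}
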