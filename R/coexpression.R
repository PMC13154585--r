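# Simplified weighted co-expression module analysis of TE profiles.
#
# Adjacency a_ij = |cor(i,j)|^beta (unsigned by default), topological
# overlap similarity, average-linkage clustering of 1 - TOM with a static
# cut, minimum module size with a reserved "grey" label for unassigned
# genes, and iterative eigengene merging. This is a deliberately simplified
# re-implementation of the WGCNA procedure: dynamic tree cut is replaced by
# a static cut plus eigengene merging, and module recovery on planted
# structure -- not numerical identity with the reference package -- is the
# accuracy contract.

#' Network parameters for module detection
#'
#' @param power Soft-thresholding exponent beta (default 9).
#' @param merge_cut_height Eigengene dissimilarity below which modules are
#'   merged; modules merge while eigengene correlation exceeds
#'   `1 - merge_cut_height` (default 0.26, so cor > 0.74).
#' @param min_module_size Minimum genes per module (default 35); smaller
#'   clusters are labelled grey.
#' @param cut_height Static cut height on the 1 - TOM dendrogram.
#' @param te_min Mean-TE floor of the gene filter.
#' @param variance_quantile Fraction of mean-passing genes kept by the
#'   variance filter (top 70% by default).
#' @param signed Use signed adjacency (`((1 + cor)/2)^power`) instead of
#'   the unsigned default `|cor|^power`.
#' @return List of class `"network_params"`.
#' @export
network_params <- function(power = 9, merge_cut_height = 0.26,
                           min_module_size = 35L, cut_height = 0.98,
                           te_min = 1, variance_quantile = 0.70,
                           signed = FALSE) {
  if (power < 1) stop("power must be >= 1")
  if (merge_cut_height <= 0 || merge_cut_height >= 1)
    stop("merge_cut_height must be in (0, 1)")
  if (min_module_size < 2L) stop("min_module_size must be >= 2")
  structure(list(power = power, merge_cut_height = merge_cut_height,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, te_min = te_min,
                 variance_quantile = variance_quantile, signed = signed),
            class = "network_params")
}

#' TE-based gene filter for network construction
#'
#' Keeps genes with mean TE at or above `te_min`, then among those the top
#' `variance_quantile` fraction by variance (ties broken by gene id so the
#' retained count is exact).
#'
#' @param te_matrix TE matrix, genes x samples.
#' @param params A [network_params()] object.
#' @return Character vector of retained gene ids.
#' @export
filter_te_genes <- function(te_matrix, params = network_params()) {
  te_matrix <- as.matrix(te_matrix)
  mean_pass <- rownames(te_matrix)[rowMeans(te_matrix) >= params$te_min]
  if (!length(mean_pass))
    stop("no gene passes the mean-TE filter; relax te_min")
  v <- apply(te_matrix[mean_pass, , drop = FALSE], 1, stats::var)
  keep_n <- floor(length(mean_pass) * params$variance_quantile)
  if (keep_n < 1L)
    stop("variance filter leaves no genes; relax variance_quantile")
  ord <- order(-v, mean_pass)  # ties by gene id
  mean_pass[ord][seq_len(keep_n)]
}

# Unsigned topological overlap similarity from an adjacency matrix with
# zero diagonal: TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
# L = A %*% A, k = row connectivity; diagonal set to 1.
tom_similarity <- function(adj) {
  diag(adj) <- 0
  l_mat <- adj %*% adj
  k <- rowSums(adj)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l_mat + adj) / denom
  diag(tom) <- 1
  tom
}

module_eigengene <- function(x) {
  # x: genes x samples; eigengene = first PC of standardized expression,
  # signed so the mean gene-eigengene correlation is non-negative
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (mean(stats::cor(t(xs), e)) < 0) e <- -e
  e
}

#' Detect co-expression modules
#'
#' @param expr Expression (TE) matrix, genes x samples, already filtered.
#' @param params A [network_params()] object.
#' @return List of class `"module_result"`: `labels` (named character,
#'   "grey" for unassigned), `eigengenes` (samples x modules matrix),
#'   `params`.
#' @export
detect_modules <- function(expr, params = network_params()) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4L) stop("module detection needs >= 4 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " constant gene(s)")
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < params$min_module_size)
    stop("fewer genes than min_module_size")
  cors <- stats::cor(t(expr))
  adj <- if (params$signed) ((1 + cors) / 2)^params$power else
    abs(cors)^params$power
  tom <- tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = params$cut_height)

  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  labels <- rep("grey", nrow(expr))
  names(labels) <- rownames(expr)
  for (m in seq_along(keep))
    labels[cl == as.integer(keep[m])] <- sprintf("ME%02d", m)

  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    eg <- sapply(mods, function(m)
      module_eigengene(expr[labels == m, , drop = FALSE]))
    ec <- stats::cor(eg)
    diag(ec) <- -Inf
    best <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (ec[best[1], best[2]] <= 1 - params$merge_cut_height) break
    pair <- sort(mods[best])
    labels[labels == pair[2]] <- pair[1]
  }
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(-tabulate(factor(labels, levels = mods)))]
  relabel <- stats::setNames(sprintf("ME%02d", seq_along(mods)), mods)
  labels[labels != "grey"] <- relabel[labels[labels != "grey"]]
  mods <- sort(unique(labels[labels != "grey"]))
  eigengenes <- matrix(NA_real_, ncol(expr), length(mods),
                       dimnames = list(colnames(expr), mods))
  for (m in mods)
    eigengenes[, m] <- module_eigengene(expr[labels == m, , drop = FALSE])
  structure(list(labels = labels, eigengenes = eigengenes, params = params,
                 expr = expr),
            class = "module_result")
}

#' Module-trait correlations, gene significance and module membership
#'
#' Pearson correlation of each module eigengene with each trait (two-sided
#' t-test p-values), per-gene gene significance `GS` (correlation with the
#' trait) and module membership `MM` (correlation with the gene's own
#' module eigengene).
#'
#' @param result A [detect_modules()] result.
#' @param traits Data frame, first column `sample_id`, remaining columns
#'   numeric or 0/1-coded traits aligned with the expression samples.
#' @return List with `module_trait` (data frame `module`, `trait`, `cor`,
#'   `p`) and `gene_stats` (data frame `gene_id`, `module`, per-trait GS
#'   columns, `MM`).
#' @export
module_trait_stats <- function(result, traits) {
  stopifnot(inherits(result, "module_result"))
  expr <- result$expr
  tr <- traits[match(colnames(expr), traits$sample_id), -1, drop = FALSE]
  if (anyNA(tr)) stop("traits missing for some samples")
  if (any(vapply(tr, function(x) stats::var(as.numeric(x)) == 0,
                 logical(1))))
    stop("constant trait: correlation undefined")
  n <- ncol(expr)
  cor_p <- function(r) {
    t_stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-12))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  mt <- list()
  for (m in colnames(result$eigengenes)) {
    for (v in names(tr)) {
      r <- stats::cor(result$eigengenes[, m], as.numeric(tr[[v]]))
      mt[[length(mt) + 1L]] <- data.frame(module = m, trait = v, cor = r,
                                          p = cor_p(r),
                                          stringsAsFactors = FALSE)
    }
  }
  gs <- sapply(names(tr), function(v)
    as.vector(stats::cor(t(expr), as.numeric(tr[[v]]))))
  colnames(gs) <- paste0("GS_", names(tr))
  mm <- rep(NA_real_, nrow(expr))
  for (m in colnames(result$eigengenes)) {
    idx <- result$labels == m
    mm[idx] <- as.vector(stats::cor(t(expr[idx, , drop = FALSE]),
                                    result$eigengenes[, m]))
  }
  list(module_trait = do.call(rbind, mt),
       gene_stats = data.frame(gene_id = rownames(expr),
                               module = unname(result$labels),
                               gs, MM = mm, stringsAsFactors = FALSE))
}

#' Hub-gene selection
#'
#' Hubs are genes with `|GS| > gs_min` and `|MM| > mm_min` inside modules
#' significantly associated with the trait (`p < alpha` on the
#' module-trait correlation).
#'
#' @param stats_result Output of [module_trait_stats()].
#' @param trait Trait name to use for GS and module significance.
#' @param gs_min,mm_min Absolute thresholds (defaults 0.4 / 0.7).
#' @param alpha Module-trait significance threshold.
#' @return Character vector of hub gene ids.
#' @export
select_hubs <- function(stats_result, trait, gs_min = 0.4, mm_min = 0.7,
                        alpha = 0.05) {
  mt <- stats_result$module_trait
  sig_mods <- mt$module[mt$trait == trait & mt$p < alpha]
  gstat <- stats_result$gene_stats
  gs_col <- paste0("GS_", trait)
  if (!gs_col %in% names(gstat)) stop("unknown trait: ", trait)
  hubs <- gstat$gene_id[gstat$module %in% sig_mods &
                          abs(gstat[[gs_col]]) > gs_min &
                          !is.na(gstat$MM) & abs(gstat$MM) > mm_min]
  sort(hubs)
}

#' @export
print.module_result <- function(x, ...) {
  tab <- table(x$labels)
  cat("Co-expression modules (", sum(names(tab) != "grey"),
      " modules, grey = unassigned)\n", sep = "")
  print(tab)
  invisible(x)
}
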