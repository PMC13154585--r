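# Differential expression and differential translation efficiency.
#
# The engine is a negative binomial GLM (log link) with per-sample
# log-size-factor offsets and a fixed per-gene dispersion alpha
# (variance mu + alpha mu^2). Differential TE is tested as the
# condition:assay interaction on the stacked RNA + RIBO counts of a gene,
# so genes, not samples, are the unit of fitting. Raw Wald p-values at 0.05
# are the default call threshold; no multiple-testing correction is applied
# unless requested.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across genes of the ratio
#' of a sample's count to the gene's geometric mean, taken over genes whose
#' geometric mean is positive.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no gene has a nonzero count in every sample; ",
         "consider a pseudo-reference fallback")
  gm <- exp(log_gm[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
    stats::median(cnt / gm))
  if (any(sf <= 0))
    stop("non-positive size factor; counts too sparse for median-of-ratios")
  unname(sf)
}

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per-gene dispersion on size-factor-normalized counts:
#' `alpha_hat = max(0, (s^2 - m) / m^2)` with mean and pooled within-group
#' variance taken across conditions, shrunk toward a fitted mean-dispersion
#' trend `a0 + a1/mean` with weight proportional to the within-gene degrees
#' of freedom against `prior_df` pseudo-observations.
#'
#' @param counts Count matrix, genes x samples.
#' @param condition Factor/character vector of per-sample conditions.
#' @param sf Size factors; computed from `counts` when `NULL`.
#' @param prior_df Prior degrees of freedom of the trend.
#' @return Numeric vector of per-gene dispersions (>= 0).
#' @export
estimate_dispersion <- function(counts, condition, sf = NULL,
                                prior_df = 10) {
  counts <- as.matrix(counts)
  condition <- factor(condition)
  if (ncol(counts) < 2L) stop("dispersion estimation needs >= 2 samples")
  if (any(table(condition) < 2L))
    stop("each condition needs >= 2 samples")
  if (is.null(sf)) sf <- size_factors(counts)
  z <- sweep(counts, 2, sf, "/")
  k <- nlevels(condition)
  n <- ncol(z)
  mu <- rowMeans(z)
  ss <- 0
  for (lev in levels(condition)) {
    zi <- z[, condition == lev, drop = FALSE]
    ss <- ss + rowSums((zi - rowMeans(zi))^2)
  }
  s2 <- ss / (n - k)
  raw <- pmax(0, (s2 - mu) / mu^2)
  raw[!is.finite(raw)] <- 0

  # parametric trend alpha(mu) = a0 + a1/mu on genes with signal
  use <- mu > 0 & raw > 0
  trend <- if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    a <- pmax(stats::coef(fit), 0)
    a[1] + a[2] / pmax(mu, 1e-8)
  } else {
    rep(stats::median(raw[mu > 0]), length(raw))
  }
  df <- n - k
  shrunk <- (df * raw + prior_df * trend) / (df + prior_df)
  pmax(shrunk, 1e-8)
}

nb_loglik <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-10)
  if (alpha <= 1e-12) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
}

#' Fit a negative binomial GLM with fixed dispersion
#'
#' Fisher-scoring IRLS for the NB log-linear model
#' `log mu = X beta + offset` with known dispersion `alpha`. Convergence
#' when the largest coefficient update falls below `tol` (default 1e-8)
#' within `max_iter` iterations; degenerate fits (e.g. all-zero counts) are
#' flagged, never silent.
#'
#' @param y Non-negative integer response vector.
#' @param X Design matrix (full column rank).
#' @param offset Per-observation offset (log size factors).
#' @param alpha NB dispersion (0 gives the Poisson limit).
#' @param tol,max_iter Convergence controls.
#' @return List of class `"nb_fit"`: `coefficients`, `se`, `alpha`,
#'   `deviance`, `loglik`, `converged`, `iter`, `mu`.
#' @export
fit_nb_glm <- function(y, X, offset = rep(0, length(y)), alpha = 0,
                       tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full column rank")
  if (any(!is.finite(offset))) stop("offsets must be finite")
  n <- length(y)
  beta <- numeric(ncol(X))
  beta[1] <- log(max(mean(y / exp(offset)), 1e-4))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    new_beta <- tryCatch(
      drop(solve(XtW %*% X, XtW %*% z)),
      error = function(e) beta)
    new_beta <- pmin(pmax(new_beta, -30), 30)
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(pmax(diag(solve(info)), 0)),
                 error = function(e) rep(NA_real_, ncol(X)))
  ll <- nb_loglik(y, mu, alpha)
  ll_sat <- nb_loglik(y, pmax(y, 1e-10), alpha)
  if (all(y == 0)) converged <- FALSE
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 alpha = alpha,
                 deviance = 2 * (ll_sat - ll),
                 loglik = ll,
                 converged = converged, iter = iter, mu = mu),
            class = "nb_fit")
}

wald_p <- function(est, se) {
  p <- 2 * stats::pnorm(-abs(est / se))
  p[!is.finite(p)] <- 1
  p
}

as_condition <- function(condition) {
  condition <- as.character(condition)
  levs <- unique(condition)
  if (all(c("normal", "tumour") %in% levs)) levs <- c("normal", "tumour")
  factor(condition, levels = levs)
}

#' Per-gene differential expression test (NB Wald)
#'
#' Fits, per gene, `count ~ condition` as an NB GLM with log-size-factor
#' offsets and trend-shrunk dispersions, and Wald-tests the condition
#' coefficient. Genes that are zero in every sample are reported with
#' `log2fc = 0`, `p = 1` (documented convention), never dropped from the
#' output.
#'
#' @param counts Count matrix, genes x samples.
#' @param condition Per-sample condition labels; `"normal"` is used as the
#'   reference level when present.
#' @param sf Optional size factors.
#' @param dispersions Optional per-gene dispersions.
#' @return Data frame `gene_id`, `base_mean`, `log2fc`, `p`.
#' @export
test_deg <- function(counts, condition, sf = NULL, dispersions = NULL) {
  counts <- as.matrix(counts)
  condition <- as_condition(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions required")
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, condition, sf)
  X <- stats::model.matrix(~condition)
  off <- log(sf)
  n_g <- nrow(counts)
  l2fc <- numeric(n_g); p <- numeric(n_g)
  for (g in seq_len(n_g)) {
    y <- counts[g, ]
    if (all(y == 0)) { l2fc[g] <- 0; p[g] <- 1; next }
    fit <- fit_nb_glm(y, X, off, dispersions[g])
    l2fc[g] <- fit$coefficients[2] / log(2)
    p[g] <- wald_p(fit$coefficients[2], fit$se[2])
  }
  data.frame(gene_id = rownames(counts) %||% sprintf("G%05d", seq_len(n_g)),
             base_mean = rowMeans(sweep(counts, 2, sf, "/")),
             log2fc = l2fc, p = p, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Differential translation efficiency via the interaction model
#'
#' For each gene, stacks the RNA and RIBO counts and fits one NB GLM with
#' design `~ condition + assay + condition:assay`, per-assay size-factor
#' offsets, and a dispersion shared between the assays of the gene (the
#' mean of the two per-assay trend-shrunk estimates). The interaction
#' coefficient is the log fold-change of TE between conditions; its Wald
#' p-value calls differential TE.
#'
#' @param rna,ribo Count matrices with identical gene and sample indices.
#' @param condition Per-sample condition labels (shared by both assays).
#' @return Data frame `gene_id`, `log2fc_te`, `p`.
#' @export
test_dteg <- function(rna, ribo, condition) {
  rna <- as.matrix(rna); ribo <- as.matrix(ribo)
  if (!identical(dim(rna), dim(ribo)))
    stop("rna and ribo must share gene and sample indices")
  if (!is.null(rownames(rna)) && !identical(rownames(rna), rownames(ribo)))
    stop("rna and ribo gene ids differ")
  condition <- as_condition(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions required")
  sf_rna <- size_factors(rna)
  sf_ribo <- size_factors(ribo)
  disp_rna <- estimate_dispersion(rna, condition, sf_rna)
  disp_ribo <- estimate_dispersion(ribo, condition, sf_ribo)
  disp <- (disp_rna + disp_ribo) / 2

  cond2 <- factor(rep(as.character(condition), 2L),
                  levels = levels(condition))
  assay <- factor(rep(c("rna", "ribo"), each = ncol(rna)),
                  levels = c("rna", "ribo"))
  X <- stats::model.matrix(~ cond2 + assay + cond2:assay)
  off <- log(c(sf_rna, sf_ribo))
  n_g <- nrow(rna)
  l2fc <- numeric(n_g); p <- numeric(n_g)
  ix <- ncol(X)  # interaction column
  for (g in seq_len(n_g)) {
    y <- c(rna[g, ], ribo[g, ])
    if (all(y == 0)) { l2fc[g] <- 0; p[g] <- 1; next }
    fit <- fit_nb_glm(y, X, off, disp[g])
    l2fc[g] <- fit$coefficients[ix] / log(2)
    p[g] <- wald_p(fit$coefficients[ix], fit$se[ix])
  }
  data.frame(gene_id = rownames(rna) %||% sprintf("G%05d", seq_len(n_g)),
             log2fc_te = l2fc, p = p, stringsAsFactors = FALSE)
}

#' Per-gene, per-group translation efficiency
#'
#' TE is the ratio of the group-mean normalized RIBO count to the
#' group-mean normalized RNA count; `epsilon` is added to the denominator
#' only when it is zero.
#'
#' @param rna,ribo Count matrices with matching indices.
#' @param condition Per-sample condition labels.
#' @param sf_rna,sf_ribo Optional per-assay size factors.
#' @param epsilon Guard added to zero denominators.
#' @return Matrix genes x conditions of TE values.
#' @export
compute_te <- function(rna, ribo, condition, sf_rna = NULL, sf_ribo = NULL,
                       epsilon = 1) {
  rna <- as.matrix(rna); ribo <- as.matrix(ribo)
  stopifnot(identical(dim(rna), dim(ribo)))
  condition <- as_condition(condition)
  if (is.null(sf_rna)) sf_rna <- size_factors(rna)
  if (is.null(sf_ribo)) sf_ribo <- size_factors(ribo)
  zr <- sweep(rna, 2, sf_rna, "/")
  zb <- sweep(ribo, 2, sf_ribo, "/")
  te <- sapply(levels(condition), function(lev) {
    num <- rowMeans(zb[, condition == lev, drop = FALSE])
    den <- rowMeans(zr[, condition == lev, drop = FALSE])
    num / ifelse(den == 0, den + epsilon, den)
  })
  rownames(te) <- rownames(rna)
  te
}

#' Four-class regulatory categorization
#'
#' Combines RNA-level and TE-level calls into the regulatory classes:
#' `forwarded` (RNA significant only), `exclusive` (TE significant only),
#' `intensified` (both significant, same sign), `buffered` (both
#' significant, opposing signs), else `not_significant`.
#'
#' @param p_rna,log2fc_rna,p_te,log2fc_te Per-gene vectors.
#' @param alpha_sig Significance threshold on raw p-values.
#' @return Character vector of class labels.
#' @export
classify_regulatory <- function(p_rna, log2fc_rna, p_te, log2fc_te,
                                alpha_sig = 0.05) {
  if (anyNA(p_rna) || anyNA(p_te))
    stop("missing p-values; classification requires complete results")
  sig_r <- p_rna < alpha_sig
  sig_t <- p_te < alpha_sig
  cls <- rep("not_significant", length(p_rna))
  cls[sig_r & !sig_t] <- "forwarded"
  cls[!sig_r & sig_t] <- "exclusive"
  same <- sign(log2fc_rna) == sign(log2fc_te)
  cls[sig_r & sig_t & same] <- "intensified"
  cls[sig_r & sig_t & !same] <- "buffered"
  cls
}

#' Differential translation analysis of paired RNA-seq / Ribo-seq counts
#'
#' The front door of the package's statistical engine. Runs per-assay
#' size-factor normalization, NB Wald tests for differential expression at
#' the RNA and RIBO levels, the interaction test for differential TE, TE
#' summaries per condition, and the four-class regulatory categorization.
#'
#' @param rna,ribo Count matrices (genes x samples, identical indices).
#' @param condition Per-sample condition labels (two levels; `"normal"` is
#'   the reference when present).
#' @param alpha_sig Raw p-value threshold for significance calls.
#' @param fdr If `TRUE`, classify on Benjamini-Hochberg adjusted p-values
#'   instead of raw ones (off by default, matching the raw-p calling
#'   convention of the emulated analysis).
#' @return Object of class `"dte_fit"` with `results` (one row per gene:
#'   log2 fold-changes, p-values, TE per group, class), `size_factors`,
#'   `alpha_sig`, `call`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 60, n_tumour = 6,
#'                                   n_normal = 6, seed = 42))
#' fit <- dte(sim$rna, sim$ribo, sim$design$condition)
#' summary(fit)
#' @export
dte <- function(rna, ribo, condition, alpha_sig = 0.05, fdr = FALSE) {
  rna <- as.matrix(rna); ribo <- as.matrix(ribo)
  keep <- rowSums(rna) + rowSums(ribo) > 0  # drop genes zero everywhere
  rna_k <- rna[keep, , drop = FALSE]
  ribo_k <- ribo[keep, , drop = FALSE]
  deg_rna <- test_deg(rna_k, condition)
  deg_ribo <- test_deg(ribo_k, condition)
  dteg <- test_dteg(rna_k, ribo_k, condition)
  te <- compute_te(rna_k, ribo_k, condition)
  p_rna <- if (fdr) stats::p.adjust(deg_rna$p, "BH") else deg_rna$p
  p_te <- if (fdr) stats::p.adjust(dteg$p, "BH") else dteg$p
  cls <- classify_regulatory(p_rna, deg_rna$log2fc, p_te, dteg$log2fc_te,
                             alpha_sig)
  res <- data.frame(gene_id = deg_rna$gene_id,
                    base_mean = deg_rna$base_mean,
                    log2fc_rna = deg_rna$log2fc, p_rna = deg_rna$p,
                    log2fc_ribo = deg_ribo$log2fc, p_ribo = deg_ribo$p,
                    log2fc_te = dteg$log2fc_te, p_te = dteg$p,
                    stringsAsFactors = FALSE)
  te_df <- as.data.frame(te)
  names(te_df) <- paste0("te_", names(te_df))
  res <- cbind(res, te_df, class = cls, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(results = res, size_factors = list(
    rna = size_factors(rna_k), ribo = size_factors(ribo_k)),
    n_dropped = sum(!keep), alpha_sig = alpha_sig, fdr = fdr,
    call = match.call()), class = "dte_fit")
}

#' @export
print.dte_fit <- function(x, ...) {
  cat("Differential translation efficiency fit\n")
  cat("  genes analysed:", nrow(x$results),
      " (", x$n_dropped, "all-zero genes excluded )\n")
  cat("  significance threshold:", x$alpha_sig,
      if (x$fdr) "(BH-adjusted)" else "(raw p)", "\n")
  print(table(x$results$class))
  invisible(x)
}

#' @export
summary.dte_fit <- function(object, ...) {
  r <- object$results
  up <- function(p, fc) sum(p < object$alpha_sig & fc > 0)
  dn <- function(p, fc) sum(p < object$alpha_sig & fc < 0)
  out <- list(
    n_genes = nrow(r),
    deg = c(up = up(r$p_rna, r$log2fc_rna), down = dn(r$p_rna, r$log2fc_rna)),
    dteg = c(up = up(r$p_te, r$log2fc_te), down = dn(r$p_te, r$log2fc_te)),
    classes = table(factor(r$class, levels = c(
      "forwarded", "exclusive", "intensified", "buffered",
      "not_significant"))))
  class(out) <- "summary.dte_fit"
  out
}

#' @export
print.summary.dte_fit <- function(x, ...) {
  cat("Genes analysed:", x$n_genes, "\n")
  cat("DEGs (RNA level):  ", x$deg["up"], "up /", x$deg["down"], "down\n")
  cat("DTEGs (TE level):  ", x$dteg["up"], "up /", x$dteg["down"], "down\n")
  cat("Regulatory classes:\n")
  print(x$classes)
  invisible(x)
}

#' @export
coef.dte_fit <- function(object, ...) {
  r <- object$results
  m <- cbind(log2fc_rna = r$log2fc_rna, log2fc_ribo = r$log2fc_ribo,
             log2fc_te = r$log2fc_te)
  rownames(m) <- r$gene_id
  m
}

#' Scatter of transcriptional versus translational fold-changes
#'
#' @param x A `dte_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dte_fit <- function(x, ...) {
  r <- x$results
  cols <- c(forwarded = "#1b9e77", exclusive = "#d95f02",
            intensified = "#7570b3", buffered = "#e7298a",
            not_significant = "grey70")
  graphics::plot(r$log2fc_rna, r$log2fc_te, col = cols[r$class], pch = 16,
                 cex = 0.6, xlab = "log2 fold-change (RNA)",
                 ylab = "log2 fold-change (TE)", ...)
  graphics::abline(h = 0, v = 0, col = "grey50", lty = 2)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(x)
}
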