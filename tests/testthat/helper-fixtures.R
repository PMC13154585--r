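# Shared toy fixtures, built in code.

# Minimal two-transcript annotation: one coding, one lncRNA.
toy_annotation <- function() {
  data.frame(
    transcript_id = c("TXC", "TXL"),
    gene_id = c("GC", "GL"),
    gene_biotype = c("protein_coding", "lncRNA"),
    tx_len = c(400L, 300L),
    cds_start = c(60L, NA),
    cds_end = c(360L, NA),
    stringsAsFactors = FALSE)
}

# One ORF call-set row.
orf_row <- function(orf_id, start, end, tx = "TXC", caller = "orfquant") {
  data.frame(orf_id = orf_id, transcript_id = tx, gene_id = "GC",
             strand = "+", start = start, end = end, caller = caller,
             stringsAsFactors = FALSE)
}

# Named list of per-sample call sets from a list of orf_id vectors,
# using a shared ORF coordinate table.
toy_callsets <- function(detections, coords) {
  lapply(detections, function(ids) {
    if (!length(ids)) return(coords[0, ])
    do.call(rbind, lapply(ids, function(i)
      coords[coords$orf_id == i, , drop = FALSE]))
  })
}

# Two-sided Fisher p by direct hypergeometric enumeration (independent
# oracle for stats::fisher.test): tables with fixed margins, summing
# probabilities <= that of the observed table.
fisher_enum_p <- function(k1, n1, k2, n2) {
  big_k <- k1 + k2
  xs <- max(0L, big_k - n2):min(n1, big_k)
  probs <- stats::dhyper(xs, n1, n2, big_k)
  obs <- stats::dhyper(k1, n1, n2, big_k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force NB/Poisson likelihood maximization on a two-column design
# (intercept + group indicator) by two-stage grid search; returns the
# maximal log-likelihood (independent oracle for fit_nb_glm).
grid_loglik <- function(y, group, offset = rep(0, length(y)), alpha = 0) {
  ll <- function(b0, b1) {
    mu <- exp(b0 + b1 * group + offset)
    if (alpha <= 1e-12) sum(stats::dpois(y, mu, log = TRUE))
    else sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  best <- c(log(mean(y) + 0.5), 0)
  width <- 2
  for (step in c(0.05, 0.002, 1e-4)) {
    b0s <- seq(best[1] - width, best[1] + width, by = step)
    b1s <- seq(best[2] - width, best[2] + width, by = step)
    grid <- outer(b0s, b1s, Vectorize(ll))
    idx <- arrayInd(which.max(grid), dim(grid))
    best <- c(b0s[idx[1]], b1s[idx[2]])
    width <- step * 2
  }
  ll(best[1], best[2])
}
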