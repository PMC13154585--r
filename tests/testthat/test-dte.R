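test_that("median-of-ratios size factors match hand computation", {
  counts <- rbind(g1 = c(2, 8), g2 = c(50, 200))
  expect_equal(size_factors(counts), c(0.5, 2.0))
  # identical columns give unit factors
  same <- matrix(rep(c(3, 10, 100), 4), 3, 4)
  expect_equal(size_factors(same), rep(1, 4))
  # scaling a column scales its factor relative to the others
  sc <- same
  sc[, 2] <- sc[, 2] * 5
  sf <- size_factors(sc)
  expect_equal(sf[2] / sf[1], 5)
  expect_equal(sf[c(1, 3, 4)], rep(sf[1], 3))
  expect_error(size_factors(rbind(c(0, 1), c(1, 0))), "nonzero")
})

test_that("dispersion estimates recover the simulated truth", {
  set.seed(101)
  n <- 20
  cond <- rep(c("a", "b"), each = n / 2)
  mu <- stats::rlnorm(800, log(100), 0.7)
  pois <- matrix(stats::rpois(800 * n, mu), 800, n)
  a_hat <- estimate_dispersion(pois, cond, sf = rep(1, n))
  expect_lte(stats::median(a_hat), 0.01)
  mu2 <- stats::rlnorm(2000, log(100), 0.7)
  nb <- matrix(stats::rnbinom(2000 * n, mu = mu2, size = 1 / 0.2), 2000, n)
  a_nb <- estimate_dispersion(nb, cond, sf = rep(1, n))
  expect_gte(stats::median(a_nb), 0.1)
  expect_lte(stats::median(a_nb), 0.3)
  # constant gene: raw estimate truncates at (numerically) zero
  const <- rbind(rep(5, n), matrix(stats::rpois(100 * n, 50), 100, n))
  a_c <- estimate_dispersion(const, cond, sf = rep(1, n), prior_df = 0)
  expect_lte(a_c[1], 1e-6)
  expect_error(estimate_dispersion(pois[, 1, drop = FALSE], "a"), "samples")
})

test_that("the Poisson-limit GLM matches the closed-form two-group MLE", {
  y <- c(10, 10, 10, 20, 20, 20)
  X <- cbind(intercept = 1, group = c(0, 0, 0, 1, 1, 1))
  fit <- fit_nb_glm(y, X, alpha = 0)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients),
               c(log(10), log(2)), tolerance = 1e-7)
  # equal group means: effect -> 0
  fit0 <- fit_nb_glm(rep(7, 6), X, alpha = 0)
  expect_equal(unname(fit0$coefficients[2]), 0, tolerance = 1e-7)
})

test_that("GLM deviance matches brute-force grid maximization", {
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))
  set.seed(7)
  for (alpha in c(0, 0.1, 0.4)) {
    y <- stats::rnbinom(6, mu = c(15, 15, 15, 40, 40, 40),
                        size = if (alpha == 0) Inf else 1 / alpha)
    off <- log(c(0.8, 1, 1.2, 0.9, 1.1, 1))
    fit <- fit_nb_glm(y, X, off, alpha)
    ll_grid <- grid_loglik(y, X[, 2], off, alpha)
    expect_lt(abs(fit$loglik - ll_grid), 5e-5)
  }
})

test_that("GLM agrees with the glm() negative binomial family", {
  skip_if_not_installed("MASS")
  set.seed(12)
  X <- cbind(1, rep(c(0, 1), each = 4))
  y <- stats::rnbinom(8, mu = rep(c(20, 60), each = 4), size = 5)
  off <- log(runif(8, 0.7, 1.4))
  fit <- fit_nb_glm(y, X, off, alpha = 0.2)
  ref <- stats::glm(y ~ X[, 2] + offset(off),
                    family = MASS::negative.binomial(theta = 5))
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-5)
})

test_that("degenerate all-zero input is flagged, never silent", {
  X <- cbind(1, c(0, 0, 1, 1))
  fit <- fit_nb_glm(c(0, 0, 0, 0), X, alpha = 0.1)
  expect_false(fit$converged)
  expect_error(fit_nb_glm(c(1, 2, 3, 4), cbind(1, 1), alpha = 0), "rank")
})

test_that("DEG test recovers planted fold-changes with power", {
  cfg <- sim_config(n_genes = 500, n_tumour = 10, n_normal = 10,
                    class_fractions = c(forwarded = 0.3, null = 0.7),
                    lfc_rna = 2, dispersion = 0.1, seed = 91)
  sim <- simulate_counts(cfg)
  deg <- test_deg(sim$rna, sim$design$condition)
  planted <- sim$truth$class == "forwarded"
  called <- deg$p < 0.05 &
    sign(deg$log2fc) == sign(sim$truth$lfc_rna)
  expect_gte(mean(called[planted]), 0.9)
  # all-zero genes are reported with the documented convention
  rna0 <- sim$rna
  rna0[1, ] <- 0
  deg0 <- test_deg(rna0, sim$design$condition)
  expect_identical(deg0$p[1], 1)
  expect_identical(deg0$log2fc[1], 0)
})

test_that("interaction test sees TE shifts and cancels shared shifts", {
  # stable background plus one focal gene, noise-free at the means
  n <- 6
  cond <- rep(c("normal", "tumour"), each = n / 2)
  base <- matrix(rep(c(50, 80, 120, 200, 30, 60, 90, 150, 70, 110),
                     each = n), 10, n, byrow = TRUE)
  rna <- rbind(base, focal = rep(100, n))
  ribo <- rbind(base, focal = c(rep(100, n / 2), rep(400, n / 2)))
  rownames(rna) <- rownames(ribo) <- c(sprintf("b%02d", 1:10), "focal")
  out <- test_dteg(rna, ribo, cond)
  expect_equal(out$log2fc_te[out$gene_id == "focal"], 2, tolerance = 0.05)
  # both assays shifting 2-fold: interaction cancels
  rna2 <- rbind(base, focal = c(rep(100, n / 2), rep(200, n / 2)))
  ribo2 <- rbind(base, focal = c(rep(100, n / 2), rep(200, n / 2)))
  rownames(rna2) <- rownames(ribo2) <- rownames(rna)
  out2 <- test_dteg(rna2, ribo2, cond)
  expect_equal(out2$log2fc_te[out2$gene_id == "focal"], 0, tolerance = 0.05)
  expect_gt(out2$p[out2$gene_id == "focal"], 0.5)
  expect_error(test_dteg(rna[, -1], ribo, cond), "share")
})

test_that("TE is the normalized ribo/rna mean ratio with the zero guard", {
  rna <- rbind(g1 = c(4, 4), g2 = c(0, 0))
  ribo <- rbind(g1 = c(10, 10), g2 = c(5, 5))
  colnames(rna) <- colnames(ribo) <- c("s1", "s2")
  te <- compute_te(rna, ribo, c("tumour", "tumour"),
                   sf_rna = c(1, 1), sf_ribo = c(1, 1))
  expect_equal(unname(te[, "tumour"]), c(2.5, 5))
  te2 <- compute_te(rna, 2 * ribo, c("tumour", "tumour"),
                    sf_rna = c(1, 1), sf_ribo = c(1, 1))
  expect_equal(unname(te2[, 1]), 2 * unname(te[, 1]))
})

test_that("regulatory classification is total, exclusive and label-stable", {
  p_rna <- c(0.01, 0.5, 0.01, 0.01, 0.5)
  p_te <- c(0.5, 0.01, 0.01, 0.01, 0.5)
  l_rna <- c(1, 0, 1, 1, 0)
  l_te <- c(0, 1, 1, -1, 0)
  cls <- classify_regulatory(p_rna, l_rna, p_te, l_te)
  expect_identical(cls, c("forwarded", "exclusive", "intensified",
                          "buffered", "not_significant"))
  # permutation equivariance
  perm <- c(3, 5, 1, 2, 4)
  expect_identical(classify_regulatory(p_rna[perm], l_rna[perm],
                                       p_te[perm], l_te[perm]), cls[perm])
  expect_error(classify_regulatory(c(0.1, NA), c(0, 0), c(0.1, 0.1),
                                   c(0, 0)), "missing")
})

test_that("the dte() front door returns a coherent classed fit", {
  sim <- simulate_counts(sim_config(n_genes = 80, n_tumour = 6,
                                    n_normal = 6, seed = 42))
  fit <- dte(sim$rna, sim$ribo, sim$design$condition)
  expect_s3_class(fit, "dte_fit")
  r <- fit$results
  expect_identical(nrow(r) + fit$n_dropped, 80L)
  expect_true(all(r$class %in% c("forwarded", "exclusive", "intensified",
                                 "buffered", "not_significant")))
  # class counts partition the analysed genes
  s <- summary(fit)
  expect_identical(sum(s$classes), nrow(r))
  expect_identical(dim(coef(fit)), c(nrow(r), 3L))
  # significant class implies a significant test (invariant)
  sig <- r$class != "not_significant"
  expect_true(all(r$p_rna[sig] < 0.05 | r$p_te[sig] < 0.05))
})
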