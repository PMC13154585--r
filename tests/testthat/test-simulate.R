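test_that("count simulation has the promised shape and is reproducible", {
  cfg <- sim_config(n_genes = 100, n_tumour = 5, n_normal = 5, seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(dim(a$rna), c(100L, 10L))
  expect_identical(dim(a$ribo), c(100L, 10L))
  expect_identical(dimnames(a$rna), dimnames(a$ribo))
  expect_identical(a$rna, b$rna)
  expect_identical(a$ribo, b$ribo)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_counts(sim_config(n_genes = 100, n_tumour = 5,
                                   n_normal = 5, seed = 8))
  expect_false(identical(a$rna, c_$rna))
})

test_that("degenerate class configuration plants only the null class", {
  cfg <- sim_config(n_genes = 50, class_fractions = c(null = 1), seed = 1)
  sim <- simulate_counts(cfg)
  expect_setequal(unique(sim$truth$class), "not_significant")
  expect_true(all(sim$truth$lfc_rna == 0 & sim$truth$lfc_te == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_fractions = c(null = 0.5)), "sum to 1")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(orf_dropout = 1), "orf_dropout")
  expect_error(sim_config(n_genes = 0), ">= 1")
})

test_that("simulated counts match the NB mean-variance law", {
  # moment check at n >= 10,000 draws: var ~ mu + alpha mu^2
  for (alpha in c(0, 0.1)) {
    set.seed(42)
    mu <- 50
    x <- translatomics:::rnbinom_mv(20000, mu, alpha)
    expect_equal(mean(x), mu, tolerance = 0.02)
    expect_equal(stats::var(x), mu + alpha * mu^2, tolerance = 0.08)
  }
})

test_that("per-gene TE ratios concentrate when biological noise is shared", {
  cfg <- sim_config(n_genes = 500, n_tumour = 20, n_normal = 20,
                    class_fractions = c(null = 1), dispersion = 0.05,
                    shared_dispersion = 1, baseline_mean = 500,
                    baseline_sdlog = 0.5, seed = 7)
  sim <- simulate_counts(cfg)
  zr <- sweep(sim$rna, 2, size_factors(sim$rna), "/")
  zb <- sweep(sim$ribo, 2, size_factors(sim$ribo), "/")
  for (g in c("tumour", "normal")) {
    idx <- sim$design$condition == g
    ratio <- rowMeans(zb[, idx]) / rowMeans(zr[, idx])
    expect_gte(mean(abs(ratio - 1) < 0.1), 0.95)
  }
})

test_that("planted TE fold-changes appear in the RIBO/RNA mean ratio", {
  cfg <- sim_config(n_genes = 400, n_tumour = 20, n_normal = 20,
                    class_fractions = c(exclusive = 0.5, null = 0.5),
                    lfc_te = 2, dispersion = 0.05, shared_dispersion = 1,
                    baseline_mean = 500, baseline_sdlog = 0.5, seed = 3)
  sim <- simulate_counts(cfg)
  zr <- sweep(sim$rna, 2, size_factors(sim$rna), "/")
  zb <- sweep(sim$ribo, 2, size_factors(sim$ribo), "/")
  tum <- sim$design$condition == "tumour"
  te_t <- rowMeans(zb[, tum]) / rowMeans(zr[, tum])
  te_n <- rowMeans(zb[, !tum]) / rowMeans(zr[, !tum])
  lfc_hat <- log2(te_t / te_n)
  up <- sim$truth$lfc_te > 0
  dn <- sim$truth$lfc_te < 0
  expect_equal(mean(lfc_hat[up]), 2, tolerance = 0.1)
  expect_equal(mean(lfc_hat[dn]), -2, tolerance = 0.1)
  expect_equal(mean(lfc_hat[sim$truth$lfc_te == 0]), 0, tolerance = 0.1)
})

test_that("ORF call sets honour dropout, specificity and decoy planting", {
  cfg <- sim_config(orf_dropout = 0, seed = 11)
  so <- simulate_orf_callsets(cfg, n_orfs = 100)
  # zero dropout: every expressed ORF detected in every sample of its group
  tum_samples <- so$design$sample_id[so$design$condition == "tumour"]
  expressed_t <- so$truth$orf_id[so$truth$expressed_tumour]
  for (s in tum_samples[1:3])
    expect_true(all(expressed_t %in% so$callsets[[s]]$orf_id))
  # tumour-specific ORFs never appear in normal samples
  nor_samples <- so$design$sample_id[so$design$condition == "normal"]
  ts <- so$truth$orf_id[so$truth$spec_class == "tumour_specific"]
  for (s in nor_samples)
    expect_length(intersect(ts, so$callsets[[s]]$orf_id), 0)
  # decoy pairs share a start with their primary and are shorter
  dup <- so$orfs[!is.na(so$orfs$dup_of), ]
  prim <- so$orfs[match(dup$dup_of, so$orfs$orf_id), ]
  expect_true(all(dup$start == prim$start))
  expect_true(all(dup$length < prim$length))
})

test_that("with dropout, detection is per-sample and truth has no orphans", {
  cfg <- sim_config(orf_dropout = 0.3, seed = 13)
  so <- simulate_orf_callsets(cfg, n_orfs = 120)
  det <- table(unlist(lapply(so$callsets, `[[`, "orf_id")))
  # every detected ORF has a truth record, and vice versa for expressed ORFs
  expect_true(all(names(det) %in% so$truth$orf_id))
  detected_frac <- mean(so$truth$orf_id[so$truth$spec_class != "neither"]
                        %in% names(det))
  expect_gt(detected_frac, 0.99)
  expect_false(any(so$truth$orf_id[so$truth$spec_class == "neither"]
                   %in% names(det)))
})

test_that("P-site reads follow the configured geometry", {
  ann <- simulate_annotation(seed = 2)
  expect_error(simulate_psite_reads(ann, offset = 30, read_length = 30),
               "offset")
  r <- simulate_psite_reads(ann, 2000, read_length = NULL,
                            length_range = c(25, 50), seed = 4)
  expect_true(all(r$length >= 25 & r$length <= 50))
  # noise-free reads sit exactly 12 nt upstream of frame-0 positions
  r0 <- simulate_psite_reads(ann, 2000, noise = 0, offset = 12, seed = 4)
  cs <- ann$cds_start[match(r0$transcript_id, ann$transcript_id)]
  expect_true(all((r0$pos5 + 12 - cs) %% 3 == 0))
})

test_that("feature prevalences land within binomial bounds of the target", {
  fp <- simulate_features_and_peptides(
    sprintf("T%02d", 1:50), sprintf("C%02d", 1:50),
    orf_proteins = character(0), orf_groups = character(0), seed = 5)
  f <- fp$features
  is_t <- f$gene_id %in% sprintf("T%02d", 1:50)
  # binomial 95% bounds at n = 50: 0.8 +/- 1.96*sqrt(.8*.2/50) ~ 0.11
  expect_lt(abs(mean(f$n_m6a_sites[is_t] > 0) - 0.8), 0.12)
  expect_lt(abs(mean(f$n_m6a_sites[!is_t] > 0) - 0.2), 0.12)
  expect_equal(f$cumulative_m6a[f$n_m6a_sites == 0],
               rep(0, sum(f$n_m6a_sites == 0)))
})

test_that("peptides are real substrings with group-restricted presence", {
  prot <- c(ORFT = paste(rep("ACDEFGHIKL", 8), collapse = ""),
            ORFN = paste(rep("MNPQRSTVWY", 8), collapse = ""),
            ORFB = paste(rep("LKIHGFEDCA", 8), collapse = ""))
  fp <- simulate_features_and_peptides(
    "g1", "g2", prot, c(ORFT = "tumour", ORFN = "normal", ORFB = "both"),
    n_peptides_per_orf = 4, seed = 9)
  expect_true(all(nchar(fp$peptides$peptide) >= 7 &
                    nchar(fp$peptides$peptide) <= 16))
  for (i in seq_len(nrow(fp$truth))) {
    src <- prot[[fp$truth$source_orf[i]]]
    expect_true(grepl(fp$truth$peptide[i], src, fixed = TRUE))
  }
  # tumour-only peptides never appear in normal samples
  tum_only <- fp$truth$peptide[fp$truth$group == "tumour"]
  nor_lists <- fp$peptides$peptide[fp$peptides$group == "normal"]
  expect_length(intersect(tum_only, nor_lists), 0)
  # out-of-window planted lengths are recorded but not emitted
  fp6 <- simulate_features_and_peptides(
    "g1", "g2", prot, c(ORFT = "tumour", ORFN = "normal", ORFB = "both"),
    n_peptides_per_orf = 3, peptide_length_range = c(5, 6), seed = 9)
  expect_true(all(!fp6$truth$emitted))
  expect_identical(nrow(fp6$peptides), 0L)
})

test_that("planted modules carry the configured correlation structure", {
  cfg <- sim_config(n_tumour = 30, module_spec = list(
    list(size = 50, r = 0.9, trait = TRUE),
    list(size = 60, r = 0.9, trait = FALSE)), seed = 21)
  md <- simulate_module_data(cfg)
  expect_error(simulate_module_data(
    sim_config(module_spec = list(), seed = 1)), "non-empty")
  for (m in c("M01", "M02")) {
    idx <- md$truth$module == m
    cors <- stats::cor(t(md$te[idx, ]))
    expect_gte(mean(cors[upper.tri(cors)]), 0.8)
  }
  bg <- md$truth$module == "background"
  cors_bg <- stats::cor(t(md$te[which(bg)[1:50], ]))
  expect_lt(mean(abs(cors_bg[upper.tri(cors_bg)])), 0.25)
  # trait-associated module's mean profile tracks the trait
  m1 <- colMeans(md$te[md$truth$module == "M01", ])
  expect_gt(abs(stats::cor(m1, md$traits$trait)), 0.6)
})
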