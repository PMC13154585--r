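coords3 <- rbind(orf_row("ORFA", 60, 360), orf_row("ORFB", 0, 30, "TXL"),
                 orf_row("ORFC", 63, 300))

test_that("the per-group detection threshold retains and discards correctly", {
  groups <- c(T1 = "tumour", T2 = "tumour", N1 = "normal", N2 = "normal")
  # ORFA in 2 tumour samples -> retained; ORFB in 1 tumour + 1 normal ->
  # discarded (no group reaches 2); ORFC in 2 normal -> retained
  cs <- toy_callsets(list(T1 = c("ORFA", "ORFB"), T2 = "ORFA",
                          N1 = c("ORFB", "ORFC"), N2 = "ORFC"), coords3)
  cat_df <- consolidate_orfs(cs, groups, min_samples = 2)
  expect_setequal(cat_df$orf_id, c("ORFA", "ORFC"))
  expect_true(cat_df$tumour_retained[cat_df$orf_id == "ORFA"])
  expect_false(cat_df$normal_retained[cat_df$orf_id == "ORFA"])
  expect_error(consolidate_orfs(cs, groups[-1]), "unlabelled")
})

test_that("longest-ORF dedup keeps the longest of shared-coordinate groups", {
  groups <- c(T1 = "tumour", T2 = "tumour")
  coords <- rbind(orf_row("A", 60, 360),   # 300 nt
                  orf_row("B", 60, 210),   # 150 nt, shares start with A
                  orf_row("C", 120, 360),  # shares end with A
                  orf_row("D", 0, 90, "TXL"))
  cs <- toy_callsets(list(T1 = c("A", "B", "C", "D"),
                          T2 = c("A", "B", "C", "D")), coords)
  cat_df <- consolidate_orfs(cs, groups)
  expect_setequal(cat_df$orf_id, c("A", "D"))
  # order independence: reversing the call-set rows changes nothing
  cs_rev <- lapply(cs, function(x) x[rev(seq_len(nrow(x))), ])
  cat_rev <- consolidate_orfs(cs_rev, groups)
  expect_identical(cat_df$orf_id, cat_rev$orf_id)
  # equal lengths sharing a start: smallest start then lexicographic id
  coords_tie <- rbind(orf_row("Z", 60, 210), orf_row("Y", 60, 210))
  cs_tie <- toy_callsets(list(T1 = c("Z", "Y"), T2 = c("Z", "Y")),
                         coords_tie)
  expect_identical(consolidate_orfs(cs_tie, groups)$orf_id, "Y")
})

test_that("consolidation is idempotent", {
  groups <- c(T1 = "tumour", T2 = "tumour", N1 = "normal")
  coords <- rbind(orf_row("A", 60, 360), orf_row("B", 60, 210))
  cs <- toy_callsets(list(T1 = c("A", "B"), T2 = c("A", "B"), N1 = "A"),
                     coords)
  cat1 <- consolidate_orfs(cs, groups)
  # re-feed the catalog as a single call set detected everywhere
  cs2 <- list(T1 = cat1[, names(coords)[names(coords) %in% names(cat1)]],
              T2 = cat1[, names(coords)[names(coords) %in% names(cat1)]])
  cat2 <- consolidate_orfs(cs2, groups)
  expect_identical(cat1$orf_id, cat2$orf_id)
})

test_that("ORF categories follow frame and biotype rules", {
  ann <- toy_annotation()
  df <- rbind(orf_row("A", 60, 360),  # identical to the annotated CDS
              orf_row("B", 64, 360),  # 4 nt into the CDS: out of frame
              orf_row("C", 66, 360),  # 6 nt: in frame
              orf_row("D", 0, 90, "TXL"))
  out <- categorize_orfs(df, ann)
  expect_identical(out$category,
                   c("annotated", "out_of_frame", "in_frame", "lncORF"))
  bad <- orf_row("E", 0, 30, "TXMISSING")
  expect_error(categorize_orfs(bad, ann), "missing")
})

test_that("TPM normalizes to a million with the length-rate definition", {
  m1 <- matrix(5, 1, 2, dimnames = list("g", c("s1", "s2")))
  expect_true(all(tpm(m1, 100) == 1e6))
  m2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s"))
  out <- tpm(m2, c(1000, 2000))
  expect_equal(unname(out[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  m3 <- rbind(m2[, 1], c(0))
  out3 <- tpm(matrix(c(10, 0), 2, 1), c(1000, 2000))
  expect_identical(out3[2, 1], 0)
  expect_error(tpm(m2, c(0, 10)), "lengths")
  expect_error(tpm(matrix(0, 2, 1), c(1, 1)), "zero total")
})

test_that("specificity classes follow the percentile-rank dichotomy", {
  # 10 ORFs; focal ORF ranked 5th in tumour, lowest in normal
  ids <- sprintf("O%02d", 1:10)
  cat_df <- data.frame(orf_id = ids, stringsAsFactors = FALSE)
  tum <- c(5, 1:4, 6:10)        # O01 is 5th from bottom in tumour
  nor <- c(0.01, 2:10)          # O01 lowest in normal
  tp <- cbind(T1 = tum, T2 = tum, N1 = nor, N2 = nor)
  rownames(tp) <- ids
  groups <- c(T1 = "tumour", T2 = "tumour", N1 = "normal", N2 = "normal")
  out <- specificity_classify(cat_df, tp, groups, q_low = 0.10)
  expect_identical(out$spec_class[out$orf_id == "O01"], "tumour_specific")
  # an ORF high in both groups is "both"
  expect_identical(out$spec_class[out$orf_id == "O10"], "both")
  # all-tied TPMs: ties take the maximum rank, everything is "both"
  tp_tie <- matrix(3, 10, 4, dimnames = list(ids, names(groups)))
  out_tie <- specificity_classify(cat_df, tp_tie, groups)
  expect_setequal(unique(out_tie$spec_class), "both")
  expect_error(specificity_classify(cat_df[0, , drop = FALSE], tp, groups),
               "empty")
})

test_that("the upregulated-ORF union applies both clauses", {
  cat_df <- data.frame(
    orf_id = c("TS1", "B1", "B2", "B3", "NS1"),
    spec_class = c("tumour_specific", "both", "both", "both",
                   "normal_specific"),
    stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("B1", "B2", "B3"),
                   log2fc = c(0.5, -1, 0.2), p = c(0.04, 0.01, 0.5))
  # TS1 included with no DE record; B1 significant up; B2 wrong sign;
  # B3 not significant
  expect_identical(upregulated_orfs(cat_df, de), c("B1", "TS1"))
  expect_error(upregulated_orfs(cat_df, de[-1, ]), "missing DE record")
})

test_that("C1-C4 clusters encode level-exclusive regulation", {
  rna <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    log2fc = c(1, 0.1, -1, 0.2, 1),
                    p = c(0.01, 0.6, 0.01, 0.6, 0.01))
  ribo <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                     log2fc = c(0, -1, 0, -1, 2),
                     p = c(0.6, 0.01, 0.9, 0.01, 0.01))
  expect_identical(expression_cluster(c("a", "b", "c", "d", "e"), rna, ribo),
                   c("C1", "C4", "C3", "C4", "none"))
  # C2: ribo-up only
  expect_identical(expression_cluster(
    "x",
    data.frame(gene_id = "x", log2fc = 0, p = 1),
    data.frame(gene_id = "x", log2fc = 1, p = 0.001)), "C2")
  expect_error(expression_cluster("zz", rna, ribo), "cover")
})
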