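# End-to-end orchestration: fixture bundle generation, stage execution in
# dependency order, TSV outputs and a consolidated JSON summary.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Write a complete synthetic fixture bundle
#'
#' Generates every input the pipeline consumes -- paired count matrices with
#' design, per-sample ORF call sets with ORF-level counts, GTF annotation,
#' P-site reads, ORF protein FASTA, 5'UTR feature table, per-sample peptide
#' lists, TE matrix with traits -- plus the planted truth tables, into one
#' directory with a JSON manifest.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "callsets"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  cnt <- simulate_counts(config)
  write_counts_tsv(cnt$rna, p("rna_counts.tsv"))
  write_counts_tsv(cnt$ribo, p("ribo_counts.tsv"))
  write_tsv(cnt$design, p("design.tsv"))
  write_tsv(cnt$truth, p("truth_genes.tsv"))

  ann <- simulate_annotation(seed = config$seed)
  write_annotation_gtf(ann, p("annotation.gtf"))

  orfs <- simulate_orf_callsets(config, annotation = ann)
  for (s in names(orfs$callsets))
    write_tsv(orfs$callsets[[s]], p("callsets", paste0(s, ".tsv")))
  write_tsv(orfs$orfs, p("orfs.tsv"))
  write_counts_tsv(orfs$counts_ribo, p("orf_counts_ribo.tsv"))
  write_counts_tsv(orfs$counts_rna, p("orf_counts_rna.tsv"))
  write_tsv(orfs$truth, p("truth_orfs.tsv"))

  reads <- simulate_psite_reads(ann, n_reads = 20000L, noise = 0.1,
                                seed = config$seed)
  write_tsv(reads, p("reads.tsv"))

  # random ORF protein sequences for the peptide stage
  primary <- orfs$truth[is.na(orfs$truth$dup_of) &
                          orfs$truth$spec_class != "neither", ]
  proteins <- with_seed(stream_seed(config$seed, "proteins"), {
    stats::setNames(vapply(seq_len(nrow(primary)), function(i)
      paste(sample(AA_LETTERS, 60L, replace = TRUE), collapse = ""),
      character(1)), primary$orf_id)
  })
  write_protein_fasta(proteins, p("orf_proteins.fasta"))
  grp_map <- c(tumour_specific = "tumour", normal_specific = "normal",
               both = "both")
  orf_groups <- stats::setNames(grp_map[primary$spec_class],
                                primary$orf_id)

  # UTR features: planted enrichment in the translationally upregulated set
  truth <- cnt$truth
  excl_up <- truth$gene_id[truth$class == "exclusive" & truth$lfc_te > 0]
  nulls <- truth$gene_id[truth$class == "not_significant"]
  n_set <- min(50L, length(excl_up), length(nulls))
  target <- utils::head(excl_up, n_set)
  control <- utils::head(nulls, n_set)
  fp <- simulate_features_and_peptides(
    target, control, proteins, orf_groups,
    samples = cnt$design, seed = config$seed)
  write_tsv(fp$features, p("features.tsv"))
  write_tsv(fp$peptides, p("peptides.tsv"))
  write_tsv(fp$truth, p("truth_peptides.tsv"))
  write_tsv(data.frame(gene_id = target), p("target_genes.tsv"))
  write_tsv(data.frame(gene_id = control), p("control_genes.tsv"))

  mod <- simulate_module_data(config)
  write_counts_tsv(mod$te, p("te_matrix.tsv"))
  write_tsv(mod$traits, p("traits.tsv"))
  write_tsv(mod$truth, p("truth_modules.tsv"))

  manifest <- list(
    seed = config$seed,
    n_tumour = config$n_tumour, n_normal = config$n_normal,
    n_genes = config$n_genes,
    files = list(
      design = "design.tsv", rna_counts = "rna_counts.tsv",
      ribo_counts = "ribo_counts.tsv", annotation = "annotation.gtf",
      callsets_dir = "callsets", orfs = "orfs.tsv",
      orf_counts_ribo = "orf_counts_ribo.tsv",
      orf_counts_rna = "orf_counts_rna.tsv",
      reads = "reads.tsv", orf_proteins = "orf_proteins.fasta",
      features = "features.tsv", peptides = "peptides.tsv",
      target_genes = "target_genes.tsv",
      control_genes = "control_genes.tsv",
      te_matrix = "te_matrix.tsv", traits = "traits.tsv",
      truth_genes = "truth_genes.tsv", truth_orfs = "truth_orfs.tsv",
      truth_peptides = "truth_peptides.tsv",
      truth_modules = "truth_modules.tsv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Run the full translatome analysis pipeline on a fixture bundle
#'
#' Executes the enabled stages in dependency order -- QC, ORF catalog,
#' differential expression / TE with the four-class categorization, 5'UTR
#' feature comparison, co-expression modules and hubs, peptide
#' cross-referencing -- writing per-stage TSV outputs and one JSON summary.
#' Re-running on unchanged inputs reproduces every output byte for byte
#' (no stage consumes random numbers).
#'
#' @param bundle_dir Directory written by [write_fixture_bundle()] (or laid
#'   out the same way).
#' @param out_dir Output directory.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("qc", "catalog", "dte", "utr", "modules", "peptides")`.
#' @param min_samples,q_low,alpha_sig Stage parameters (detection
#'   threshold, specificity percentile, significance level).
#' @param params A [network_params()] for the module stage.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(bundle_dir, out_dir,
                         stages = c("qc", "catalog", "dte", "utr",
                                    "modules", "peptides"),
                         min_samples = 2L, q_low = 0.10, alpha_sig = 0.05,
                         params = network_params()) {
  stages <- match.arg(stages, c("qc", "catalog", "dte", "utr", "modules",
                                "peptides"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p_in <- function(...) file.path(bundle_dir, ...)
  p_out <- function(...) file.path(out_dir, ...)
  fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)
  summary <- list(stages = as.list(stages))

  design <- read_tsv(p_in("design.tsv"))
  groups <- stats::setNames(design$condition, design$sample_id)
  annotation <- read_annotation_gtf(p_in("annotation.gtf"))

  if ("qc" %in% stages) {
    qc <- tryCatch({
      reads <- read_tsv(p_in("reads.tsv"))
      ribo_qc(reads, annotation)
    }, error = function(e) fail("qc", e))
    write_tsv(qc$length_histogram, p_out("qc_length_histogram.tsv"))
    write_tsv(data.frame(length = as.integer(names(qc$offsets)),
                         offset = unname(qc$offsets)),
              p_out("qc_offsets.tsv"))
    summary$qc <- list(offsets = as.list(qc$offsets),
                       frame_fractions = as.list(round(
                         qc$frame_fractions, 6)),
                       region_fractions = as.list(round(
                         qc$region_fractions, 6)))
  }

  catalog <- NULL
  if ("catalog" %in% stages) {
    catalog <- tryCatch({
      cs_files <- list.files(p_in("callsets"), full.names = TRUE)
      callsets <- lapply(cs_files, read_tsv)
      names(callsets) <- sub("\\.tsv$", "", basename(cs_files))
      cat_df <- consolidate_orfs(callsets, groups, min_samples)
      cat_df <- categorize_orfs(cat_df, annotation)
      ribo_orf <- read_counts_tsv(p_in("orf_counts_ribo.tsv"))
      ribo_orf <- ribo_orf[rownames(ribo_orf) %in% cat_df$orf_id, ,
                           drop = FALSE]
      tpm_mat <- tpm(ribo_orf,
                     cat_df$length[match(rownames(ribo_orf),
                                         cat_df$orf_id)])
      specificity_classify(cat_df, tpm_mat, groups, q_low)
    }, error = function(e) fail("catalog", e))
    summary$catalog <- list(
      size = nrow(catalog),
      by_category = as.list(table(catalog$category)),
      by_specificity = as.list(table(catalog$spec_class)))
  }

  if ("dte" %in% stages) {
    fit <- tryCatch({
      rna <- read_counts_tsv(p_in("rna_counts.tsv"))
      ribo <- read_counts_tsv(p_in("ribo_counts.tsv"))
      if (!identical(colnames(rna), design$sample_id))
        stop("sample ids of counts and design disagree")
      dte(rna, ribo, design$condition, alpha_sig = alpha_sig)
    }, error = function(e) fail("dte", e))
    write_tsv(fit$results, p_out("dte_results.tsv"))
    s <- summary.dte_fit(fit)
    summary$dte <- list(
      n_genes = s$n_genes,
      deg = as.list(s$deg), dteg = as.list(s$dteg),
      classes = as.list(s$classes))

    if (!is.null(catalog)) {
      ccl <- tryCatch({
        ribo_orf <- read_counts_tsv(p_in("orf_counts_ribo.tsv"))
        rna_orf <- read_counts_tsv(p_in("orf_counts_rna.tsv"))
        keep <- rownames(ribo_orf) %in% catalog$orf_id
        de_r <- test_deg(rna_orf[keep, , drop = FALSE], groups[colnames(rna_orf)])
        de_b <- test_deg(ribo_orf[keep, , drop = FALSE],
                         groups[colnames(ribo_orf)])
        clusters <- expression_cluster(catalog$orf_id, de_r, de_b,
                                       alpha_sig)
        catalog$cluster <- clusters
        up <- upregulated_orfs(catalog, de_b, alpha_sig)
        list(catalog = catalog, upregulated = up)
      }, error = function(e) fail("dte", e))
      catalog <- ccl$catalog
      write_tsv(data.frame(orf_id = ccl$upregulated),
                p_out("upregulated_orfs.tsv"))
      summary$catalog$clusters <- as.list(table(catalog$cluster))
      summary$catalog$n_upregulated <- length(ccl$upregulated)
    }
  }
  if (!is.null(catalog)) write_tsv(catalog, p_out("orf_catalog.tsv"))

  if ("utr" %in% stages) {
    cmp <- tryCatch({
      features <- read_tsv(p_in("features.tsv"))
      target <- read_tsv(p_in("target_genes.tsv"))$gene_id
      control <- read_tsv(p_in("control_genes.tsv"))$gene_id
      compare_utr_features(target, control, features)
    }, error = function(e) fail("utr", e))
    write_tsv(cmp, p_out("utr_comparison.tsv"))
    summary$utr <- lapply(split(cmp, cmp$feature), function(r)
      list(target = round(r$target, 6), control = round(r$control, 6),
           p = signif(r$p, 6)))
  }

  if ("modules" %in% stages) {
    mods <- tryCatch({
      te <- read_counts_tsv(p_in("te_matrix.tsv"))
      traits <- read_tsv(p_in("traits.tsv"))
      keep <- filter_te_genes(te, params)
      res <- detect_modules(te[keep, , drop = FALSE], params)
      st <- module_trait_stats(res, traits)
      hubs <- select_hubs(st, "trait")
      list(res = res, st = st, hubs = hubs)
    }, error = function(e) fail("modules", e))
    write_tsv(data.frame(gene_id = names(mods$res$labels),
                         module = unname(mods$res$labels)),
              p_out("module_assignments.tsv"))
    write_tsv(mods$st$module_trait, p_out("module_trait.tsv"))
    write_tsv(data.frame(gene_id = mods$hubs), p_out("hub_genes.tsv"))
    summary$modules <- list(
      n_modules = ncol(mods$res$eigengenes),
      sizes = as.list(table(mods$res$labels)),
      n_hubs = length(mods$hubs))
  }

  if ("peptides" %in% stages) {
    pep <- tryCatch({
      peptides <- read_tsv(p_in("peptides.tsv"))
      proteins <- read_protein_fasta(p_in("orf_proteins.fasta"))
      categories <- NULL
      if (!is.null(catalog))
        categories <- stats::setNames(catalog$category, catalog$orf_id)
      match_peptides(peptides, proteins, categories)
    }, error = function(e) fail("peptides", e))
    write_tsv(pep, p_out("peptide_records.tsv"))
    write_tsv(peptide_category_summary(pep),
              p_out("peptide_summary.tsv"))
    summary$peptides <- list(
      n_peptides = nrow(pep),
      n_tumour_specific = sum(pep$tumour_specific),
      by_category = as.list(table(pep$category)))
  }

  jsonlite::write_json(summary, p_out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}
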