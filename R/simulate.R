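# Synthetic translatome generator with planted ground truth.
#
# Every downstream stage (QC, catalog, DTE, UTR features, modules, peptide
# cross-referencing) can be exercised on output of this module alone. All
# randomness flows from one global seed through named sub-streams
# (see stream_seed), so adding a stage never perturbs earlier draws.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the
#' `simulate_*` generators. Defaults mirror the study design being emulated:
#' 19 tumour and 15 normal tissues profiled with paired RNA-seq and Ribo-seq.
#'
#' @param n_tumour,n_normal Number of tumour / normal samples.
#' @param n_genes Number of simulated genes.
#' @param class_fractions Named proportions of planted regulatory classes.
#'   Names from `forwarded`, `exclusive`, `intensified`, `buffered`,
#'   `not_significant` (alias `null`); must sum to 1.
#' @param lfc_rna,lfc_te Magnitude (log2) of planted transcriptional and
#'   translational fold-changes.
#' @param dispersion Negative binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); scalar, recycled per gene.
#' @param baseline_mean Scale of baseline NB means; per-gene means are
#'   log-normal around this value.
#' @param baseline_sdlog Log-sd of the per-gene baseline means.
#' @param libsize_range Range of per-sample multiplicative library-size
#'   factors, drawn log-uniformly (default `[0.5, 2]`), independently per
#'   assay, so size-factor estimation is nontrivial.
#' @param shared_dispersion Fraction of `dispersion` realized as a gamma
#'   factor shared between the paired RNA and RIBO libraries of a sample
#'   (biological noise common to both assays). 0 = fully independent assays
#'   (the model the NB GLM assumes); 1 = all overdispersion shared, so
#'   per-gene TE ratios concentrate. Marginal counts are NB(mu, dispersion)
#'   either way.
#' @param orf_dropout Per-sample probability that an expressed ORF fails to
#'   be detected by the caller.
#' @param module_spec List of planted co-expression modules; each element a
#'   list with `size`, `r` (within-module correlation) and `trait`
#'   (logical: associated with the binary trait).
#' @param seed Integer global seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_tumour = 19L, n_normal = 15L, n_genes = 2000L,
                       class_fractions = c(not_significant = 0.78,
                                           forwarded = 0.15,
                                           exclusive = 0.03,
                                           intensified = 0.01,
                                           buffered = 0.03),
                       lfc_rna = 2, lfc_te = 2,
                       dispersion = 0.1,
                       baseline_mean = 100, baseline_sdlog = 1,
                       libsize_range = c(0.5, 2),
                       shared_dispersion = 0,
                       orf_dropout = 0.1,
                       module_spec = list(
                         list(size = 50L, r = 0.9, trait = TRUE),
                         list(size = 60L, r = 0.9, trait = FALSE)),
                       seed = 1L) {
  names(class_fractions)[names(class_fractions) == "null"] <- "not_significant"
  known <- c("forwarded", "exclusive", "intensified", "buffered",
             "not_significant")
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% known))
    stop("class_fractions must be named with regulatory classes: ",
         paste(known, collapse = ", "))
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (n_tumour < 1 || n_normal < 1 || n_genes < 1)
    stop("sample and gene counts must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (orf_dropout < 0 || orf_dropout >= 1)
    stop("orf_dropout must be in [0, 1)")
  if (shared_dispersion < 0 || shared_dispersion > 1)
    stop("shared_dispersion must be in [0, 1]")
  stopifnot(length(libsize_range) == 2L, all(libsize_range > 0),
            libsize_range[1] <= libsize_range[2])
  structure(list(n_tumour = as.integer(n_tumour),
                 n_normal = as.integer(n_normal),
                 n_genes = as.integer(n_genes),
                 class_fractions = class_fractions,
                 lfc_rna = lfc_rna, lfc_te = lfc_te,
                 dispersion = dispersion,
                 baseline_mean = baseline_mean,
                 baseline_sdlog = baseline_sdlog,
                 libsize_range = libsize_range,
                 shared_dispersion = shared_dispersion,
                 orf_dropout = orf_dropout,
                 module_spec = module_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# NB draw parameterized by mean and dispersion (variance mu + alpha mu^2);
# alpha ~ 0 degenerates to Poisson.
rnbinom_mv <- function(n, mu, alpha) {
  if (all(alpha <= 1e-12)) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

plant_classes <- function(config) {
  fr <- config$class_fractions
  n <- config$n_genes
  n_per <- floor(fr * n)
  rem <- n - sum(n_per)
  if (rem > 0) {
    ord <- order(fr * n - n_per, decreasing = TRUE)
    n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
  }
  cls <- rep(names(n_per), n_per)
  cls[sample.int(n)]  # shuffle so class blocks are not contiguous
}

#' Simulate paired RNA-seq / Ribo-seq count matrices
#'
#' Generates gene-by-sample negative binomial counts for the two assays with
#' planted transcriptional (`lfc_rna`) and translational (`lfc_te`)
#' log2 fold-changes per regulatory class: `forwarded` genes change at the
#' RNA level only, `exclusive` genes at the TE level only, `intensified`
#' genes in the same direction at both levels, and `buffered` genes with
#' opposing RNA and TE changes.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_counts"`: `rna` and `ribo` (integer
#'   matrices, genes x samples, identical dimnames), `design` (data frame
#'   with `sample_id`, `condition`), `truth` (data frame with `gene_id`,
#'   `class`, `lfc_rna`, `lfc_te`) and the `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stream_seed(config$seed, "counts"), {
    n_g <- config$n_genes
    n_t <- config$n_tumour
    n_n <- config$n_normal
    n_s <- n_t + n_n
    samples <- c(sprintf("T%02d", seq_len(n_t)), sprintf("N%02d", seq_len(n_n)))
    genes <- sprintf("G%05d", seq_len(n_g))
    tumour <- rep(c(1, 0), c(n_t, n_n))

    cls <- plant_classes(config)
    s_rna <- sample(c(-1, 1), n_g, replace = TRUE)
    s_te <- sample(c(-1, 1), n_g, replace = TRUE)
    lfc_rna <- ifelse(cls %in% c("forwarded", "intensified", "buffered"),
                      s_rna * config$lfc_rna, 0)
    lfc_te <- numeric(n_g)
    lfc_te[cls == "exclusive"] <- s_te[cls == "exclusive"] * config$lfc_te
    lfc_te[cls == "intensified"] <-
      s_rna[cls == "intensified"] * config$lfc_te
    lfc_te[cls == "buffered"] <- -s_rna[cls == "buffered"] * config$lfc_te

    mu <- stats::rlnorm(n_g, log(config$baseline_mean), config$baseline_sdlog)
    lr <- log(config$libsize_range)
    lib_rna <- exp(stats::runif(n_s, lr[1], lr[2]))
    lib_ribo <- exp(stats::runif(n_s, lr[1], lr[2]))

    alpha <- config$dispersion
    a_sh <- alpha * config$shared_dispersion
    a_res <- alpha * (1 - config$shared_dispersion)
    gam <- if (a_sh > 1e-12) {
      matrix(stats::rgamma(n_g * n_s, shape = 1 / a_sh, scale = a_sh),
             n_g, n_s)
    } else {
      matrix(1, n_g, n_s)
    }

    fc_rna <- outer(2^lfc_rna, tumour, function(f, t) f^t)
    fc_te <- outer(2^lfc_te, tumour, function(f, t) f^t)
    mu_rna <- mu * gam * fc_rna * rep(lib_rna, each = n_g)
    mu_ribo <- mu * gam * fc_rna * fc_te * rep(lib_ribo, each = n_g)

    rna <- matrix(rnbinom_mv(n_g * n_s, as.vector(mu_rna), a_res), n_g, n_s,
                  dimnames = list(genes, samples))
    ribo <- matrix(rnbinom_mv(n_g * n_s, as.vector(mu_ribo), a_res), n_g, n_s,
                   dimnames = list(genes, samples))

    structure(list(
      rna = rna, ribo = ribo,
      design = data.frame(sample_id = samples,
                          condition = rep(c("tumour", "normal"), c(n_t, n_n)),
                          stringsAsFactors = FALSE),
      truth = data.frame(gene_id = genes, class = cls,
                         lfc_rna = lfc_rna, lfc_te = lfc_te,
                         stringsAsFactors = FALSE),
      config = config), class = "sim_counts")
  })
}

#' Simulate a transcript annotation
#'
#' Builds a transcript-space annotation: protein-coding transcripts with
#' 5'UTR / CDS / 3'UTR partitions (CDS length a multiple of 3) and lncRNA
#' transcripts without a CDS. Coordinates are 0-based half-open in
#' transcript space.
#'
#' @param n_coding,n_lnc Numbers of protein-coding and lncRNA transcripts.
#' @param seed Integer seed.
#' @return A data frame with columns `transcript_id`, `gene_id`,
#'   `gene_biotype`, `tx_len`, `cds_start`, `cds_end` (NA for lncRNA).
#' @export
simulate_annotation <- function(n_coding = 200L, n_lnc = 40L, seed = 1L) {
  with_seed(stream_seed(seed, "annotation"), {
    n <- n_coding + n_lnc
    tx <- sprintf("TX%04d", seq_len(n))
    gene <- sprintf("GN%04d", seq_len(n))
    biotype <- rep(c("protein_coding", "lncRNA"), c(n_coding, n_lnc))
    utr5 <- sample(50:90, n, replace = TRUE)
    cds_len <- 3L * sample(100:400, n, replace = TRUE)
    utr3 <- sample(50:150, n, replace = TRUE)
    ann <- data.frame(transcript_id = tx, gene_id = gene,
                      gene_biotype = biotype,
                      tx_len = utr5 + cds_len + utr3,
                      cds_start = utr5, cds_end = utr5 + cds_len,
                      stringsAsFactors = FALSE)
    ann$cds_start[biotype == "lncRNA"] <- NA_integer_
    ann$cds_end[biotype == "lncRNA"] <- NA_integer_
    ann$tx_len[biotype == "lncRNA"] <-
      sample(300:1200, sum(biotype == "lncRNA"), replace = TRUE)
    ann
  })
}

#' Simulate per-sample ORF call sets with planted specificity
#'
#' Plants ORFs of the four catalog categories (annotated, in-frame,
#' out-of-frame, lncORF) on an annotation, assigns each a true specificity
#' class (expressed in tumour only, normal only, both groups, or in neither),
#' and emits per-sample call sets where an expressed ORF is detected with
#' probability `1 - orf_dropout`. Duplicate-coordinate decoy pairs (a
#' shorter ORF sharing the start of a longer one) are planted to exercise
#' longest-ORF deduplication. ORF-level RNA and RIBO count matrices are
#' generated so specificity classification and ORF-level DE are testable.
#'
#' @param config A [sim_config()].
#' @param annotation Annotation from [simulate_annotation()]; generated from
#'   `config$seed` when `NULL`.
#' @param n_orfs Number of primary planted ORFs.
#' @param spec_fractions Named fractions over true specificity classes
#'   `both`, `tumour_specific`, `normal_specific`, `neither`, realized as
#'   exact counts. For the rank-based specificity classifier (bottom-decile
#'   dichotomy) to recover the planted classes, the group-specific fractions
#'   should each stay below `q_low` of the retained catalog.
#' @param n_dup_pairs Number of planted shared-start decoy pairs.
#' @param expressed_mean,silent_mean RIBO count means for ORFs in groups
#'   where they are / are not expressed (30-fold separation by default).
#' @return A list: `callsets` (named list of per-sample data frames),
#'   `orfs` (master ORF table), `counts_ribo`, `counts_rna`, `design`,
#'   `truth`, `annotation`.
#' @export
simulate_orf_callsets <- function(config, annotation = NULL, n_orfs = 200L,
                                  spec_fractions = c(both = 0.72,
                                                     tumour_specific = 0.08,
                                                     normal_specific = 0.06,
                                                     neither = 0.14),
                                  n_dup_pairs = 5L,
                                  expressed_mean = 150, silent_mean = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (abs(sum(spec_fractions) - 1) > 1e-9)
    stop("spec_fractions must sum to 1")
  if (is.null(annotation))
    annotation <- simulate_annotation(seed = config$seed)
  with_seed(stream_seed(config$seed, "orfs"), {
    coding <- annotation[annotation$gene_biotype == "protein_coding", ]
    lnc <- annotation[annotation$gene_biotype == "lncRNA", ]
    n_t <- config$n_tumour; n_n <- config$n_normal
    samples <- c(sprintf("T%02d", seq_len(n_t)), sprintf("N%02d", seq_len(n_n)))
    group <- rep(c("tumour", "normal"), c(n_t, n_n))

    cats <- sample(c("annotated", "in_frame", "out_of_frame", "lncORF"),
                   n_orfs, replace = TRUE,
                   prob = c(0.55, 0.25, 0.08, 0.12))
    n_need_lnc <- sum(cats == "lncORF")
    n_need_cod <- n_orfs - n_need_lnc
    if (n_need_cod > nrow(coding) || n_need_lnc > nrow(lnc))
      stop("annotation has too few transcripts for ", n_orfs,
           " one-per-transcript ORFs")
    # one primary ORF per transcript: coordinate sharing is then planted
    # (the decoy pairs below), never accidental
    cod_tx <- coding[sample.int(nrow(coding), n_need_cod), ]
    lnc_tx <- lnc[sample.int(nrow(lnc), n_need_lnc), ]
    i_cod <- 0L; i_lnc <- 0L
    recs <- vector("list", n_orfs)
    for (i in seq_len(n_orfs)) {
      cat_i <- cats[i]
      if (cat_i == "lncORF") {
        i_lnc <- i_lnc + 1L
        tx <- lnc_tx[i_lnc, ]
        len <- 3L * sample(30:120, 1L)
        start <- sample.int(max(tx$tx_len - len, 1L), 1L) - 1L
        end <- start + len
      } else {
        i_cod <- i_cod + 1L
        tx <- cod_tx[i_cod, ]
        cds_len <- tx$cds_end - tx$cds_start
        if (cat_i == "annotated") {
          start <- tx$cds_start; end <- tx$cds_end
        } else if (cat_i == "in_frame") {
          off <- 3L * sample.int(cds_len %/% 6L, 1L)
          start <- tx$cds_start + off
          end <- tx$cds_end
        } else {
          off <- 3L * sample.int(max(cds_len %/% 6L, 1L), 1L) +
            sample(1:2, 1L)
          start <- tx$cds_start + off
          end <- start + 3L * sample(30:90, 1L)
          end <- min(end, tx$tx_len)
        }
      }
      recs[[i]] <- data.frame(orf_id = sprintf("ORF%04d", i),
                              transcript_id = tx$transcript_id,
                              gene_id = tx$gene_id, strand = "+",
                              start = start, end = end,
                              category_true = cat_i,
                              stringsAsFactors = FALSE)
    }
    orfs <- do.call(rbind, recs)

    # shared-start decoys: shorter twins of existing ORFs, never expressed
    # independently -- they ride along in the same samples as the primary
    if (n_dup_pairs > 0L) {
      long_enough <- which(orfs$end - orfs$start >= 180L)
      hosts <- sample(long_enough, min(n_dup_pairs, length(long_enough)))
      dup <- orfs[hosts, ]
      dup$orf_id <- sprintf("ORFD%03d", seq_along(hosts))
      dup$end <- dup$start + 3L * ((dup$end - dup$start) %/% 6L)
      dup$category_true <- "dup_shadow"
      dup$dup_of <- orfs$orf_id[hosts]
      orfs$dup_of <- NA_character_
      orfs <- rbind(orfs, dup)
    } else {
      orfs$dup_of <- NA_character_
    }
    orfs$length <- orfs$end - orfs$start

    n_all <- nrow(orfs)
    primary <- is.na(orfs$dup_of)
    # exact per-class counts (not multinomial draws) so the planted
    # tumour/normal-specific mass stays inside the percentile dichotomy the
    # rank-based classifier uses
    spec <- character(n_all)
    n_p <- sum(primary)
    n_per <- floor(spec_fractions * n_p)
    rem <- n_p - sum(n_per)
    if (rem > 0) {
      ord <- order(spec_fractions * n_p - n_per, decreasing = TRUE)
      n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
    }
    spec[primary] <- sample(rep(names(n_per), n_per))
    spec[!primary] <- spec[match(orfs$dup_of[!primary], orfs$orf_id)]
    expr_t <- spec %in% c("both", "tumour_specific")
    expr_n <- spec %in% c("both", "normal_specific")

    detected <- matrix(FALSE, n_all, length(samples),
                       dimnames = list(orfs$orf_id, samples))
    for (j in seq_along(samples)) {
      expressed <- if (group[j] == "tumour") expr_t else expr_n
      detected[, j] <- expressed &
        stats::runif(n_all) >= config$orf_dropout
    }
    # decoys are emitted exactly where their primary is detected
    detected[!primary, ] <- detected[match(orfs$dup_of[!primary],
                                           orfs$orf_id), , drop = FALSE]

    callers <- c("orfquant", "ribotricer")
    callsets <- lapply(seq_along(samples), function(j) {
      idx <- which(detected[, j])
      if (!length(idx)) {
        return(orfs[0, c("orf_id", "transcript_id", "gene_id", "strand",
                         "start", "end", "length")])
      }
      cs <- orfs[idx, c("orf_id", "transcript_id", "gene_id", "strand",
                        "start", "end", "length")]
      cs$caller <- sample(callers, length(idx), replace = TRUE)
      rownames(cs) <- NULL
      cs
    })
    names(callsets) <- samples

    mu_ribo <- ifelse(outer(expr_t, group == "tumour") |
                        outer(expr_n, group == "normal"),
                      expressed_mean, silent_mean)
    counts_ribo <- matrix(rnbinom_mv(length(mu_ribo), as.vector(mu_ribo),
                                     config$dispersion),
                          n_all, length(samples),
                          dimnames = list(orfs$orf_id, samples))
    counts_rna <- matrix(rnbinom_mv(length(mu_ribo), as.vector(mu_ribo),
                                    config$dispersion),
                         n_all, length(samples),
                         dimnames = list(orfs$orf_id, samples))

    list(callsets = callsets,
         orfs = orfs,
         counts_ribo = counts_ribo,
         counts_rna = counts_rna,
         design = data.frame(sample_id = samples, condition = group,
                             stringsAsFactors = FALSE),
         truth = data.frame(orf_id = orfs$orf_id,
                            category = orfs$category_true,
                            spec_class = spec,
                            expressed_tumour = expr_t,
                            expressed_normal = expr_n,
                            dup_of = orfs$dup_of,
                            stringsAsFactors = FALSE),
         annotation = annotation)
  })
}

#' Simulate ribosome footprint reads with known P-site geometry
#'
#' Emits synthetic reads on coding transcripts whose 5' ends sit a fixed
#' offset upstream of in-frame codon positions, plus a configurable
#' out-of-frame noise fraction distributed uniformly over the three frames.
#' With noise fraction `nu` the expected frame-0 fraction is
#' `(1 - nu) + nu/3`.
#'
#' @param annotation Annotation data frame (needs >= 1 coding transcript).
#' @param n_reads Number of reads.
#' @param read_length Read length in nt, or `NULL` to draw from
#'   `length_range`.
#' @param length_range Inclusive range of read lengths when `read_length`
#'   is `NULL` (default 25-50, the retained footprint window).
#' @param offset P-site offset: distance from the 5' end to the P-site.
#' @param noise Fraction of reads whose P-site frame is uniform over frames.
#' @param start_bias Fraction of reads placed on the initiating codon,
#'   emulating the elevated start-codon occupancy of ribosome footprint
#'   metagenes; this peak is what offset calibration locks onto.
#' @param seed Integer seed.
#' @return Data frame with `transcript_id`, `pos5` (0-based transcript
#'   coordinate of the 5' end) and `length`.
#' @export
simulate_psite_reads <- function(annotation, n_reads = 10000L,
                                 read_length = 30L, length_range = c(25L, 50L),
                                 offset = 12L, noise = 0, start_bias = 0.15,
                                 seed = 1L) {
  coding <- annotation[!is.na(annotation$cds_start), ]
  if (!nrow(coding)) stop("annotation contains no CDS")
  coding <- coding[coding$cds_start >= offset, ]
  if (!nrow(coding))
    stop("no transcript has a 5'UTR long enough for the requested offset")
  min_len <- if (is.null(read_length)) length_range[1] else read_length
  if (offset >= min_len) stop("offset must be smaller than the read length")
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  with_seed(stream_seed(seed, "psites"), {
    lens <- if (is.null(read_length)) {
      sample(length_range[1]:length_range[2], n_reads, replace = TRUE)
    } else {
      rep(as.integer(read_length), n_reads)
    }
    ti <- sample.int(nrow(coding), n_reads, replace = TRUE)
    cds_start <- coding$cds_start[ti]
    n_codon <- (coding$cds_end[ti] - cds_start) %/% 3L
    # keep P-sites >= offset into the transcript and away from the CDS end
    codon <- floor(stats::runif(n_reads) * pmax(n_codon - 2L, 1L))
    codon[stats::runif(n_reads) < start_bias] <- 0L
    psite <- cds_start + 3L * codon
    noisy <- stats::runif(n_reads) < noise
    psite[noisy] <- psite[noisy] + sample(0:2, sum(noisy), replace = TRUE)
    data.frame(transcript_id = coding$transcript_id[ti],
               pos5 = psite - offset,
               length = lens,
               stringsAsFactors = FALSE)
  })
}

#' Simulate 5'UTR feature tables and immunopeptide lists
#'
#' Plants binary 5'UTR features (uORF, TOP, m6A presence) at configured
#' prevalences in a target versus a control gene set, continuous features
#' (AU content, IRES probability, cumulative m6A score) with a configured
#' shift, and per-sample peptide lists in which every emitted peptide is an
#' exact substring (7-16 aa) of its source ORF translation, with
#' group-restricted presence for tumour-only peptides.
#'
#' @param target_genes,control_genes Disjoint character vectors of gene ids.
#' @param orf_proteins Named character vector of ORF amino-acid sequences
#'   used as peptide sources; names are ORF ids.
#' @param orf_groups Named character vector mapping ORF ids to `"tumour"`,
#'   `"normal"` or `"both"` (which groups express the ORF).
#' @param prevalence Named list of length-2 numeric vectors
#'   `c(target, control)` for the binary features `uorf`, `top`, `m6a`.
#' @param n_peptides_per_orf Peptides drawn from each source ORF.
#' @param peptide_length_range Candidate peptide lengths; lengths outside
#'   7-16 aa are recorded in the truth table but never emitted.
#' @param samples Data frame with `sample_id` and `group` columns.
#' @param seed Integer seed.
#' @return List with `features` (one row per gene), `peptides`
#'   (`sample_id`, `group`, `peptide`) and `truth` (per planted peptide:
#'   source ORF, group presence, emitted flag).
#' @export
simulate_features_and_peptides <- function(target_genes, control_genes,
                                           orf_proteins, orf_groups,
                                           prevalence = list(
                                             uorf = c(0.5, 0.3),
                                             top = c(0.3, 0.1),
                                             m6a = c(0.8, 0.2)),
                                           n_peptides_per_orf = 2L,
                                           peptide_length_range = c(8L, 11L),
                                           samples = data.frame(
                                             sample_id = c("T01", "T02", "T03",
                                                           "N01", "N02"),
                                             group = c("tumour", "tumour",
                                                       "tumour", "normal",
                                                       "normal")),
                                           seed = 1L) {
  if (!length(target_genes) || !length(control_genes))
    stop("gene sets must be non-empty")
  if (length(intersect(target_genes, control_genes)))
    stop("target and control gene sets must be disjoint")
  if ("condition" %in% names(samples) && !"group" %in% names(samples))
    names(samples)[names(samples) == "condition"] <- "group"
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("samples must have sample_id and group columns")
  with_seed(stream_seed(seed, "features"), {
    genes <- c(target_genes, control_genes)
    is_t <- c(rep(TRUE, length(target_genes)),
              rep(FALSE, length(control_genes)))
    pick <- function(p) ifelse(is_t, p[1], p[2])
    has_uorf <- stats::runif(length(genes)) < pick(prevalence$uorf)
    has_top <- stats::runif(length(genes)) < pick(prevalence$top)
    has_m6a <- stats::runif(length(genes)) < pick(prevalence$m6a)
    n_m6a <- ifelse(has_m6a, 1L + stats::rpois(length(genes), 1.5), 0L)
    cumulative_m6a <- vapply(n_m6a, function(k) {
      if (k == 0L) 0 else sum(stats::runif(k, 0.2, 1))
    }, numeric(1))
    au_content <- stats::rbeta(length(genes),
                               ifelse(is_t, 12, 8), ifelse(is_t, 8, 12))
    ires_prob <- stats::rbeta(length(genes),
                              ifelse(is_t, 4, 2), ifelse(is_t, 4, 6))
    features <- data.frame(gene_id = genes,
                           has_uorf = has_uorf, has_top = has_top,
                           au_content = au_content, ires_prob = ires_prob,
                           n_m6a_sites = n_m6a,
                           cumulative_m6a = cumulative_m6a,
                           stringsAsFactors = FALSE)

    # peptides: exact substrings of source ORF translations
    truth <- list(); pep_rows <- list()
    tum_samples <- samples$sample_id[samples$group == "tumour"]
    nor_samples <- samples$sample_id[samples$group == "normal"]
    for (orf in names(orf_proteins)) {
      prot <- orf_proteins[[orf]]
      grp <- orf_groups[[orf]]
      for (k in seq_len(n_peptides_per_orf)) {
        len <- sample(peptide_length_range[1]:peptide_length_range[2], 1L)
        if (nchar(prot) < len) next
        st <- sample.int(nchar(prot) - len + 1L, 1L)
        pep <- substr(prot, st, st + len - 1L)
        emitted <- len >= 7L && len <= 16L
        in_t <- grp %in% c("tumour", "both")
        in_n <- grp %in% c("normal", "both")
        truth[[length(truth) + 1L]] <- data.frame(
          peptide = pep, source_orf = orf, group = grp,
          emitted = emitted, stringsAsFactors = FALSE)
        if (!emitted) next
        smp <- c(if (in_t) sample(tum_samples,
                                  max(1L, length(tum_samples) %/% 2L)),
                 if (in_n) sample(nor_samples,
                                  max(1L, length(nor_samples) %/% 2L)))
        pep_rows[[length(pep_rows) + 1L]] <- data.frame(
          sample_id = smp,
          group = samples$group[match(smp, samples$sample_id)],
          peptide = pep, stringsAsFactors = FALSE)
      }
    }
    peptides <- if (length(pep_rows)) do.call(rbind, pep_rows) else
      data.frame(sample_id = character(), group = character(),
                 peptide = character(), stringsAsFactors = FALSE)
    list(features = features, peptides = peptides,
         truth = if (length(truth)) do.call(rbind, truth) else NULL)
  })
}

#' Simulate a TE matrix with planted co-expression modules
#'
#' Genes within a planted module load on a shared latent factor so their
#' pairwise correlation is near the configured `r`; trait-associated modules
#' have a latent factor correlated (`trait_r`) with a balanced binary trait.
#' Background genes are independent noise. Values are shifted to be positive
#' so the matrix can double as a translation-efficiency matrix.
#'
#' @param config A [sim_config()]; `module_spec` defines the modules and
#'   `n_tumour` the number of samples.
#' @param n_background Number of unstructured background genes.
#' @param trait_r Latent-trait correlation for associated modules.
#' @return List with `te` (genes x samples), `traits` (`sample_id`,
#'   `trait`), `truth` (gene to planted module label).
#' @export
simulate_module_data <- function(config, n_background = 200L, trait_r = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$module_spec
  if (!length(spec)) stop("module_spec must be non-empty")
  n_s <- config$n_tumour
  sizes <- vapply(spec, function(m) as.integer(m$size), integer(1))
  if (any(sizes < 1L)) stop("module sizes must be >= 1")
  with_seed(stream_seed(config$seed, "modules"), {
    trait <- rep(c(0, 1), length.out = n_s)[sample.int(n_s)]
    t_std <- as.numeric(scale(trait))
    blocks <- list(); labels <- character(0)
    for (m in seq_along(spec)) {
      sz <- sizes[m]; r <- spec[[m]]$r
      f <- if (isTRUE(spec[[m]]$trait)) {
        trait_r * t_std + sqrt(1 - trait_r^2) * stats::rnorm(n_s)
      } else {
        stats::rnorm(n_s)
      }
      # unit sample variance so a module's genes do not share a low-variance
      # fate under the downstream top-variance filter
      f <- as.numeric(scale(f))
      b <- sqrt(r)
      x <- matrix(stats::rnorm(sz * n_s), sz, n_s)
      x <- b * matrix(f, sz, n_s, byrow = TRUE) + sqrt(1 - b^2) * x
      blocks[[m]] <- x
      labels <- c(labels, rep(sprintf("M%02d", m), sz))
    }
    bg <- matrix(stats::rnorm(n_background * n_s), n_background, n_s)
    te <- rbind(do.call(rbind, blocks), bg)
    labels <- c(labels, rep("background", n_background))
    te <- 0.5 * te + 2  # positive scale, mean TE ~ 2
    dimnames(te) <- list(sprintf("MG%05d", seq_len(nrow(te))),
                         sprintf("T%02d", seq_len(n_s)))
    list(te = te,
         traits = data.frame(sample_id = colnames(te), trait = trait,
                             stringsAsFactors = FALSE),
         truth = data.frame(gene_id = rownames(te), module = labels,
                            trait_associated = labels %in%
                              sprintf("M%02d", which(vapply(spec, function(m)
                                isTRUE(m$trait), logical(1)))),
                            stringsAsFactors = FALSE))
  })
}
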