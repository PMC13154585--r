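# Immunopeptide-to-ORF cross-referencing.
#
# MS identification is upstream; here a peptide matches an ORF iff it is an
# exact contiguous substring of the ORF's translation. The 7-16 aa length
# window is applied before matching. When a peptide matches ORFs of several
# categories, its source category follows the precedence
# canonical > in_frame > out_of_frame > lncORF.

CATEGORY_PRECEDENCE <- c("canonical", "in_frame", "out_of_frame", "lncORF")

#' Translate ORF nucleotide sequences
#'
#' Standard genetic code, trimmed at the first stop codon; ORFs with an
#' internal stop (a stop before the final codon) are rejected with a
#' warning and omitted.
#'
#' @param dna Named character vector or `Biostrings::DNAStringSet` of ORF
#'   nucleotide sequences (lengths multiples of 3).
#' @return Named character vector of amino-acid sequences.
#' @export
translate_orfs <- function(dna) {
  if (!inherits(dna, "DNAStringSet"))
    dna <- Biostrings::DNAStringSet(dna)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(dna, if.fuzzy.codon = "solve")))
  has_stop <- regexpr("*", aa, fixed = TRUE)
  internal <- has_stop > 0 & has_stop < nchar(aa)
  if (any(internal)) {
    warning("dropping ", sum(internal), " ORF(s) with internal stop codons")
    aa <- aa[!internal]
  }
  sub("\\*$", "", aa)
}

#' Match peptides to ORF translations
#'
#' @param peptides Data frame with `sample_id`, `group` (`"tumour"` or
#'   `"normal"`), `peptide` and optionally `immunogenic` (passed through).
#' @param proteins Named character vector (or `AAStringSet`) of ORF
#'   amino-acid sequences.
#' @param categories Named character vector mapping ORF ids to categories
#'   (`canonical`/`annotated`, `in_frame`, `out_of_frame`, `lncORF`);
#'   `"annotated"` is treated as `"canonical"`. `NULL` leaves categories
#'   unresolved.
#' @param min_len,max_len Peptide length window (default 7-16 aa), applied
#'   before matching.
#' @param il_equivalent Collapse isoleucine and leucine before matching
#'   (mass spectrometry cannot distinguish them); off by default.
#' @return Data frame of class `"peptide_records"`: one row per unique
#'   peptide with `peptide`, `n_tumour`, `n_normal`, `matched_orfs`
#'   (comma-separated), `n_matches`, `category`, `tumour_specific`.
#' @export
match_peptides <- function(peptides, proteins, categories = NULL,
                           min_len = 7L, max_len = 16L,
                           il_equivalent = FALSE) {
  need <- c("sample_id", "group", "peptide")
  if (!all(need %in% names(peptides)))
    stop("peptides must have columns: ", paste(need, collapse = ", "))
  proteins <- stats::setNames(toupper(as.character(proteins)),
                              names(proteins))
  peps <- toupper(peptides$peptide)
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps)))
    stop("peptides contain non-amino-acid characters")
  len_ok <- nchar(peps) >= min_len & nchar(peps) <= max_len
  peptides <- peptides[len_ok, , drop = FALSE]
  peps <- peps[len_ok]
  if (!nrow(peptides))
    return(structure(data.frame(peptide = character()),
                     class = c("peptide_records", "data.frame")))

  subj <- if (il_equivalent) gsub("I", "L", proteins) else proteins
  uniq <- sort(unique(peps))
  quer <- if (il_equivalent) gsub("I", "L", uniq) else uniq
  hits <- lapply(quer, function(p)
    names(subj)[grepl(p, subj, fixed = TRUE)])

  if (!is.null(categories)) {
    categories[categories == "annotated"] <- "canonical"
    cat_of <- function(orfs) {
      if (!length(orfs)) return("unmatched")
      got <- unique(categories[orfs])
      got <- got[!is.na(got)]
      hit <- CATEGORY_PRECEDENCE[CATEGORY_PRECEDENCE %in% got]
      if (length(hit)) hit[1] else "unmatched"
    }
  } else {
    cat_of <- function(orfs) if (length(orfs)) "matched" else "unmatched"
  }

  n_t <- vapply(uniq, function(p) {
    i <- peps == p
    length(unique(peptides$sample_id[i & peptides$group == "tumour"]))
  }, integer(1))
  n_n <- vapply(uniq, function(p) {
    i <- peps == p
    length(unique(peptides$sample_id[i & peptides$group == "normal"]))
  }, integer(1))

  out <- data.frame(
    peptide = uniq,
    n_tumour = n_t, n_normal = n_n,
    matched_orfs = vapply(hits, function(h)
      paste(sort(h), collapse = ","), character(1)),
    n_matches = lengths(hits),
    category = vapply(hits, cat_of, character(1)),
    tumour_specific = n_t >= 1L & n_n == 0L,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("peptide_records", "data.frame")
  out
}

#' Tumour-specific peptides
#'
#' Peptides present in at least one tumour sample and absent from all
#' normal samples.
#'
#' @param records A [match_peptides()] result.
#' @return Character vector of peptide sequences.
#' @export
tumour_specific_peptides <- function(records) {
  sort(records$peptide[records$tumour_specific])
}

#' Peptide counts by source category
#'
#' Summary table of peptide counts per source category, overall and for
#' tumour-specific peptides.
#'
#' @param records A [match_peptides()] result.
#' @return Data frame `category`, `n_peptides`, `n_tumour_specific`.
#' @export
peptide_category_summary <- function(records) {
  levs <- c(CATEGORY_PRECEDENCE, "unmatched")
  cat_f <- factor(records$category, levels = levs)
  data.frame(category = levs,
             n_peptides = as.integer(table(cat_f)),
             n_tumour_specific = as.integer(
               table(cat_f[records$tumour_specific])),
             stringsAsFactors = FALSE)
}
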