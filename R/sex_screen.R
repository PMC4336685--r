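#' Filter a genotype matrix to loci polymorphic between the parents
#'
#' In an F1 full-sib design only loci at which the two parents differ are
#' informative: a (locus, position) row is kept iff both parents are called
#' (non-missing) and their genotypes differ. Everything else is dropped,
#' with counts by reason.
#'
#' @param geno a [call_genotypes()] result (or its `calls` tibble).
#' @param mother_id,father_id parent column names.
#' @return list: `calls` (kept rows), `log` (tibble reason/n with reasons
#'   `kept`, `monomorphic`, `parent_missing`).
#' @export
filter_parent_polymorphic <- function(geno, mother_id, father_id) {
  calls <- if (inherits(geno, "genotype_matrix")) geno$calls else geno
  if (!all(c(mother_id, father_id) %in% names(calls))) {
    stop("unknown parent id: ", mother_id, " / ", father_id)
  }
  m <- calls[[mother_id]]; f <- calls[[father_id]]
  parent_missing <- is_missing_call(m) | is_missing_call(f)
  mono <- !parent_missing & m == f
  keep <- !parent_missing & !mono
  list(
    calls = calls[keep, , drop = FALSE],
    log = tibble::tibble(
      reason = c("kept", "monomorphic", "parent_missing"),
      n = c(sum(keep), sum(mono), sum(parent_missing)))
  )
}

split_gt <- function(g) c(substr(g, 1, 1), substr(g, 3, 3))

#' Screen for SNPs co-segregating perfectly with sex
#'
#' A (locus, position) row is a sex-marker candidate iff, over all
#' non-missing individuals (allowing at most `max_missing` missing calls),
#' every female carries one identical heterozygous genotype and every male
#' one identical homozygous genotype whose base is one of the het pair —
#' or the mirror image (every male het, every female hom). The first
#' pattern marks the female as the heterogametic sex (ZW-type signal), the
#' mirror the male (XY-type). Parents are part of the check: for a
#' female-heterogametic candidate the mother must be het and the father
#' hom, the informative-cross configuration.
#'
#' @param calls genotype tibble (e.g. [filter_parent_polymorphic()]`$calls`).
#' @param sexes named character vector mapping every genotype column to
#'   `"female"` or `"male"`.
#' @param max_missing maximum missing calls tolerated per row (default 0:
#'   a perfect-information screen).
#' @param catalog optional [build_catalog()] result; when given, candidates
#'   carry the 82-nt tag with the SNP bracketed as its IUPAC code, plus its
#'   reverse complement (assay primers are often read off the opposite
#'   strand).
#' @param marker_prefix prefix for auto-generated marker names
#'   `SNP-<prefix>-<locus>` (default `"SIM"`).
#' @return tibble of candidates: `marker_name`, `locus_id`, `position`,
#'   `female_genotype`, `male_genotype`, `heterogametic_sex`, `iupac`,
#'   `flanking_sequence`, `flanking_revcomp` (NA when no catalog given).
#' @export
screen_sex_association <- function(calls, sexes, max_missing = 0L,
                                   catalog = NULL, marker_prefix = "SIM") {
  ids <- intersect(names(calls), names(sexes))
  if (length(ids) == 0L) stop("no genotype columns match `sexes` names")
  if (!all(sexes[ids] %in% c("female", "male"))) {
    stop("sexes must be 'female' or 'male'")
  }
  females <- ids[sexes[ids] == "female"]
  males <- ids[sexes[ids] == "male"]

  out <- list()
  for (i in seq_len(nrow(calls))) {
    g <- unlist(calls[i, ids])
    if (sum(is_missing_call(g)) > max_missing) next
    gf <- g[females][!is_missing_call(g[females])]
    gm <- g[males][!is_missing_call(g[males])]
    if (length(gf) == 0L || length(gm) == 0L) next
    if (length(unique(gf)) != 1L || length(unique(gm)) != 1L) next
    f1 <- gf[[1]]; m1 <- gm[[1]]
    f_het <- is_het_call(f1); m_het <- is_het_call(m1)

    het_sex <- NULL
    if (f_het && !m_het && split_gt(m1)[1] %in% split_gt(f1)) {
      het_sex <- "female"; het_gt <- f1
    } else if (m_het && !f_het && split_gt(f1)[1] %in% split_gt(m1)) {
      het_sex <- "male"; het_gt <- m1
    }
    if (is.null(het_sex)) next

    pair <- split_gt(het_gt)
    code <- iupac_code(pair[1], pair[2])
    flank <- NA_character_; flank_rc <- NA_character_
    if (!is.null(catalog)) {
      ref <- catalog$loci$reference_consensus[
        catalog$loci$locus_id == calls$locus_id[i]]
      if (length(ref) == 1L) {
        p <- calls$position[i]
        flank <- paste0(substr(ref, 1, p - 1), "(", code, ")",
                        substr(ref, p + 1, nchar(ref)))
        flat <- unbracket_sequence(flank)
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(flat)))
        rp <- nchar(flat) - p + 1L
        flank_rc <- paste0(substr(rc, 1, rp - 1), "(",
                           substr(rc, rp, rp), ")",
                           substr(rc, rp + 1, nchar(rc)))
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      marker_name = sprintf("SNP-%s-%s", marker_prefix, calls$locus_id[i]),
      locus_id = calls$locus_id[i],
      position = calls$position[i],
      female_genotype = f1, male_genotype = m1,
      heterogametic_sex = het_sex, iupac = code,
      flanking_sequence = flank, flanking_revcomp = flank_rc)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(marker_name = character(0), locus_id = character(0),
                          position = integer(0), female_genotype = character(0),
                          male_genotype = character(0),
                          heterogametic_sex = character(0), iupac = character(0),
                          flanking_sequence = character(0),
                          flanking_revcomp = character(0)))
  }
  do.call(rbind, out)
}

#' Infer the heterogametic sex-determination system from candidates
#'
#' All-female-heterogametic candidates indicate a ZW/ZZ system (females
#' carry the two different sex chromosomes); all-male-heterogametic
#' candidates indicate XY/XX; anything else (none, or a mixture) is
#' undetermined.
#'
#' @param candidates [screen_sex_association()] output.
#' @return list of class `sex_system_call`: `system` (`"ZW"`, `"XY"` or
#'   `"undetermined"`), `n_female_het_loci`, `n_male_het_loci`.
#' @export
infer_sex_system <- function(candidates) {
  nf <- sum(candidates$heterogametic_sex == "female")
  nm <- sum(candidates$heterogametic_sex == "male")
  system <- if (nf >= 1 && nm == 0) "ZW"
            else if (nm >= 1 && nf == 0) "XY"
            else "undetermined"
  structure(list(system = system, n_female_het_loci = nf,
                 n_male_het_loci = nm),
            class = "sex_system_call")
}

#' @export
print.sex_system_call <- function(x, ...) {
  cat(sprintf("sex system: %s (%d female-heterogametic, %d male-heterogametic loci)\n",
              x$system, x$n_female_het_loci, x$n_male_het_loci))
  invisible(x)
}

#' Chance probability of perfect sex-cosegregation at an autosomal locus
#'
#' For an informative autosomal locus (one parent het, the other hom), each
#' progeny is het with probability 1/2 independently of sex. A perfect
#' sex-split (all of one sex het and all of the other hom, either
#' orientation) therefore occurs with probability
#' `2 * (1/2)^(n_female + n_male)` — the false-positive rate per informative
#' autosomal locus of the perfect-cosegregation screen.
#'
#' @param n_female,n_male progeny counts per sex (>= 1).
#' @return probability.
#' @export
#' @examples
#' chance_cosegregation_probability(8, 8)  # 2 * 2^-16
chance_cosegregation_probability <- function(n_female, n_male) {
  stopifnot(n_female >= 1, n_male >= 1)
  2 * 0.5^(n_female + n_male)
}

#' Score candidate markers against a validation panel
#'
#' Applies the heterogamety rule (het genotype => the marker's heterogametic
#' sex, hom => the other sex) to an independent panel of individuals with
#' known sex, and reports per-marker accuracy. Individuals with missing
#' calls are counted separately, not as errors; markers predicting every
#' scored individual correctly are flagged `validated`.
#'
#' @param candidates [screen_sex_association()] output.
#' @param panel tibble with columns `individual_id`, `sex`, and one
#'   genotype column per `marker_name` ("A/C"-style calls, "./." missing).
#' @return tibble: `marker_name`, `n_scored`, `n_correct`, `n_missing`,
#'   `accuracy`, `validated`.
#' @export
score_validation_panel <- function(candidates, panel) {
  if (nrow(panel) == 0L) stop("validation panel is empty")
  stopifnot(all(c("individual_id", "sex") %in% names(panel)))
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    mk <- candidates$marker_name[i]
    if (!mk %in% names(panel)) next
    g <- panel[[mk]]
    miss <- is_missing_call(g)
    het_sex <- candidates$heterogametic_sex[i]
    hom_sex <- setdiff(c("female", "male"), het_sex)
    pred <- ifelse(is_het_call(g), het_sex, hom_sex)
    correct <- !miss & pred == panel$sex
    n_scored <- sum(!miss)
    acc <- if (n_scored > 0) sum(correct) / n_scored else NA_real_
    out[[length(out) + 1L]] <- tibble::tibble(
      marker_name = mk, n_scored = n_scored, n_correct = sum(correct),
      n_missing = sum(miss), accuracy = acc,
      validated = !is.na(acc) && acc == 1)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(marker_name = character(0), n_scored = integer(0),
                          n_correct = integer(0), n_missing = integer(0),
                          accuracy = numeric(0), validated = logical(0)))
  }
  do.call(rbind, out)
}
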