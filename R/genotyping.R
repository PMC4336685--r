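#' Call per-individual genotypes at catalog variant positions
#'
#' Converts each individual's allele observations at every non-repetitive,
#' variant-bearing catalog locus into diploid genotype calls. At a locus an
#' individual is called:
#' * heterozygous when exactly two alleles each reach `min_allele_depth`
#'   and the minor/major depth ratio is at least `min_minor_ratio` — the
#'   call at each variant position pairs the two alleles' bases there;
#' * homozygous when a single allele reaches `min_allele_depth` (a shallow
#'   second allele below the depth floor — the pattern sequencing-error
#'   stacks produce — is discarded with a logged note);
#' * missing otherwise, with a reason: `no_stack`, `low_depth`,
#'   `allele_imbalance` (two credible alleles whose depth ratio is too
#'   skewed to call confidently), or `ambiguous` (more than two credible
#'   alleles).
#'
#' Het calls are unordered: the genotype string always lists the two bases
#' alphabetically ("A/C", never "C/A").
#'
#' @param catalog a [build_catalog()] result.
#' @param individuals character vector of all individuals that should appear
#'   as columns (individuals without alleles at a locus are `no_stack`).
#' @param min_allele_depth minimum reads supporting an allele (default 3).
#' @param min_minor_ratio minimum minor/major allele depth ratio for a het
#'   call (default 0.25).
#' @return list of class `genotype_matrix`: `calls` (tibble: `locus_id`,
#'   `position`, then one genotype column per individual, "A/C"-style or
#'   "./."), and `notes` (tibble: `locus_id`, `individual_id`, `note`).
#' @export
call_genotypes <- function(catalog, individuals, min_allele_depth = 3L,
                           min_minor_ratio = 0.25) {
  stopifnot(inherits(catalog, "rad_catalog"),
            min_allele_depth >= 1, min_minor_ratio >= 0, min_minor_ratio <= 1)
  loci <- catalog$loci
  target <- loci[!loci$repetitive & lengths(loci$variant_positions) > 0, ,
                 drop = FALSE]
  rows <- list()
  notes <- list()
  if (nrow(target) > 0) {
    alleles_by_locus <- split(catalog$alleles,
                              factor(catalog$alleles$locus_id,
                                     levels = target$locus_id))
    for (li in seq_len(nrow(target))) {
      locus <- target$locus_id[li]
      vp <- target$variant_positions[[li]]
      al <- alleles_by_locus[[locus]]
      geno <- matrix("./.", nrow = length(vp), ncol = length(individuals),
                     dimnames = list(NULL, individuals))
      for (id in individuals) {
        sub <- al[al$individual_id == id, , drop = FALSE]
        if (nrow(sub) == 0L) {
          notes[[length(notes) + 1L]] <- data.frame(
            locus_id = locus, individual_id = id, note = "no_stack")
          next
        }
        sub <- sub[order(-sub$depth, sub$allele), , drop = FALSE]
        pass <- sub$depth >= min_allele_depth
        if (!any(pass)) {
          notes[[length(notes) + 1L]] <- data.frame(
            locus_id = locus, individual_id = id, note = "low_depth")
          next
        }
        kept <- sub[pass, , drop = FALSE]
        if (nrow(kept) > 2L) {
          notes[[length(notes) + 1L]] <- data.frame(
            locus_id = locus, individual_id = id, note = "ambiguous")
          next
        }
        if (nrow(kept) == 2L) {
          ratio <- kept$depth[2] / kept$depth[1]
          if (ratio >= min_minor_ratio) {
            b1 <- substring(kept$allele[1], vp, vp)
            b2 <- substring(kept$allele[2], vp, vp)
            geno[, id] <- genotype_string(pmin(b1, b2), pmax(b1, b2))
          } else {
            notes[[length(notes) + 1L]] <- data.frame(
              locus_id = locus, individual_id = id, note = "allele_imbalance")
          }
          next
        }
        if (nrow(sub) > nrow(kept)) {
          notes[[length(notes) + 1L]] <- data.frame(
            locus_id = locus, individual_id = id, note = "allele_imbalance")
        }
        b <- substring(kept$allele[1], vp, vp)
        geno[, id] <- genotype_string(b, b)
      }
      rows[[length(rows) + 1L]] <- cbind(
        tibble::tibble(locus_id = locus, position = vp),
        tibble::as_tibble(geno))
    }
  }
  calls <- if (length(rows)) tibble::as_tibble(do.call(rbind, rows)) else
    tibble::as_tibble(c(list(locus_id = character(0), position = integer(0)),
                        setNames(rep(list(character(0)), length(individuals)),
                                 individuals)))
  nt <- if (length(notes)) tibble::as_tibble(do.call(rbind, notes)) else
    tibble::tibble(locus_id = character(0), individual_id = character(0),
                   note = character(0))
  structure(list(calls = calls, notes = nt), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d (locus, position) rows x %d individuals, %d notes\n",
              nrow(x$calls), ncol(x$calls) - 2L, nrow(x$notes)))
  invisible(x)
}
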