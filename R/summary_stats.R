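#' Per-individual RAD sequencing summary row
#'
#' Derives the standard reduced-representation accounting for one individual
#' from its read and tag counts:
#' * total RAD sequence (bp) = read number x 82 (the fixed tag length),
#' * total tag sequence (bp) = number of RAD tags x 82,
#' * coverage depth (x) = read number / number of RAD tags,
#' * sequence coverage (x) = total RAD sequence / genome size.
#'
#' Ratios are returned unrounded; [radseq_summary_table()] applies the
#' printed-precision rounding (one decimal for the x-columns) when the full
#' table is assembled, so that group subtotals and means are computed on
#' exact values.
#'
#' @param individual_id sample label.
#' @param read_number number of demultiplexed 82-nt reads.
#' @param n_rad_tags number of distinct RAD tag stacks.
#' @param genome_size haploid genome size in bp used for sequence coverage
#'   (default 660 Mbp, the flow-cytometry estimate for pistachio; synthetic
#'   runs pass the simulated genome length).
#' @param base_counts optional named vector of A/C/G/T counts over all read
#'   bases, used to compute the GC rate; alternatively pass `gc_rate`.
#' @param gc_rate optional GC percentage (used when base counts are not
#'   available, e.g. when reproducing a published table).
#' @param total_snp,het_snp_rate optional SNP count and heterozygous-SNP
#'   percentage carried through to the summary table.
#' @param tag_length fixed RAD tag length in bp (82 for 90-bp reads with an
#'   8-nt inline barcode).
#' @return a one-row [tibble::tibble()] with the derived columns; coverage
#'   depth is `NA` when `n_rad_tags` is 0.
#' @export
#' @examples
#' summarize_individual("F-1", read_number = 15873498, n_rad_tags = 422422)
summarize_individual <- function(individual_id, read_number, n_rad_tags,
                                 genome_size = 660e6, base_counts = NULL,
                                 gc_rate = NA_real_, total_snp = NA_real_,
                                 het_snp_rate = NA_real_, tag_length = 82L) {
  stopifnot(read_number >= 0, n_rad_tags >= 0, genome_size > 0)
  if (!is.null(base_counts)) {
    tot <- sum(base_counts[c("A", "C", "G", "T")])
    gc_rate <- if (tot > 0) 100 * sum(base_counts[c("G", "C")]) / tot else NA_real_
  }
  tibble::tibble(
    individual_id = individual_id,
    read_number = read_number,
    total_rad_sequence = read_number * tag_length,
    n_rad_tags = n_rad_tags,
    total_tag_sequence = n_rad_tags * tag_length,
    coverage_depth = if (n_rad_tags > 0) read_number / n_rad_tags else NA_real_,
    sequence_coverage = read_number * tag_length / genome_size,
    gc_rate = gc_rate,
    total_snp = total_snp,
    het_snp_rate = het_snp_rate
  )
}

#' SNP density as base pairs per SNP
#'
#' The inverse SNP rate over the assembled tag sequence: how many bp of tag
#' sequence carry, on average, one SNP. Rounded half-up to the nearest
#' integer, the convention used when quoting figures such as "one SNP per
#' 449 bp".
#'
#' @param total_tag_sequence tag sequence length in bp.
#' @param total_snp SNP count; `NA` is returned when 0.
#' @return integer-valued bp-per-SNP figure (NA when undefined).
#' @export
bp_per_snp <- function(total_tag_sequence, total_snp) {
  ifelse(is.na(total_snp) | total_snp <= 0, NA_real_,
         round_half_up(total_tag_sequence / total_snp))
}

#' Group subtotal and mean rows for a RAD summary
#'
#' Computes, for each group label and for the full table, a `Subtotal` (or
#' `Total`) row of column sums and a `Subaverage` (or `Average`) row of
#' arithmetic means over the per-individual values. Ratio columns (coverage
#' depth, sequence coverage, rates) are summed and averaged as per-individual
#' ratios, not re-derived from the summed counts: a group's mean depth is the
#' mean of its individuals' depths, which differs from the ratio of its
#' summed reads to summed tags when depth varies between individuals.
#'
#' @param rows tibble of per-individual rows from [summarize_individual()].
#' @param groups character vector of group labels, one per row.
#' @return tibble of subtotal/subaverage rows per group plus overall
#'   total/average rows, with a `row_type` column.
#' @export
summarize_group <- function(rows, groups) {
  stopifnot(nrow(rows) >= 1, length(groups) == nrow(rows))
  num_cols <- c("read_number", "total_rad_sequence", "n_rad_tags",
                "total_tag_sequence", "coverage_depth", "sequence_coverage",
                "gc_rate", "total_snp", "het_snp_rate")
  agg <- function(sub, label, type, fun) {
    out <- tibble::tibble(individual_id = label)
    for (cl in num_cols) out[[cl]] <- fun(sub[[cl]])
    out$row_type <- type
    out
  }
  res <- list()
  for (g in unique(groups)) {
    sub <- rows[groups == g, , drop = FALSE]
    res[[paste0(g, "_subtotal")]] <-
      agg(sub, paste(g, "Subtotal"), "subtotal", function(x) sum(x))
    res[[paste0(g, "_subaverage")]] <-
      agg(sub, paste(g, "Subaverage"), "subaverage", function(x) mean(x))
  }
  res$total <- agg(rows, "Total", "total", function(x) sum(x))
  res$average <- agg(rows, "Average", "average", function(x) mean(x))
  do.call(rbind, res)
}

#' Assemble a printed-precision RAD sequencing summary table
#'
#' Binds per-individual rows and their group subtotal/mean rows into one
#' table and rounds the derived columns to the conventional display
#' precision: coverage depth and sequence coverage to 1 decimal (half-up),
#' GC rate to 2 decimals, heterozygous-SNP rate to 1 decimal, counts to
#' integers.
#'
#' @inheritParams summarize_group
#' @return tibble with individual rows followed by group rows, rounded.
#' @export
radseq_summary_table <- function(rows, groups) {
  rows$row_type <- "individual"
  grp <- summarize_group(rows[, setdiff(names(rows), "row_type")], groups)
  out <- rbind(rows[, names(grp)], grp)
  out$coverage_depth <- round_half_up(out$coverage_depth, 1)
  out$sequence_coverage <- round_half_up(out$sequence_coverage, 1)
  out$gc_rate <- round_half_up(out$gc_rate, 2)
  out$het_snp_rate <- round_half_up(out$het_snp_rate, 1)
  for (cl in c("read_number", "total_rad_sequence", "n_rad_tags",
               "total_tag_sequence", "total_snp")) {
    out[[cl]] <- round_half_up(out[[cl]])
  }
  tibble::as_tibble(out)
}
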