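#' Generate 8-nt multiplex identifier barcodes
#'
#' Random 8-nt inline barcodes (MIDs) with pairwise Hamming distance >= 3,
#' so exact-match demultiplexing is robust to any single sequencing error in
#' the barcode.
#'
#' @param ids individual identifiers (one barcode per id).
#' @param seed RNG seed.
#' @param min_distance minimum pairwise Hamming distance (default 3).
#' @return named character vector of barcodes.
#' @export
make_mid_barcodes <- function(ids, seed, min_distance = 3L) {
  set.seed(seed)
  mids <- character(0)
  attempts <- 0L
  while (length(mids) < length(ids)) {
    cand <- random_dna(MID_LENGTH)
    if (length(mids) == 0L || all(hamming(cand, mids) >= min_distance)) {
      mids <- c(mids, cand)
    }
    attempts <- attempts + 1L
    if (attempts > 10000L) stop("could not generate enough distinct MIDs")
  }
  setNames(mids, ids)
}

#' Read-simulation parameters
#'
#' @param read_length total read length including the 8-nt inline barcode;
#'   must equal 8 + 82 = 90.
#' @param mean_depth_per_tag expected read depth per tag per individual
#'   (split Poisson(mean/2) per haplotype).
#' @param error_rate per-base substitution probability, in \[0, 0.05\].
#' @param seed RNG seed, recorded in the run manifest.
#' @return list of class `radsex_read_params`.
#' @export
radsex_read_params <- function(read_length = 90L, mean_depth_per_tag = 20,
                               error_rate = 0.005, seed = 1L) {
  stopifnot(read_length == MID_LENGTH + TAG_LENGTH,
            mean_depth_per_tag >= 0,
            error_rate >= 0, error_rate <= 0.05)
  structure(list(read_length = as.integer(read_length),
                 mean_depth_per_tag = mean_depth_per_tag,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "radsex_read_params")
}

# Apply the individual's alt alleles carried on haplotype `hap` to the
# reference tag of `site`.
haplotype_tag <- function(genome, cross, individual_id, site, hap) {
  tag <- reference_tag(genome, site)
  if (is.na(tag)) return(NA_character_)
  idx <- which(cross$variants$site == site & cross$haplotypes[[individual_id]][, hap])
  for (i in idx) {
    p <- cross$variants$tag_pos[i]
    substr(tag, p, p) <- cross$variants$alt[i]
  }
  tag
}

#' Simulate a barcoded single-end RAD library
#'
#' Emits, for every individual, EcoRI site and haplotype, Poisson-distributed
#' copies of the read `MID + AATTC + 77 nt` of downstream haplotype sequence
#' (90 nt total), with independent per-base substitution errors. Base
#' qualities are constant (Q30) since the pipeline does not use them. Sites
#' too close to the genome end to yield a full 82-nt tag are skipped and
#' logged in the manifest.
#'
#' @param cross a [simulate_cross()] result.
#' @param genome the [simulate_genome()] result the cross was built on.
#' @param params a [radsex_read_params()] object.
#' @param barcodes named character vector of unique 8-nt MIDs, one per
#'   pedigree individual, pairwise Hamming distance >= 3
#'   (see [make_mid_barcodes()]).
#' @param fastq_path output FASTQ path (plain text).
#' @return invisibly, the run manifest: list with `params`, per-individual
#'   read counts, `total_reads`, `skipped_sites`, and the drawn depth table
#'   (`depths`: individual, site, haplotype, depth).
#' @export
simulate_reads <- function(cross, genome, params, barcodes, fastq_path) {
  stopifnot(inherits(cross, "sim_cross"), inherits(genome, "sim_genome"),
            inherits(params, "radsex_read_params"))
  ids <- cross$pedigree$individual_id
  if (!all(ids %in% names(barcodes))) stop("missing barcode for some individuals")
  barcodes <- barcodes[ids]
  stopifnot(all(nchar(barcodes) == MID_LENGTH), !anyDuplicated(barcodes))
  if (length(barcodes) > 1) {
    for (i in seq_along(barcodes)[-1]) {
      if (any(hamming(barcodes[i], barcodes[seq_len(i - 1)]) < 3)) {
        stop("MID barcodes must have pairwise Hamming distance >= 3")
      }
    }
  }

  set.seed(params$seed)
  usable <- genome$ecoRI_sites[genome$ecoRI_sites + 83L <= genome$length]
  skipped <- setdiff(genome$ecoRI_sites, usable)

  seqs <- character(0)
  names_out <- character(0)
  depth_rows <- list()
  per_ind <- setNames(integer(length(ids)), ids)

  for (id in ids) {
    mid <- barcodes[[id]]
    ind_seqs <- list()
    for (s in usable) {
      for (hap in 1:2) {
        d <- rpois(1, params$mean_depth_per_tag / 2)
        depth_rows[[length(depth_rows) + 1L]] <-
          data.frame(individual_id = id, site = s, haplotype = hap, depth = d)
        if (d == 0L) next
        tag <- haplotype_tag(genome, cross, id, s, hap)
        reads <- rep(paste0(mid, tag), d)
        if (params$error_rate > 0) {
          n_err <- rbinom(d, params$read_length, params$error_rate)
          for (r in which(n_err > 0L)) {
            pos <- sample.int(params$read_length, n_err[r])
            for (p in pos) {
              cur <- substr(reads[r], p, p)
              substr(reads[r], p, p) <- sample(setdiff(BASES, cur), 1)
            }
          }
        }
        ind_seqs[[length(ind_seqs) + 1L]] <- reads
        names_out <- c(names_out,
                       sprintf("%s:site%d:hap%d:%d", id, s, hap, seq_len(d)))
      }
    }
    ind_reads <- unlist(ind_seqs)
    if (is.null(ind_reads)) ind_reads <- character(0)
    per_ind[[id]] <- length(ind_reads)
    seqs <- c(seqs, ind_reads)
  }

  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names_out
  qual <- Biostrings::BStringSet(rep(strrep("?", params$read_length),
                                     length(dna)))  # constant Q30
  Biostrings::writeXStringSet(dna, fastq_path, format = "fastq",
                              qualities = qual)

  depths <- do.call(rbind, depth_rows)
  manifest <- list(
    params = unclass(params),
    sex_system = cross$sex_system,
    n_individuals = length(ids),
    reads_per_individual = as.list(per_ind),
    total_reads = length(seqs),
    total_drawn_depth = sum(depths$depth),
    skipped_sites = skipped,
    fastq = fastq_path,
    depths = depths
  )
  stopifnot(manifest$total_reads == manifest$total_drawn_depth)
  invisible(manifest)
}

#' Write a sample sheet mapping individuals to sex, role and barcode
#'
#' @param pedigree pedigree tibble from [simulate_cross()].
#' @param barcodes named character vector of MIDs.
#' @param path output TSV path; when `NULL` the sheet is only returned.
#' @return the sample sheet tibble (`individual_id`, `sex`, `role`, `mid`).
#' @export
write_sample_sheet <- function(pedigree, barcodes, path = NULL) {
  sheet <- tibble::tibble(
    individual_id = pedigree$individual_id,
    sex = pedigree$sex,
    role = pedigree$role,
    mid = unname(barcodes[pedigree$individual_id])
  )
  if (!is.null(path)) write_tsv(sheet, path)
  sheet
}
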