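#' Match tag stacks across individuals into catalog loci
#'
#' Single-linkage merge of per-individual stack consensi at Hamming
#' distance <= `catalog_mismatch` (default 2, mirroring the within-individual
#' clustering radius). Each resulting cluster is a catalog locus; the
#' distinct consensi an individual contributes to a locus are its alleles.
#' Loci where any individual contributes more than two distinct alleles are
#' flagged repetitive (putative paralog collapse) and carry no variant
#' positions. For the remaining loci, `variant_positions` are exactly the
#' 1-based tag columns (position 1 = the leading A of `AATTC`) at which
#' member alleles disagree.
#'
#' Candidate pairs are found by exact-match bucketing on
#' `catalog_mismatch + 1` sequence chunks (two sequences within the radius
#' must agree exactly on at least one chunk), so no quadratic all-pairs scan
#' is needed at catalog scale.
#'
#' @param stacks tibble with columns `individual_id`, `consensus`, `depth`
#'   (concatenated [build_stacks()] outputs across individuals).
#' @param catalog_mismatch merge radius (default 2).
#' @param parent_ids optional character vector; when parents contributed to
#'   a locus the reference consensus is the depth-weighted majority over the
#'   parental alleles, otherwise over all alleles.
#' @return object of class `rad_catalog`: list with `loci` (tibble:
#'   `locus_id`, `reference_consensus`, `repetitive`, `n_individuals`,
#'   `variant_positions` list-column) and `alleles` (tibble: `locus_id`,
#'   `individual_id`, `allele`, `depth`).
#' @export
build_catalog <- function(stacks, catalog_mismatch = 2L, parent_ids = NULL) {
  stopifnot(all(c("individual_id", "consensus", "depth") %in% names(stacks)))
  useq <- sort(unique(stacks$consensus))
  n <- length(useq)
  if (n == 0L) {
    return(structure(list(
      loci = tibble::tibble(locus_id = character(0),
                            reference_consensus = character(0),
                            repetitive = logical(0),
                            n_individuals = integer(0),
                            variant_positions = list()),
      alleles = tibble::tibble(locus_id = character(0),
                               individual_id = character(0),
                               allele = character(0), depth = integer(0))),
      class = "rad_catalog"))
  }
  mat <- seq_matrix(useq)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  w <- nchar(useq[1])
  k <- catalog_mismatch + 1L
  bounds <- floor(seq(0, w, length.out = k + 1L))
  for (c_i in seq_len(k)) {
    chunk <- substr(useq, bounds[c_i] + 1L, bounds[c_i + 1L])
    for (grp in split(seq_len(n), chunk)) {
      if (length(grp) < 2L) next
      for (a in seq_len(length(grp) - 1L)) {
        da <- row_hamming(mat, grp[a], grp[(a + 1L):length(grp)])
        for (b in which(da <= catalog_mismatch)) {
          union2(grp[a], grp[a + b])
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster_of <- match(roots, sort(unique(roots)))

  # Aggregate duplicate (individual, consensus) stacks; assign clusters.
  agg <- stats::aggregate(depth ~ individual_id + consensus, data = stacks, sum)
  agg$cluster <- cluster_of[match(agg$consensus, useq)]

  loci_rows <- list()
  allele_rows <- list()
  n_clusters <- max(cluster_of)
  id_width <- max(5L, nchar(as.character(n_clusters)))
  for (cl in seq_len(n_clusters)) {
    sub <- agg[agg$cluster == cl, , drop = FALSE]
    locus_id <- sprintf("L%0*d", id_width, cl)
    per_ind <- table(sub$individual_id)
    repetitive <- any(per_ind > 2L)

    ref_sub <- sub
    if (!is.null(parent_ids) && any(sub$individual_id %in% parent_ids)) {
      ref_sub <- sub[sub$individual_id %in% parent_ids, , drop = FALSE]
    }
    ref <- weighted_consensus(ref_sub$consensus, ref_sub$depth)

    vp <- integer(0)
    if (!repetitive) {
      alleles <- unique(sub$consensus)
      if (length(alleles) > 1L) {
        am <- seq_matrix(alleles)
        vp <- which(apply(am, 2, function(col) length(unique(col)) > 1L))
      }
    }
    loci_rows[[cl]] <- tibble::tibble(
      locus_id = locus_id, reference_consensus = ref,
      repetitive = repetitive, n_individuals = length(per_ind),
      variant_positions = list(as.integer(vp)))
    allele_rows[[cl]] <- tibble::tibble(
      locus_id = locus_id, individual_id = sub$individual_id,
      allele = sub$consensus, depth = as.integer(sub$depth))
  }
  structure(list(loci = do.call(rbind, loci_rows),
                 alleles = do.call(rbind, allele_rows)),
            class = "rad_catalog")
}

# Depth-weighted per-column majority over a set of allele sequences; ties
# resolved by the deepest allele's base.
weighted_consensus <- function(seqs, depths) {
  if (length(seqs) == 1L) return(seqs)
  mat <- seq_matrix(seqs)
  top <- which.max(depths)
  cons <- integer(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    votes <- rowsum(depths, mat[, j])
    best <- max(votes)
    winners <- as.integer(rownames(votes))[votes == best]
    cons[j] <- if (mat[top, j] %in% winners) mat[top, j] else winners[1]
  }
  intToUtf8(cons)
}

#' @export
print.rad_catalog <- function(x, ...) {
  cat(sprintf("rad_catalog: %d loci (%d repetitive), %d alleles, %d variant-bearing loci\n",
              nrow(x$loci), sum(x$loci$repetitive), nrow(x$alleles),
              sum(lengths(x$loci$variant_positions) > 0 & !x$loci$repetitive)))
  invisible(x)
}
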