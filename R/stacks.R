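#' Cluster one individual's RAD reads into tag stacks
#'
#' Greedy abundance-ordered star clustering: unique read sequences are
#' sorted by descending count (ties lexicographic); the most abundant
#' unassigned sequence founds a stack, and every unassigned sequence within
#' Hamming distance 2 of that founder joins it. The stack consensus is the
#' per-column majority over member reads weighted by read count, ties broken
#' by the founder's base. Stacks whose total depth falls below
#' `min_stack_depth` are moved to a residual list rather than reported, so
#' singleton sequencing errors do not masquerade as tags.
#'
#' A heterozygous individual's two tag alleles usually differ by only one
#' or two substitutions and therefore land in the same stack. Each stack is
#' consequently decomposed into its haplotype alleles: a column is
#' polymorphic within the stack when its second-most-supported base reaches
#' `min_allele_depth` reads and at least `min_minor_ratio` of the leading
#' base's support; member reads are then grouped by their bases at the
#' polymorphic columns and the two best-supported haplotypes become the
#' stack's alleles (one allele — the consensus — when no column is
#' polymorphic). The allele table is what [build_catalog()] matches across
#' individuals and [call_genotypes()] consumes.
#'
#' @param reads character vector of 82-nt read sequences (one element per
#'   read; duplicates are the depth signal).
#' @param min_stack_depth minimum total read depth for a reported stack
#'   (default 3).
#' @param max_mismatch clustering radius to the founder (default 2).
#' @param min_allele_depth,min_minor_ratio thresholds for declaring a
#'   within-stack polymorphic column (defaults 3 and 0.25, matching the
#'   genotyping defaults).
#' @return list with `stacks` (tibble: `stack`, `consensus`, `depth`,
#'   `n_members` = distinct member sequences) sorted by descending depth,
#'   `alleles` (tibble: `stack`, `allele`, `depth`), and `residual`
#'   (tibble: `sequence`, `count`) holding reads from sub-threshold stacks.
#' @export
build_stacks <- function(reads, min_stack_depth = 3L, max_mismatch = 2L,
                         min_allele_depth = 3L, min_minor_ratio = 0.25) {
  empty <- list(stacks = tibble::tibble(stack = integer(0),
                                        consensus = character(0),
                                        depth = integer(0),
                                        n_members = integer(0)),
                alleles = tibble::tibble(stack = integer(0),
                                         allele = character(0),
                                         depth = integer(0)),
                residual = tibble::tibble(sequence = character(0),
                                          count = integer(0)))
  if (length(reads) == 0L) return(empty)
  if (any(nchar(reads) != TAG_LENGTH)) {
    stop("all reads must be ", TAG_LENGTH, " nt")
  }
  tab <- table(reads)
  useq <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, useq)
  useq <- useq[ord]; cnt <- cnt[ord]
  mat <- seq_matrix(useq)

  n <- length(useq)
  assigned <- rep(FALSE, n)
  clusters <- list()
  while (!all(assigned)) {
    seed <- which(!assigned)[1]
    open <- which(!assigned)
    d <- row_hamming(mat, seed, open)
    members <- open[d <= max_mismatch]
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <-
      list(seed = seed, members = members,
           consensus = stack_consensus(mat, members, cnt[members], seed))
  }

  # Consensus-level merging: reads carrying a sequencing error on top of a
  # minor allele can found a satellite cluster whose consensus still lies
  # within the radius of the main cluster's consensus; fold satellites
  # into the deeper cluster before allele decomposition so minor-allele
  # support is not fragmented.
  repeat {
    if (length(clusters) < 2L) break
    depths <- vapply(clusters, function(cl) sum(cnt[cl$members]), numeric(1))
    cons_mat <- seq_matrix(vapply(clusters, `[[`, character(1), "consensus"))
    merged <- FALSE
    for (i in order(depths)) {
      others <- setdiff(seq_along(clusters), i)
      others <- others[depths[others] >= depths[i]]
      if (length(others) == 0L) next
      d <- row_hamming(cons_mat, i, others)
      if (min(d) > max_mismatch) next
      j <- others[which(d == min(d))]
      j <- j[which.max(depths[j])]
      tgt <- clusters[[j]]
      tgt$members <- c(tgt$members, clusters[[i]]$members)
      tgt$consensus <- stack_consensus(mat, tgt$members, cnt[tgt$members],
                                       tgt$seed)
      clusters[[j]] <- tgt
      clusters[[i]] <- NULL
      merged <- TRUE
      break
    }
    if (!merged) break
  }

  # Sub-threshold clusters feed the loose pool.
  depths <- vapply(clusters, function(cl) sum(cnt[cl$members]), numeric(1))
  loose <- unlist(lapply(clusters[depths < min_stack_depth], `[[`, "members"))
  if (is.null(loose)) loose <- integer(0)
  clusters <- clusters[depths >= min_stack_depth]
  if (length(clusters) == 0L) {
    out <- empty
    out$residual <- tibble::tibble(sequence = useq[loose],
                                   count = cnt[loose])
    return(out)
  }

  # Secondary attachment: a read carrying a sequencing error on top of a
  # non-founder allele lies outside the founder's radius but close to the
  # stack consensus; re-admit loose sequences within max_mismatch + 2 of a
  # consensus (nearest wins, ties to the deeper stack) before allele
  # decomposition, so allele depths are not biased against variant-bearing
  # haplotypes.
  if (length(loose) > 0L) {
    cons_all <- vapply(clusters, `[[`, character(1), "consensus")
    depths_all <- vapply(clusters, function(cl) sum(cnt[cl$members]),
                         numeric(1))
    still_loose <- logical(length(loose))
    for (r in seq_along(loose)) {
      d <- hamming(useq[loose[r]], cons_all)
      best <- min(d)
      if (best <= max_mismatch + 2L) {
        j <- which(d == best)
        j <- j[which.max(depths_all[j])]
        clusters[[j]]$members <- c(clusters[[j]]$members, loose[r])
      } else {
        still_loose[r] <- TRUE
      }
    }
    loose <- loose[still_loose]
  }

  stacks <- list()
  alleles <- list()
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    stacks[[k]] <- data.frame(stack = k, consensus = cl$consensus,
                              depth = sum(cnt[cl$members]),
                              n_members = length(cl$members))
    al <- decompose_stack_alleles(mat, cl$members, cnt[cl$members],
                                  cl$consensus, min_allele_depth,
                                  min_minor_ratio)
    alleles[[k]] <- data.frame(stack = k, allele = al$allele,
                               depth = al$depth)
  }
  st <- do.call(rbind, stacks)
  al <- do.call(rbind, alleles)

  # A shallow stack founded by error reads of a real allele sits within
  # the clustering radius of that allele but outside the radius of its own
  # founder; absorb such stacks into the matching allele of a deeper stack
  # so they are not reported as extra tags or extra alleles.
  merged <- reattach_error_stacks(st, al, max_mismatch)
  st <- merged$stacks; al <- merged$alleles

  ord <- order(-st$depth, st$consensus)
  st <- st[ord, , drop = FALSE]
  list(stacks = tibble::as_tibble(st), alleles = tibble::as_tibble(al),
       residual = tibble::tibble(sequence = useq[loose], count = cnt[loose]))
}

# Merge single-allele stacks into the nearest allele of a deeper stack
# when the consensus lies within `max_mismatch` of that allele and the
# stack is no deeper than it (error-derived stacks are shallow).
reattach_error_stacks <- function(st, al, max_mismatch) {
  repeat {
    single <- st$stack[!st$stack %in% al$stack[duplicated(al$stack)]]
    cand <- st[st$stack %in% single, , drop = FALSE]
    cand <- cand[order(cand$depth), , drop = FALSE]
    moved <- FALSE
    for (i in seq_len(nrow(cand))) {
      s <- cand$stack[i]
      others <- al[al$stack != s, , drop = FALSE]
      if (nrow(others) == 0L) next
      d <- hamming(cand$consensus[i], others$allele)
      if (min(d) > max_mismatch) next
      j <- which(d == min(d))
      j <- j[which.max(others$depth[j])]
      tgt_stack <- others$stack[j]
      tgt_allele <- others$allele[j]
      keep <- al$stack == tgt_stack & al$allele == tgt_allele
      al$depth[keep] <- al$depth[keep] + cand$depth[i]
      st$depth[st$stack == tgt_stack] <-
        st$depth[st$stack == tgt_stack] + cand$depth[i]
      st$n_members[st$stack == tgt_stack] <-
        st$n_members[st$stack == tgt_stack] +
        st$n_members[st$stack == s]
      st <- st[st$stack != s, , drop = FALSE]
      al <- al[al$stack != s, , drop = FALSE]
      moved <- TRUE
      break
    }
    if (!moved) break
  }
  list(stacks = st, alleles = al)
}

# Split a stack into its haplotype alleles. Columns where a second base has
# enough independent read support are treated as within-stack SNPs; member
# sequences are grouped by their base tuple at those columns and the two
# best-supported tuples define the alleles (reads whose tuple arose from
# sequencing error fall outside the top two and are ignored for allele
# depth, though they remain in the stack depth).
decompose_stack_alleles <- function(mat, members, weights, consensus,
                                    min_allele_depth, min_minor_ratio) {
  sub <- mat[members, , drop = FALSE]
  het_cols <- integer(0)
  for (j in seq_len(ncol(sub))) {
    votes <- sort(rowsum(weights, sub[, j])[, 1], decreasing = TRUE)
    if (length(votes) >= 2L && votes[2] >= min_allele_depth &&
        votes[2] / votes[1] >= min_minor_ratio) {
      het_cols <- c(het_cols, j)
    }
  }
  if (length(het_cols) == 0L) {
    return(data.frame(allele = consensus, depth = sum(weights)))
  }
  tuples <- apply(sub[, het_cols, drop = FALSE], 1, paste, collapse = ",")
  support <- sort(rowsum(weights, tuples)[, 1], decreasing = TRUE)
  top <- names(support)[seq_len(min(2L, length(support)))]
  out <- lapply(seq_along(top), function(t) {
    bases <- as.integer(strsplit(top[t], ",")[[1]])
    al <- consensus
    for (h in seq_along(het_cols)) {
      substr(al, het_cols[h], het_cols[h]) <- intToUtf8(bases[h])
    }
    data.frame(allele = al, depth = unname(support[t]))
  })
  do.call(rbind, out)
}

# Weighted per-column majority consensus; ties resolved in favour of the
# founding (seed) sequence's base.
stack_consensus <- function(mat, members, weights, seed) {
  sub <- mat[members, , drop = FALSE]
  seed_row <- mat[seed, ]
  cons <- integer(ncol(sub))
  for (j in seq_len(ncol(sub))) {
    votes <- rowsum(weights, sub[, j])
    best <- max(votes)
    winners <- as.integer(rownames(votes))[votes == best]
    cons[j] <- if (seed_row[j] %in% winners) seed_row[j] else winners[1]
  }
  intToUtf8(cons)
}
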