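# Independent brute-force oracles and small-instance generators used by the
# property tests. These deliberately avoid the package's own primitives
# (distance via strsplit, clustering via naive repeated merging) so that
# agreement is informative.

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# All-pairs single-linkage clustering at a Hamming radius: start from
# singletons and merge any two clusters containing a cross-pair within the
# radius until stable. Returns a cluster index per sequence.
oracle_single_linkage <- function(seqs, radius) {
  n <- length(seqs)
  cl <- seq_len(n)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- oracle_hamming(seqs[i], seqs[j])
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] != cl[j] && d[i, j] <= radius) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl))
}

# Row-by-row perfect-cosegregation screen, written independently of
# screen_sex_association: returns the row indices that qualify, with the
# heterogametic sex per hit.
oracle_screen <- function(calls, sexes, max_missing = 0L) {
  ids <- intersect(names(calls), names(sexes))
  females <- ids[sexes[ids] == "female"]
  males <- ids[sexes[ids] == "male"]
  hits <- list()
  for (i in seq_len(nrow(calls))) {
    g <- unlist(calls[i, ids])
    miss <- g == "./."
    if (sum(miss) > max_missing) next
    gf <- unique(g[setdiff(females, ids[miss])])
    gm <- unique(g[setdiff(males, ids[miss])])
    if (length(gf) != 1L || length(gm) != 1L) next
    het <- function(x) substr(x, 1, 1) != substr(x, 3, 3)
    bases <- function(x) c(substr(x, 1, 1), substr(x, 3, 3))
    if (het(gf) && !het(gm) && bases(gm)[1] %in% bases(gf)) {
      hits[[length(hits) + 1L]] <- data.frame(row = i, het_sex = "female")
    } else if (het(gm) && !het(gf) && bases(gf)[1] %in% bases(gm)) {
      hits[[length(hits) + 1L]] <- data.frame(row = i, het_sex = "male")
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(row = integer(0), het_sex = character(0)))
  }
  do.call(rbind, hits)
}

random_tag <- function(len = 82L) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_tag <- function(tag, n_sub) {
  if (n_sub == 0L) return(tag)
  pos <- sample.int(nchar(tag), n_sub)
  for (p in pos) {
    cur <- substr(tag, p, p)
    substr(tag, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  tag
}

# An informative-cross genotype matrix (mother het, father homozygous
# reference, each progeny het with probability 1/2), as emitted by the
# genotyping stage; used for screening properties and the false-positive
# calibration.
informative_genotype_matrix <- function(n_loci, n_female, n_male,
                                        include_parents = TRUE) {
  prog_sex <- c(rep("female", n_female), rep("male", n_male))
  prog_ids <- sprintf("P%03d", seq_along(prog_sex))
  ids <- c(if (include_parents) c("mother", "father"), prog_ids)
  sexes <- stats::setNames(
    c(if (include_parents) c("female", "male"), prog_sex), ids)
  calls <- tibble::tibble(locus_id = sprintf("L%05d", seq_len(n_loci)),
                          position = rep(10L, n_loci))
  for (id in ids) calls[[id]] <- NA_character_
  for (i in seq_len(n_loci)) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    het <- paste(min(ref, alt), max(ref, alt), sep = "/")
    hom <- paste(ref, ref, sep = "/")
    g <- ifelse(stats::runif(length(prog_ids)) < 0.5, het, hom)
    row <- c(if (include_parents) c(het, hom), g)
    for (k in seq_along(ids)) calls[[ids[k]]][i] <- row[k]
  }
  list(calls = calls, sexes = sexes)
}

# A small complete simulated run shared by several test files (cheap: a
# 12-kb genome, 3 + 3 progeny, error-free deep reads).
tiny_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_radsex_pipeline(radsex_config(
        genome_length = 12000L, n_ecoRI_target = 20L,
        sex_region_fraction = 0.25, n_female = 3L, n_male = 3L,
        n_sex_linked = 2L, n_autosomal = 10L,
        mean_depth_per_tag = 30, error_rate = 0, seed = 1L), quiet = TRUE)
    }
    cache
  }
})
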