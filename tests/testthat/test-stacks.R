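test_that("hamming distance matches a naive positional comparison", {
  expect_equal(hamming("AATTC", "AATTC"), 0)
  a <- paste(rep("A", 82), collapse = "")
  b <- a; substr(b, 3, 3) <- "C"; substr(b, 70, 70) <- "G"
  expect_equal(hamming(a, b), 2)
  expect_error(hamming("AAA", "AAAA"), "equal-length")
  set.seed(101)
  for (i in 1:25) {
    x <- random_tag(40); y <- mutate_tag(x, sample(0:6, 1))
    expect_equal(hamming(x, y), oracle_hamming(x, y))
  }
})

test_that("identical reads form a single stack with themselves as consensus", {
  tag <- paste0("AATTC", strrep("A", 77))
  bs <- build_stacks(rep(tag, 20))
  expect_equal(nrow(bs$stacks), 1)
  expect_equal(bs$stacks$depth, 20)
  expect_equal(bs$stacks$consensus, tag)
  expect_equal(bs$alleles$allele, tag)
})

test_that("a minority substitution is absorbed and outvoted in the consensus", {
  set.seed(102)
  x <- random_tag(82)
  y <- mutate_tag(x, 1)
  bs <- build_stacks(c(rep(x, 15), rep(y, 2)))
  expect_equal(nrow(bs$stacks), 1)
  expect_equal(bs$stacks$depth, 17)
  expect_equal(bs$stacks$consensus, x)
})

test_that("sequences beyond the clustering radius form separate stacks", {
  set.seed(103)
  x <- random_tag(82)
  y <- mutate_tag(x, 5)
  bs <- build_stacks(c(rep(x, 10), rep(y, 10)))
  expect_equal(nrow(bs$stacks), 2)
  expect_setequal(bs$stacks$consensus, c(x, y))
})

test_that("sub-threshold sequences go to the residual, far from any stack", {
  set.seed(104)
  x <- random_tag(82)
  y <- mutate_tag(x, 20)
  bs <- build_stacks(c(rep(x, 10), rep(y, 2)), min_stack_depth = 3)
  expect_equal(nrow(bs$stacks), 1)
  expect_equal(sum(bs$residual$count), 2)
  # every input read is accounted for: stacks + residual
  expect_equal(sum(bs$stacks$depth) + sum(bs$residual$count), 12)
})

test_that("a heterozygous stack decomposes into its two haplotype alleles", {
  set.seed(105)
  x <- random_tag(82)
  y <- mutate_tag(x, 2)
  bs <- build_stacks(c(rep(x, 12), rep(y, 9)))
  expect_equal(nrow(bs$stacks), 1)  # alleles within radius share a stack
  al <- bs$alleles[order(-bs$alleles$depth), ]
  expect_equal(nrow(al), 2)
  expect_setequal(al$allele, c(x, y))
  expect_equal(al$depth, c(12, 9))
})

test_that("reads with an extra error on the minor allele still back it", {
  set.seed(106)
  x <- random_tag(82)
  y <- mutate_tag(x, 2)
  noisy <- vapply(1:4, function(i) mutate_tag(y, 1), character(1))
  bs <- build_stacks(c(rep(x, 14), rep(y, 4), noisy))
  al <- bs$alleles[order(-bs$alleles$depth), ]
  expect_equal(nrow(al), 2)
  expect_equal(al$depth, c(14, 8))
  expect_setequal(al$allele, c(x, y))
})

test_that("catalog merging matches brute-force single-linkage on random instances", {
  set.seed(107)
  for (rep in 1:60) {
    n_loci <- sample(2:5, 1)
    seqs <- character(0); owner <- character(0)
    for (l in seq_len(n_loci)) {
      base <- random_tag(82)
      n_al <- sample(1:4, 1)
      for (a in seq_len(n_al)) {
        seqs <- c(seqs, mutate_tag(base, sample(0:3, 1)))
        owner <- c(owner, sprintf("ind%d", sample(1:4, 1)))
      }
    }
    keep <- !duplicated(seqs)
    seqs <- seqs[keep]; owner <- owner[keep]
    stacks <- tibble::tibble(individual_id = owner, consensus = seqs,
                             depth = sample(3:30, length(seqs), replace = TRUE))
    cat_res <- build_catalog(stacks, catalog_mismatch = 2)
    got <- cat_res$alleles
    got_cluster <- got$locus_id[match(seqs, got$allele)]
    want_cluster <- oracle_single_linkage(seqs, 2)
    # same partition: cluster labels must be a bijection
    expect_equal(length(unique(got_cluster)), length(unique(want_cluster)))
    expect_true(all(tapply(want_cluster, got_cluster,
                           function(z) length(unique(z)) == 1)))
  }
})

test_that("catalog variant positions are the disagreeing columns", {
  set.seed(108)
  base <- random_tag(82)
  alt <- base
  substr(alt, 28, 28) <- if (substr(base, 28, 28) == "C") "T" else "C"
  stacks <- tibble::tibble(
    individual_id = c("mother", "mother", "father", "kid"),
    consensus = c(base, alt, base, base),
    depth = c(10, 9, 20, 15))
  ctl <- build_catalog(stacks, parent_ids = c("mother", "father"))
  expect_equal(nrow(ctl$loci), 1)
  expect_equal(ctl$loci$variant_positions[[1]], 28L)
  expect_false(ctl$loci$repetitive)
})

test_that("an individual with three alleles flags the locus repetitive", {
  set.seed(109)
  base <- random_tag(82)
  a1 <- mutate_tag(base, 1); a2 <- mutate_tag(base, 1)
  while (a2 == a1) a2 <- mutate_tag(base, 1)
  stacks <- tibble::tibble(
    individual_id = c("x", "x", "x", "y"),
    consensus = c(base, a1, a2, base),
    depth = c(10, 10, 10, 12))
  ctl <- build_catalog(stacks)
  expect_true(ctl$loci$repetitive)
  expect_length(ctl$loci$variant_positions[[1]], 0)
})

test_that("error-free simulation yields one catalog locus per usable site", {
  run <- tiny_run()
  usable <- sum(run$genome$ecoRI_sites + 83 <= run$genome$length)
  expect_equal(nrow(run$catalog$loci), usable)
  expect_false(any(run$catalog$loci$repetitive))
  expect_true(all(!is.na(run$locus_map$site)))
})
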