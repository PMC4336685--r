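test_that("simulated genomes carry the requested EcoRI sites", {
  g <- simulate_genome(100000, 50, 0.2, seed = 1)
  # count occurrences by direct string scan, independent of the generator
  occ <- gregexpr("GAATTC", g$sequence, fixed = TRUE)[[1]]
  expect_true(length(occ) >= 40 && length(occ) <= 60)
  expect_setequal(as.integer(occ) - 1L, g$ecoRI_sites)
  in_region <- sum(g$ecoRI_sites < g$sex_region[2])
  expect_gte(in_region, 8)
  # every listed offset points at an exact GAATTC occurrence
  for (s in g$ecoRI_sites[1:5]) {
    expect_equal(substr(g$sequence, s + 1, s + 6), "GAATTC")
  }
  expect_true(g$sex_region[2] <= g$length)
})

test_that("genome simulation is deterministic and rejects bad requests", {
  a <- simulate_genome(20000, 12, 0.3, seed = 9)
  b <- simulate_genome(20000, 12, 0.3, seed = 9)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$ecoRI_sites, b$ecoRI_sites)
  expect_error(simulate_genome(10000, 0, 0.2, seed = 1), "min_loci")
  expect_error(simulate_genome(10000, 500, 0.2, seed = 1), "unsatisfiable")
  expect_error(simulate_genome(5000, 10, 0.2, seed = 1))
})

test_that("a ZW x ZZ cross makes all W carriers het and no WW individual", {
  g <- simulate_genome(50000, 40, 0.25, seed = 2)
  v <- plant_variants(g, 1, 5, seed = 3)
  cr <- simulate_cross(g, 8, 8, v, seed = 4)
  expect_false(any(cr$pedigree$karyotype == "WW"))
  expect_equal(sum(cr$pedigree$sex == "female"), 9)  # mother + 8 daughters
  sl <- cr$truth[cr$truth$linkage == "sex_linked", ]
  expect_equal(nrow(sl), 1)
  ids <- cr$pedigree$individual_id
  g_by_ind <- unlist(sl[1, ids])
  het <- substr(g_by_ind, 1, 1) != substr(g_by_ind, 3, 3)
  sex <- setNames(cr$pedigree$sex, ids)
  expect_equal(sum(het), 9)           # every female, including the mother
  expect_true(all(sex[het] == "female"))
  expect_true(all(sex[!het] == "male"))
})

test_that("a cross with no sex-linked variants has none in the truth table", {
  g <- simulate_genome(30000, 20, 0.25, seed = 5)
  v <- plant_variants(g, 0, 4, seed = 6)
  cr <- simulate_cross(g, 2, 2, v, seed = 7)
  expect_false(any(cr$truth$linkage == "sex_linked"))
})

test_that("informative autosomal variants segregate 1:1 in progeny", {
  g <- simulate_genome(30000, 20, 0.25, seed = 8)
  v <- plant_variants(g, 0, 1, seed = 9)
  cr <- simulate_cross(g, 600, 600, v, seed = 10)
  prog <- cr$pedigree$individual_id[cr$pedigree$role == "progeny"]
  gt <- unlist(cr$truth[1, prog])
  het_frac <- mean(substr(gt, 1, 1) != substr(gt, 3, 3))
  se <- sqrt(0.25 / length(prog))
  expect_lt(abs(het_frac - 0.5), 3 * se)
})

test_that("variant offsets outside the genome are rejected", {
  g <- simulate_genome(30000, 20, 0.25, seed = 11)
  v <- plant_variants(g, 1, 1, seed = 12)
  v$genome_offset[1] <- 1e7L
  expect_error(simulate_cross(g, 2, 2, v, seed = 13), "outside genome")
})

test_that("error-free reads are MID + AATTC + 77 nt at the drawn depths", {
  g <- simulate_genome(15000, 10, 0.3, seed = 21)
  v <- plant_variants(g, 1, 2, seed = 22)
  cr <- simulate_cross(g, 1, 1, v, seed = 23)
  mids <- make_mid_barcodes(cr$pedigree$individual_id, seed = 24)
  fq <- tempfile(fileext = ".fastq")
  params <- radsex_read_params(mean_depth_per_tag = 20, error_rate = 0,
                               seed = 25)
  man <- simulate_reads(cr, g, params, mids, fq)
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  expect_equal(length(reads), man$total_reads)
  expect_equal(man$total_reads, sum(man$depths$depth))  # conservation
  expect_true(all(nchar(reads) == 90))
  trimmed <- substr(reads, 9, 90)
  expect_true(all(nchar(trimmed) == 82))
  expect_true(all(startsWith(trimmed, "AATTC")))
  expect_true(all(substr(reads, 1, 8) %in% mids))
})

test_that("zero depth yields an empty FASTQ with a valid manifest", {
  g <- simulate_genome(15000, 10, 0.3, seed = 31)
  cr <- simulate_cross(g, 1, 1, plant_variants(g, 0, 1, seed = 32), seed = 33)
  mids <- make_mid_barcodes(cr$pedigree$individual_id, seed = 34)
  fq <- tempfile(fileext = ".fastq")
  man <- simulate_reads(cr, g,
                        radsex_read_params(mean_depth_per_tag = 0,
                                           error_rate = 0, seed = 35),
                        mids, fq)
  expect_equal(man$total_reads, 0)
  expect_equal(length(Biostrings::readDNAStringSet(fq, format = "fastq")), 0)
})

test_that("the observed substitution rate matches the requested error rate", {
  g <- simulate_genome(15000, 10, 0.3, seed = 41)
  v <- plant_variants(g, 0, 0, seed = 42)
  cr <- simulate_cross(g, 1, 1, v, seed = 43)
  mids <- make_mid_barcodes(cr$pedigree$individual_id, seed = 44)
  fq <- tempfile(fileext = ".fastq")
  err <- 0.01
  man <- simulate_reads(cr, g,
                        radsex_read_params(mean_depth_per_tag = 60,
                                           error_rate = err, seed = 45),
                        mids, fq)
  reads <- Biostrings::readDNAStringSet(fq, format = "fastq")
  # with no variants every read should be MID + reference tag; count
  # mismatches against the truth sequence per read
  nm <- 0L; nb <- 0L
  rn <- names(reads)
  for (i in seq_along(reads)) {
    parts <- strsplit(rn[i], ":")[[1]]
    id <- parts[1]
    site <- as.integer(sub("site", "", parts[2]))
    truth <- paste0(mids[[id]], substr(g$sequence, site + 2, site + 83))
    nm <- nm + sum(charToRaw(as.character(reads[[i]])) != charToRaw(truth))
    nb <- nb + 90L
  }
  se <- sqrt(err * (1 - err) / nb)
  expect_lt(abs(nm / nb - err), 3 * se)
})

test_that("identical parameters reproduce the FASTQ byte for byte", {
  g <- simulate_genome(15000, 10, 0.3, seed = 51)
  v <- plant_variants(g, 1, 1, seed = 52)
  cr <- simulate_cross(g, 2, 2, v, seed = 53)
  mids <- make_mid_barcodes(cr$pedigree$individual_id, seed = 54)
  f1 <- tempfile(); f2 <- tempfile()
  p <- radsex_read_params(mean_depth_per_tag = 15, error_rate = 0.01,
                          seed = 55)
  simulate_reads(cr, g, p, mids, f1)
  simulate_reads(cr, g, p, mids, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("MID barcodes are unique with pairwise distance >= 3", {
  mids <- make_mid_barcodes(sprintf("i%02d", 1:18), seed = 61)
  expect_equal(length(unique(mids)), 18)
  expect_true(all(nchar(mids) == 8))
  for (i in 2:length(mids)) {
    expect_true(all(hamming(mids[i], mids[seq_len(i - 1)]) >= 3))
  }
})

test_that("an XY cross mirrors the ZW carrier rule", {
  g <- simulate_genome(30000, 24, 0.25, seed = 71)
  v <- plant_variants(g, 2, 3, seed = 72)
  cr <- simulate_cross(g, 4, 4, v, seed = 73, sex_system = "XY")
  sl <- cr$truth[cr$truth$linkage == "sex_linked", ]
  ids <- cr$pedigree$individual_id
  sex <- setNames(cr$pedigree$sex, ids)
  for (i in seq_len(nrow(sl))) {
    gt <- unlist(sl[i, ids])
    het <- substr(gt, 1, 1) != substr(gt, 3, 3)
    expect_true(all(sex[het] == "male"))
    expect_true(all(sex[!het] == "female"))
  }
})
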