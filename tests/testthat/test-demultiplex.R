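write_fastq <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("r%d", seq_along(seqs))
  qual <- Biostrings::BStringSet(unname(vapply(seqs, function(s)
    strrep("?", nchar(s)), character(1))))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  path
}

demo_sheet <- tibble::tibble(
  individual_id = c("A", "B"),
  sex = c("female", "male"),
  role = c("parent", "parent"),
  mid = c("AAAACCCC", "GGGGTTTT")
)

test_that("reads are assigned by exact barcode and restriction motif", {
  tag <- paste0("AATTC", strrep("G", 77))
  seqs <- c(
    paste0("AAAACCCC", tag),            # assigned to A
    paste0("GGGGTTTT", tag),            # assigned to B
    paste0("CCCCAAAA", tag),            # unknown barcode
    paste0("AAAACCCC", "TTTTC", strrep("G", 77)),  # broken motif
    paste0("AAAACCCC", "AATTC", strrep("N", 77)),  # contains N
    paste0("AAAACCCC", "AATTC", strrep("G", 40))   # wrong length
  )
  fq <- write_fastq(seqs, tempfile(fileext = ".fastq"))
  res <- demultiplex(fq, demo_sheet)
  expect_equal(res$counts$n_reads, c(1L, 1L))
  expect_equal(res$reads$A, tag)
  expect_true(all(nchar(res$reads$A) == 82))
  expect_true(startsWith(res$reads$A, "AATTC"))
  dl <- setNames(res$discards$n, res$discards$reason)
  expect_equal(dl[["unknown_barcode"]], 1L)
  expect_equal(dl[["bad_restriction_site"]], 1L)
  expect_equal(dl[["contains_N"]], 1L)
  expect_equal(dl[["wrong_length"]], 1L)
  # partition: assigned + discarded = total
  expect_equal(sum(res$counts$n_reads) + sum(res$discards$n), res$total)
})

test_that("single-mismatch rescue assigns near-miss barcodes when enabled", {
  tag <- paste0("AATTC", strrep("A", 77))
  seqs <- paste0("AAAACCCG", tag)  # one error in A's barcode
  fq <- write_fastq(seqs, tempfile(fileext = ".fastq"))
  strict <- demultiplex(fq, demo_sheet, barcode_mismatch = 0)
  expect_equal(sum(strict$counts$n_reads), 0L)
  rescue <- demultiplex(fq, demo_sheet, barcode_mismatch = 1)
  expect_equal(rescue$counts$n_reads[rescue$counts$individual_id == "A"], 1L)
})

test_that("duplicate barcodes in the sample sheet are rejected", {
  sheet <- demo_sheet
  sheet$mid <- c("AAAACCCC", "AAAACCCC")
  fq <- write_fastq(paste0("AAAACCCC", "AATTC", strrep("G", 77)),
                    tempfile(fileext = ".fastq"))
  expect_error(demultiplex(fq, sheet), "duplicate MID")
})

test_that("demultiplexed counts agree with the simulator manifest", {
  g <- simulate_genome(15000, 12, 0.3, seed = 81)
  v <- plant_variants(g, 1, 3, seed = 82)
  cr <- simulate_cross(g, 2, 2, v, seed = 83)
  mids <- make_mid_barcodes(cr$pedigree$individual_id, seed = 84)
  fq <- tempfile(fileext = ".fastq")
  man <- simulate_reads(cr, g,
                        radsex_read_params(mean_depth_per_tag = 20,
                                           error_rate = 0, seed = 85),
                        mids, fq)
  sheet <- write_sample_sheet(cr$pedigree, mids)
  res <- demultiplex(fq, sheet)
  expect_equal(sum(res$counts$n_reads), man$total_reads)
  expect_equal(
    setNames(res$counts$n_reads, res$counts$individual_id),
    unlist(man$reads_per_individual)[res$counts$individual_id])
  expect_equal(sum(res$discards$n), 0L)
})
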