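#' Published per-individual RADseq counts for the pistachio cross
#'
#' Read numbers, RAD tag counts, GC rates, SNP counts and heterozygous-SNP
#' rates for the 18 sequenced individuals of the Siirt x Bagyolu full-sib
#' family (female parent Siirt, male parent Bagyolu, 8 female and 8 male F1
#' progeny). These are the inputs to the summary accounting; all derived
#' columns (total sequence, coverage depth, sequence coverage at a 660-Mbp
#' genome, SNP densities) are recomputed by [radseq_summary_table()] and
#' [bp_per_snp()].
#'
#' @return tibble with columns `individual_id`, `sex`, `role`,
#'   `read_number`, `n_rad_tags`, `gc_rate`, `total_snp`, `het_snp_rate`.
#' @export
pistachio_radseq_counts <- function() {
  tibble::tribble(
    ~individual_id, ~sex, ~role, ~read_number, ~n_rad_tags, ~gc_rate, ~total_snp, ~het_snp_rate,
    "Siirt",   "female", "parent",  15873498, 422422, 37.65,  90999, 17.3,
    "P-F-1",   "female", "progeny", 24754856, 442751, 37.12,  98348, 26.9,
    "P-F-2",   "female", "progeny", 22527994, 513815, 37.60,  97562, 28.0,
    "P-F-3",   "female", "progeny", 28035806, 513654, 37.07,  99776, 25.3,
    "P-F-4",   "female", "progeny", 33578112, 560479, 36.86, 101339, 30.5,
    "P-F-5",   "female", "progeny", 23563272, 539390, 37.47,  98767, 31.9,
    "P-F-6",   "female", "progeny", 23374790, 523591, 37.38,  98876, 29.9,
    "P-F-7",   "female", "progeny", 28326906, 539702, 36.88, 100355, 27.4,
    "P-F-8",   "female", "progeny", 25474290, 431895, 37.64,  96551, 17.5,
    "Bagyolu", "male",   "parent",  27187532, 552533, 38.00,  79746, 33.1,
    "P-M-1",   "male",   "progeny", 22615328, 498044, 36.98,  98046, 27.2,
    "P-M-2",   "male",   "progeny", 10108252, 422176, 37.10,  75521, 20.5,
    "P-M-3",   "male",   "progeny", 19417040, 541272, 37.48,  95941, 26.7,
    "P-M-4",   "male",   "progeny", 11079312, 410036, 38.77,  72909, 18.6,
    "P-M-5",   "male",   "progeny", 38882284, 657285, 37.65, 102340, 30.5,
    "P-M-6",   "male",   "progeny", 26158302, 569710, 37.58, 100049, 27.0,
    "P-M-7",   "male",   "progeny", 29947304, 596268, 37.51,  99531, 27.5,
    "P-M-8",   "male",   "progeny", 39817004, 623841, 37.41, 103115, 27.8
  )
}

#' Published candidate sex-marker tag sequences in pistachio
#'
#' The 11 RAD tags carrying the 13 candidate sex-linked SNP loci for which
#' assay primers could be designed. Each `sequence` is the 82-nt tag written
#' 5'-3' starting at the residual EcoRI motif `AATTC`, with each candidate
#' SNP bracketed as its IUPAC ambiguity code, e.g. `(Y)`. Coordinates are
#' 1-based from the leading A of the tag, so the name suffix `Y28-77` means
#' C/T SNPs at tag positions 28 and 77.
#'
#' @return tibble with columns `marker_name`, `snp_codes`, `positions`
#'   (dash-separated, as named), `sequence` (bracketed).
#' @export
#' @examples
#' tags <- pistachio_sex_marker_tags()
#' variant_positions_from_bracketed(tags$sequence[tags$marker_name == "SNP-PIS-1319"])
pistachio_sex_marker_tags <- function() {
  tibble::tribble(
    ~marker_name, ~snp_codes, ~positions, ~sequence,
    "SNP-PIS-1319",   "Y-Y", "28-77", "AATTCGTATAGCCCGTGAGAATACATG(Y)GGATGAGGGCTATACATGAGAGAGAGTACACTCACATGGCCAAGGGTT(Y)CGAAT",
    "SNP-PIS-29689",  "Y-R", "33-71", "AATTCAACATCTTATAAAGCGAAATCACTTCA(Y)AATAATGCTTCTTCTTTGCAAGTGCACCAAACAATAT(R)TTGAATGATGA",
    "SNP-PIS-112277", "Y-R", "10-61", "AATTCGTTA(Y)CTAGAGGGTGATTTTAAAACTCTTACAGACACAAAACCATGACAATAATT(R)AAGGAAGAAAATTCAGCATGC",
    "SNP-PIS-120693", "M-W", "19-57", "AATTCAATGATCTAGATT(M)AAAGAAGGCATTGGATGTTGTGTATTGTCATTTGTAA(W)AATATCTTGGTGTGTAAAATGTGTA",
    "SNP-PIS-127343", "S",   "27",    "AATTCACCAATATTTTACTGCAATAA(S)TAAGAATGTAATGACAGGGTGAGTGAAAATGGTAGATTAAAATTTTAAGGAAATG",
    "SNP-PIS-133396", "S-Y", "46-47", "AATTCTCCTCTGTTTTTTGGGCAAACCGCAAAGAAGATTAAAGTA(S)(Y)TGATCCATGATCTTCAAGTTTCAGTACTATTCATA",
    "SNP-PIS-135862", "Y-Y", "40-41", "AATTCTTTGGTTTTGTGTCTGAATGTGGATAATATATGG(Y)(Y)GCCTCATGTTGATTATGGGAAATGTGCATGGAAATAGTATC",
    "SNP-PIS-136404", "K",   "23",    "AATTCTTTTAGGGGTTGTCAAA(K)TGACCGGATTCCTCACAAATTCAATTGCCAACTCTAAAGCTGGCAAGAAATTCTTTAGC",
    "SNP-PIS-167992", "W",   "36",    "AATTCAAACGAAAAATAACTTCATAGCGTGAGCTC(W)TTGTTCCACCTSTAACCGCAACCCTAAGCTGCAATTGATCACTTCC",
    "SNP-PIS-174431", "M",   "56",    "AATTCCATTACTTCAACAAGTCTCTAGCCGCGTACATATAAAAATTAACTACTCA(M)AGTGAAAGTGGAYAAATTGTTAAGTT",
    "SNP-PIS-176863", "R",   "57",    "AATTCCACATTTGACMAGGGTTGGAACTTTTGAGGTGGATGTGAGCTTGGAAGGTA(R)TATCATACTTTGCAGACAGGTCGAT"
  )
}

#' Variant coordinates from a bracketed tag sequence
#'
#' Parses an 82-nt tag written with each SNP as a single bracketed IUPAC
#' code, e.g. `"AATTC...(Y)...(R)..."`, and returns the 1-based positions of
#' the bracketed sites counting from the leading A of the tag (each
#' bracketed code occupies one position).
#'
#' @param sequence bracketed tag string.
#' @return integer vector of 1-based SNP positions.
#' @export
variant_positions_from_bracketed <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  tokens <- regmatches(sequence,
                       gregexpr("\\(([A-Z])\\)|[A-Z]", sequence))[[1]]
  which(startsWith(tokens, "("))
}

#' Strip brackets from a bracketed tag sequence
#'
#' Companion to [variant_positions_from_bracketed()]: returns the flat tag
#' with each bracketed SNP replaced by its IUPAC code letter.
#'
#' @inheritParams variant_positions_from_bracketed
#' @return plain character tag.
#' @export
unbracket_sequence <- function(sequence) {
  gsub("[()]", "", sequence)
}
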