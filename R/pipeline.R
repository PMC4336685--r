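#' Configuration for a full simulate-to-screen run
#'
#' Collects every stage parameter with the package defaults: a 100-kb
#' genome carrying 150 planted EcoRI sites (20% of the sequence is the
#' non-recombining sex region), a balanced cross of 8 female + 8 male F1
#' progeny plus the two parents, 5 sex-linked and 200 autosomal planted
#' SNPs, 20x mean tag depth and 0.5% per-base error. All randomness derives
#' from the single `seed` via fixed per-stage substreams.
#'
#' @param genome_length genome size in bp.
#' @param n_ecoRI_target planted EcoRI site count.
#' @param sex_region_fraction fraction of the genome in the sex region.
#' @param n_female,n_male F1 progeny counts.
#' @param n_sex_linked,n_autosomal planted variant counts.
#' @param mean_depth_per_tag,error_rate read-simulation parameters.
#' @param sex_system `"ZW"` or `"XY"`.
#' @param barcode_mismatch barcode rescue distance passed to
#'   [demultiplex()]; the pipeline default is 1 because simulated MIDs are
#'   pairwise Hamming >= 3 apart, making single-error rescue unambiguous
#'   and recovering the ~4% of reads that carry one barcode error.
#' @param min_stack_depth,catalog_mismatch,min_allele_depth,min_minor_ratio,max_missing
#'   downstream thresholds (see the stage functions).
#' @param marker_prefix marker-name prefix.
#' @param seed run seed.
#' @param outdir optional output directory; when given, all stage tables,
#'   the FASTQ and a JSON manifest are written there.
#' @return list of class `radsex_config`.
#' @export
radsex_config <- function(genome_length = 100000L, n_ecoRI_target = 150L,
                          sex_region_fraction = 0.2,
                          n_female = 8L, n_male = 8L,
                          n_sex_linked = 5L, n_autosomal = 200L,
                          mean_depth_per_tag = 20, error_rate = 0.005,
                          sex_system = c("ZW", "XY"), barcode_mismatch = 1L,
                          min_stack_depth = 3L, catalog_mismatch = 2L,
                          min_allele_depth = 3L, min_minor_ratio = 0.25,
                          max_missing = 0L, marker_prefix = "SIM",
                          seed = 1L, outdir = NULL) {
  cfg <- list(genome_length = genome_length, n_ecoRI_target = n_ecoRI_target,
              sex_region_fraction = sex_region_fraction,
              n_female = n_female, n_male = n_male,
              n_sex_linked = n_sex_linked, n_autosomal = n_autosomal,
              mean_depth_per_tag = mean_depth_per_tag, error_rate = error_rate,
              sex_system = match.arg(sex_system),
              barcode_mismatch = barcode_mismatch,
              min_stack_depth = min_stack_depth,
              catalog_mismatch = catalog_mismatch,
              min_allele_depth = min_allele_depth,
              min_minor_ratio = min_minor_ratio,
              max_missing = max_missing, marker_prefix = marker_prefix,
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "radsex_config"
  cfg
}

#' Match catalog loci to simulated EcoRI tag sites
#'
#' For each non-repetitive catalog locus, finds the simulated site whose
#' reference 82-nt tag is within the catalog merge radius of the locus
#' reference consensus (exact match is tried first).
#'
#' @param catalog a [build_catalog()] result.
#' @param genome the [simulate_genome()] result.
#' @param max_mismatch match radius (default 2).
#' @return tibble `locus_id`, `site` (NA when unmatched).
#' @export
match_loci_to_sites <- function(catalog, genome, max_mismatch = 2L) {
  sites <- genome$ecoRI_sites[genome$ecoRI_sites + 83L <= genome$length]
  tags <- vapply(sites, function(s) reference_tag(genome, s), character(1))
  loci <- catalog$loci[!catalog$loci$repetitive, , drop = FALSE]
  hit <- match(loci$reference_consensus, tags)
  todo <- which(is.na(hit))
  for (i in todo) {
    d <- hamming(loci$reference_consensus[i], tags)
    j <- which(d <= max_mismatch)
    if (length(j) >= 1L) hit[i] <- j[which.min(d[j])]
  }
  tibble::tibble(locus_id = loci$locus_id, site = sites[hit])
}

#' Compare called genotypes with the simulation truth table
#'
#' For every planted variant, locates the corresponding catalog locus row
#' (via [match_loci_to_sites()]) and compares each individual's call with
#' the truth genotype; missing calls and unrecovered variants count as
#' discordant.
#'
#' @param geno a [call_genotypes()] result.
#' @param cross the [simulate_cross()] result.
#' @param locus_map [match_loci_to_sites()] output.
#' @return list: `per_variant` tibble (`variant_id`, `linkage`, `n_match`,
#'   `n_total`, `recovered`) and `concordance` (overall fraction of
#'   individual-by-variant cells matching truth).
#' @export
genotype_concordance <- function(geno, cross, locus_map) {
  calls <- geno$calls
  ids <- cross$pedigree$individual_id
  vars <- cross$variants
  per <- list()
  n_match <- 0L; n_total <- 0L
  for (i in seq_len(nrow(vars))) {
    s <- vars$site[i]; p <- vars$tag_pos[i]
    loci <- locus_map$locus_id[!is.na(locus_map$site) & locus_map$site == s]
    row <- calls[calls$locus_id %in% loci & calls$position == p, , drop = FALSE]
    truth_g <- unlist(cross$truth[cross$truth$variant_id == vars$variant_id[i], ids])
    if (nrow(row) == 1L) {
      got <- unlist(row[1, ids])
      ok <- !is_missing_call(got) & got == truth_g
    } else {
      ok <- rep(FALSE, length(ids))
    }
    per[[i]] <- tibble::tibble(
      variant_id = vars$variant_id[i], linkage = vars$linkage[i],
      n_match = sum(ok), n_total = length(ids),
      recovered = nrow(row) == 1L)
    n_match <- n_match + sum(ok); n_total <- n_total + length(ids)
  }
  per_variant <- if (length(per)) do.call(rbind, per) else
    tibble::tibble(variant_id = character(0), linkage = character(0),
                   n_match = integer(0), n_total = integer(0),
                   recovered = logical(0))
  list(per_variant = per_variant,
       concordance = if (n_total > 0) n_match / n_total else NA_real_)
}

#' Run the full simulate-to-screen pipeline
#'
#' Executes, in order: genome simulation, variant planting, cross
#' simulation, read simulation, demultiplexing, per-individual stack
#' building, catalog construction, genotyping, parent-polymorphism
#' filtering, the perfect sex-cosegregation screen, heterogamety inference,
#' truth-table evaluation and the per-individual summary table. Re-running
#' with the same configuration reproduces every output exactly.
#'
#' @param config a [radsex_config()].
#' @param quiet suppress per-stage progress messages.
#' @return list of class `radsex_run` with elements `config`, `genome`,
#'   `cross`, `manifest`, `sample_sheet`, `demux`, `stacks`, `catalog`,
#'   `genotypes`, `parent_filter`, `candidates`, `sex_system`,
#'   `locus_map`, `evaluation` (truth comparison), `summary` (tibble),
#'   `chance_probability`.
#' @export
run_radsex_pipeline <- function(config = radsex_config(), quiet = FALSE) {
  stopifnot(inherits(config, "radsex_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fastq <- if (is.null(outdir)) tempfile(fileext = ".fastq") else
    file.path(outdir, "reads.fastq")

  say("simulate: genome %d bp, %d EcoRI sites", config$genome_length,
      config$n_ecoRI_target)
  genome <- simulate_genome(config$genome_length, config$n_ecoRI_target,
                            config$sex_region_fraction,
                            seed = derive_seed(config$seed, 1L))
  variants <- plant_variants(genome, config$n_sex_linked, config$n_autosomal,
                             seed = derive_seed(config$seed, 2L))
  cross <- simulate_cross(genome, config$n_female, config$n_male, variants,
                          seed = derive_seed(config$seed, 3L),
                          sex_system = config$sex_system)
  barcodes <- make_mid_barcodes(cross$pedigree$individual_id,
                                seed = derive_seed(config$seed, 4L))
  params <- radsex_read_params(mean_depth_per_tag = config$mean_depth_per_tag,
                               error_rate = config$error_rate,
                               seed = derive_seed(config$seed, 5L))
  manifest <- simulate_reads(cross, genome, params, barcodes, fastq)
  say("simulate: %d reads -> %s", manifest$total_reads, fastq)
  sheet <- write_sample_sheet(cross$pedigree, barcodes,
                              if (is.null(outdir)) NULL else
                                file.path(outdir, "sample_sheet.tsv"))

  demux <- demultiplex(fastq, sheet,
                       barcode_mismatch = config$barcode_mismatch)
  if (sum(demux$counts$n_reads) == 0L) {
    stop("demultiplex: no reads assigned (empty or corrupt FASTQ input)")
  }
  say("demux: %d/%d reads assigned", sum(demux$counts$n_reads), demux$total)

  per_ind <- lapply(sheet$individual_id, function(id) {
    bs <- build_stacks(demux$reads[[id]],
                       min_stack_depth = config$min_stack_depth,
                       min_allele_depth = config$min_allele_depth,
                       min_minor_ratio = config$min_minor_ratio)
    if (nrow(bs$stacks) == 0L) return(NULL)
    list(stacks = cbind(tibble::tibble(individual_id = id), bs$stacks),
         alleles = tibble::tibble(individual_id = id,
                                  consensus = bs$alleles$allele,
                                  depth = bs$alleles$depth))
  })
  per_ind <- per_ind[!vapply(per_ind, is.null, logical(1))]
  stacks_all <- do.call(rbind, lapply(per_ind, `[[`, "stacks"))
  alleles_all <- do.call(rbind, lapply(per_ind, `[[`, "alleles"))
  say("stacks: %d stacks (%d alleles) across %d individuals",
      nrow(stacks_all), nrow(alleles_all),
      length(unique(stacks_all$individual_id)))

  catalog <- build_catalog(alleles_all, config$catalog_mismatch,
                           parent_ids = c("mother", "father"))
  say("catalog: %d loci (%d repetitive)", nrow(catalog$loci),
      sum(catalog$loci$repetitive))

  geno <- call_genotypes(catalog, sheet$individual_id,
                         config$min_allele_depth, config$min_minor_ratio)
  filt <- filter_parent_polymorphic(geno, "mother", "father")
  say("genotypes: %d variant rows, %d parent-polymorphic",
      nrow(geno$calls), nrow(filt$calls))

  sexes <- setNames(sheet$sex, sheet$individual_id)
  candidates <- screen_sex_association(filt$calls, sexes,
                                       max_missing = config$max_missing,
                                       catalog = catalog,
                                       marker_prefix = config$marker_prefix)
  system_call <- infer_sex_system(candidates)
  say("screen: %d candidates, system = %s", nrow(candidates),
      system_call$system)

  locus_map <- match_loci_to_sites(catalog, genome, config$catalog_mismatch)
  evaluation <- genotype_concordance(geno, cross, locus_map)

  summary_tbl <- pipeline_summary(demux, stacks_all, geno, sheet,
                                  genome$length)
  chance <- chance_cosegregation_probability(config$n_female, config$n_male)

  run <- structure(list(
    config = config, genome = genome, cross = cross, manifest = manifest,
    sample_sheet = sheet, demux = demux, stacks = stacks_all,
    catalog = catalog, genotypes = geno, parent_filter = filt,
    candidates = candidates, sex_system = system_call,
    locus_map = locus_map, evaluation = evaluation,
    summary = summary_tbl, chance_probability = chance),
    class = "radsex_run")
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

# Per-individual summary table for a pipeline run. "SNP" here counts the
# variant rows at which the individual carries a non-missing call differing
# from hom-reference or het; het rate is the share of het calls among them.
pipeline_summary <- function(demux, stacks_all, geno, sheet, genome_size) {
  rows <- lapply(sheet$individual_id, function(id) {
    reads <- demux$reads[[id]]
    joined <- paste(reads, collapse = "")
    bc <- c(A = 0, C = 0, G = 0, T = 0)
    for (b in names(bc)) bc[b] <- nchar(joined) - nchar(gsub(b, "", joined, fixed = TRUE))
    calls <- geno$calls[[id]]
    called <- calls[!is_missing_call(calls)]
    n_het <- sum(is_het_call(called))
    summarize_individual(
      id, read_number = length(reads),
      n_rad_tags = sum(stacks_all$individual_id == id),
      genome_size = genome_size, base_counts = bc,
      total_snp = length(called),
      het_snp_rate = if (length(called) > 0) 100 * n_het / length(called)
                     else NA_real_)
  })
  rows <- do.call(rbind, rows)
  radseq_summary_table(rows, sheet$sex)
}

write_run_outputs <- function(run, outdir) {
  write_tsv(run$stacks, file.path(outdir, "stacks.tsv"))
  loci <- run$catalog$loci
  loci$variant_positions <- vapply(loci$variant_positions, paste,
                                   character(1), collapse = ",")
  write_tsv(loci, file.path(outdir, "catalog_loci.tsv"))
  write_tsv(run$catalog$alleles, file.path(outdir, "catalog_alleles.tsv"))
  write_tsv(run$genotypes$calls, file.path(outdir, "genotypes.tsv"))
  write_tsv(run$genotypes$notes, file.path(outdir, "genotype_notes.tsv"))
  write_tsv(run$candidates, file.path(outdir, "sex_marker_candidates.tsv"))
  write_tsv(run$summary, file.path(outdir, "summary.tsv"))
  write_tsv(run$cross$truth, file.path(outdir, "truth.tsv"))
  manifest <- list(
    config = unclass(run$config),
    total_reads = run$manifest$total_reads,
    skipped_sites = run$manifest$skipped_sites,
    sex_system = unclass(run$sex_system),
    n_candidates = nrow(run$candidates),
    concordance = run$evaluation$concordance,
    chance_cosegregation_probability = run$chance_probability)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(outdir)
}

#' @export
print.radsex_run <- function(x, ...) {
  cat("radsex_run\n")
  cat(sprintf("  reads: %d  loci: %d  variant rows: %d\n",
              x$manifest$total_reads, nrow(x$catalog$loci),
              nrow(x$genotypes$calls)))
  cat(sprintf("  parent-polymorphic rows: %d  candidates: %d\n",
              nrow(x$parent_filter$calls), nrow(x$candidates)))
  cat(sprintf("  system: %s  truth concordance: %.4f\n",
              x$sex_system$system, x$evaluation$concordance))
  invisible(x)
}
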