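#' Plant sex-linked and autosomal variants on a simulated genome
#'
#' Chooses variant sites inside RAD tag windows so every planted SNP is
#' observable in the sequenced tags: sex-linked variants fall in tags inside
#' the sex-determining region, autosomal variants in tags outside it. At
#' most `max_per_tag` variants are placed per tag (alleles of one tag then
#' differ by at most 2 substitutions, within the clustering radius), and
#' positions 1-5 of the tag are avoided so the residual `AATTC` motif is
#' never mutated.
#'
#' @param genome a [simulate_genome()] result.
#' @param n_sex_linked,n_autosomal numbers of variants to plant.
#' @param seed RNG seed.
#' @param max_per_tag maximum planted variants per 82-nt tag (default 2).
#' @return tibble with columns `variant_id`, `genome_offset` (0-based),
#'   `ref`, `alt`, `linkage`, `site` (0-based EcoRI site offset), `tag_pos`
#'   (1-based position within the 82-nt tag).
#' @export
plant_variants <- function(genome, n_sex_linked, n_autosomal, seed,
                           max_per_tag = 2L) {
  stopifnot(inherits(genome, "sim_genome"), n_sex_linked >= 0, n_autosomal >= 0)
  set.seed(seed)
  sex_end <- genome$sex_region[2]
  in_region <- genome$ecoRI_sites[genome$ecoRI_sites + 83L <= sex_end]
  out_region <- genome$ecoRI_sites[genome$ecoRI_sites >= sex_end]

  pick <- function(sites, n, label) {
    if (n == 0L) return(NULL)
    if (n > length(sites) * max_per_tag) {
      stop("cannot place ", n, " ", label, " variants at <= ", max_per_tag,
           " per tag across ", length(sites), " tags")
    }
    # round-robin over shuffled tags so variants spread before doubling up
    tags <- rep(sample(sites), length.out = n)
    offs <- integer(n)
    used <- list()
    for (i in seq_len(n)) {
      s <- tags[i]
      taken <- used[[as.character(s)]]
      cand <- setdiff(6:82, taken)  # tag positions clear of the AATTC motif
      p <- sample(cand, 1)
      used[[as.character(s)]] <- c(taken, p)
      offs[i] <- s + p  # 0-based genome offset of 1-based tag position p
    }
    tibble::tibble(site = tags, genome_offset = offs, linkage = label)
  }
  vars <- rbind(pick(in_region, n_sex_linked, "sex_linked"),
                pick(out_region, n_autosomal, "autosomal"))
  if (is.null(vars)) {
    return(tibble::tibble(variant_id = character(0), genome_offset = integer(0),
                          ref = character(0), alt = character(0),
                          linkage = character(0), site = integer(0),
                          tag_pos = integer(0)))
  }
  vars <- vars[order(vars$genome_offset), ]
  vars$ref <- vapply(vars$genome_offset, function(o) {
    substr(genome$sequence, o + 1L, o + 1L)
  }, character(1))
  vars$alt <- vapply(vars$ref, function(r) sample(setdiff(BASES, r), 1),
                     character(1))
  vars$tag_pos <- tag_position(vars$site, vars$genome_offset)
  vars$variant_id <- sprintf("var%04d", seq_len(nrow(vars)))
  vars[, c("variant_id", "genome_offset", "ref", "alt", "linkage",
           "site", "tag_pos")]
}

#' Simulate a heterogametic cross with planted variants
#'
#' Builds the diploid haplotypes of two parents and their F1 progeny under a
#' female-heterogametic (ZW mother x ZZ father) or male-heterogametic
#' (XX mother x XY father) system. Sex-linked variants ride exclusively on
#' the W (or Y) haplotype, so every carrier-sex individual is heterozygous
#' and every other individual homozygous reference at those sites — the
#' signature the downstream screen detects. Autosomal variants segregate
#' Mendelianly from drawn parental genotypes; variants sharing a tag are
#' co-phased and co-inherited, while different tags assort independently
#' (free recombination between RAD loci outside the sex region).
#'
#' A ZW x ZZ cross cannot produce a WW individual, and the expected
#' progeny sex ratio is 1:1; with `balanced = TRUE` (default) the requested
#' sex counts are emitted exactly, mirroring a balanced sampling design.
#'
#' @param genome a [simulate_genome()] result.
#' @param n_female,n_male progeny counts (>= 1 each).
#' @param variants tibble from [plant_variants()].
#' @param seed RNG seed.
#' @param sex_system `"ZW"` (female heterogametic, default) or `"XY"`.
#' @param autosomal_scheme `"informative"` draws every autosomal tag as a
#'   pseudo-testcross configuration (mother het, father homozygous
#'   reference); `"random"` draws each parent het or homozygous reference
#'   independently (monomorphic draws are redrawn).
#' @param balanced emit exactly the requested sex counts (default); when
#'   `FALSE`, each progeny's sex is drawn with probability 1/2 and
#'   `n_female + n_male` is the brood size.
#' @return object of class `sim_cross`: list with `pedigree` (tibble:
#'   `individual_id`, `sex`, `role`, `karyotype`), `truth` (tibble: variant
#'   rows by individual genotype columns), `haplotypes` (per-individual
#'   `n_variants x 2` logical matrix of alt carriage), `variants`,
#'   `sex_system`, `seed`.
#' @export
simulate_cross <- function(genome, n_female, n_male, variants, seed,
                           sex_system = c("ZW", "XY"),
                           autosomal_scheme = c("informative", "random"),
                           balanced = TRUE) {
  sex_system <- match.arg(sex_system)
  autosomal_scheme <- match.arg(autosomal_scheme)
  stopifnot(inherits(genome, "sim_genome"), n_female >= 1, n_male >= 1)
  if (nrow(variants) > 0 &&
      any(variants$genome_offset < 0 | variants$genome_offset >= genome$length)) {
    stop("variant offset outside genome")
  }
  set.seed(seed)
  nv <- nrow(variants)
  het_parent <- if (sex_system == "ZW") "mother" else "father"

  # Parent karyotypes; haplotype 2 of the heterogametic parent is the
  # sex-limited chromosome (W or Y) carrying every sex-linked alt allele.
  mother_kt <- if (sex_system == "ZW") "ZW" else "XX"
  father_kt <- if (sex_system == "ZW") "ZZ" else "XY"
  stopifnot(mother_kt != "WW", father_kt != "WW")

  if (balanced) {
    progeny_sex <- c(rep("female", n_female), rep("male", n_male))
  } else {
    progeny_sex <- sample(c("female", "male"), n_female + n_male,
                          replace = TRUE)
  }
  progeny_ids <- sprintf("F1-%02d", seq_along(progeny_sex))
  pedigree <- tibble::tibble(
    individual_id = c("mother", "father", progeny_ids),
    sex = c("female", "male", progeny_sex),
    role = c(rep("parent", 2), rep("progeny", length(progeny_ids))),
    karyotype = c(mother_kt, father_kt,
                  ifelse(progeny_sex == "female",
                         if (sex_system == "ZW") "ZW" else "XX",
                         if (sex_system == "ZW") "ZZ" else "XY"))
  )
  stopifnot(!any(pedigree$karyotype == "WW"))

  new_hap <- function() matrix(FALSE, nrow = nv, ncol = 2)
  H <- setNames(lapply(pedigree$individual_id, function(i) new_hap()),
                pedigree$individual_id)

  is_sex <- variants$linkage == "sex_linked"
  H[[het_parent]][is_sex, 2] <- TRUE

  # Autosomal parental genotypes, drawn per tag so shared-tag variants stay
  # in phase.
  auto_tags <- unique(variants$site[!is_sex])
  for (s in auto_tags) {
    idx <- which(!is_sex & variants$site == s)
    repeat {
      if (autosomal_scheme == "informative") {
        m_het <- TRUE; f_het <- FALSE
      } else {
        m_het <- runif(1) < 0.5; f_het <- runif(1) < 0.5
      }
      if (m_het || f_het) break
    }
    if (m_het) H[["mother"]][idx, sample(2, 1)] <- TRUE
    if (f_het) H[["father"]][idx, sample(2, 1)] <- TRUE
  }

  # Progeny inheritance: haplotype 1 maternal, haplotype 2 paternal.
  sex_tags <- unique(variants$site[is_sex])
  for (k in seq_along(progeny_ids)) {
    id <- progeny_ids[k]
    sx <- progeny_sex[k]
    for (s in unique(variants$site)) {
      idx <- which(variants$site == s)
      sexual <- s %in% sex_tags
      if (sexual) {
        if (sex_system == "ZW") {
          m_hap <- if (sx == "female") 2L else 1L  # W passes only to daughters
          p_hap <- sample(2, 1)
        } else {
          m_hap <- sample(2, 1)
          p_hap <- if (sx == "male") 2L else 1L    # Y passes only to sons
        }
      } else {
        m_hap <- sample(2, 1)
        p_hap <- sample(2, 1)
      }
      H[[id]][idx, 1] <- H[["mother"]][idx, m_hap]
      H[[id]][idx, 2] <- H[["father"]][idx, p_hap]
    }
  }

  truth <- variants[, c("variant_id", "genome_offset", "linkage", "ref", "alt")]
  for (id in pedigree$individual_id) {
    dose <- rowSums(H[[id]])
    a1 <- ifelse(dose >= 1, variants$alt, variants$ref)
    a2 <- ifelse(dose == 2, variants$alt, variants$ref)
    truth[[id]] <- genotype_string(pmin(a1, a2), pmax(a1, a2))
  }

  # Sex-linkage invariant: carrier-sex het, other-sex homozygous reference.
  if (any(is_sex)) {
    carrier <- if (sex_system == "ZW") "female" else "male"
    for (id in pedigree$individual_id) {
      g <- truth[[id]][is_sex]
      if (pedigree$sex[pedigree$individual_id == id] == carrier) {
        stopifnot(all(is_het_call(g)))
      } else {
        ref <- variants$ref[is_sex]
        stopifnot(all(g == paste(ref, ref, sep = "/")))
      }
    }
  }

  structure(list(pedigree = pedigree, truth = truth, haplotypes = H,
                 variants = variants, sex_system = sex_system,
                 seed = as.integer(seed)),
            class = "sim_cross")
}

#' @export
print.sim_cross <- function(x, ...) {
  cat(sprintf("sim_cross (%s): %d progeny (%d female, %d male), %d variants (%d sex-linked)\n",
              x$sex_system, sum(x$pedigree$role == "progeny"),
              sum(x$pedigree$sex == "female" & x$pedigree$role == "progeny"),
              sum(x$pedigree$sex == "male" & x$pedigree$role == "progeny"),
              nrow(x$variants), sum(x$variants$linkage == "sex_linked")))
  invisible(x)
}
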