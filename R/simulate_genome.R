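ECORI_SITE <- "GAATTC"

#' Simulate a genome with planted EcoRI sites and a sex-determining region
#'
#' Generates a random haploid reference of the requested length, plants
#' `n_ecoRI_target` EcoRI recognition sites (`GAATTC`) at controlled,
#' non-overlapping positions, and designates a non-recombining
#' sex-determining region at the start of the sequence covering
#' `sex_region_fraction` of its length. Sites are planted rather than left
#' to base composition so the number of RAD loci is controllable; accidental
#' `GAATTC` occurrences in the background sequence are mutated away. Sites
#' are spaced so that every tag window (82 nt downstream of the cut) is
#' complete and free of other sites.
#'
#' @param length genome length in nucleotides (>= 10,000).
#' @param n_ecoRI_target number of EcoRI sites to plant.
#' @param sex_region_fraction fraction of the genome, in (0, 0.5), assigned
#'   to the sex-determining region.
#' @param seed RNG seed, recorded in the result.
#' @param min_loci minimum number of sites required both inside and outside
#'   the sex region (error if unsatisfiable).
#' @return an object of class `sim_genome`: list with `sequence`, `length`,
#'   `ecoRI_sites` (0-based offsets of `GAATTC`), `sex_region` (0-based
#'   half-open `c(start, end)`), and `seed`.
#' @export
#' @examples
#' g <- simulate_genome(20000, 12, 0.25, seed = 1)
#' length(g$ecoRI_sites)
simulate_genome <- function(length, n_ecoRI_target, sex_region_fraction,
                            seed, min_loci = 3L) {
  stopifnot(length >= 10000, sex_region_fraction > 0, sex_region_fraction < 0.5)
  if (n_ecoRI_target < 2 * min_loci) {
    stop("n_ecoRI_target must allow at least `min_loci` sites on each side ",
         "of the sex region")
  }
  spacing <- 100L  # site + full 82-nt tag window + margin
  if (n_ecoRI_target * spacing > 0.8 * length) {
    stop("unsatisfiable EcoRI site placement: ", n_ecoRI_target,
         " sites cannot be spaced ", spacing, " bp apart in ", length, " bp")
  }
  set.seed(seed)
  sex_end <- floor(length * sex_region_fraction)

  # Allocate sites to the two compartments proportionally, honouring min_loci.
  n_in <- max(min_loci, round(n_ecoRI_target * sex_region_fraction))
  n_out <- n_ecoRI_target - n_in
  if (n_out < min_loci) stop("too few sites outside the sex region")

  place_sites <- function(lo, hi, n) {
    # lo/hi: 0-based half-open window for site starts; sites need 82 nt of
    # downstream sequence after the G, i.e. start + 83 <= genome length.
    usable <- (hi - lo) - spacing
    if (usable < n * spacing) stop("unsatisfiable site placement in compartment")
    # spaced lattice with small jitter keeps every inter-site gap > the
    # 83-nt site-plus-tag footprint, so tag windows never contain a second
    # site and never run off the compartment
    lattice <- lo + floor(seq(0, usable - spacing, length.out = n))
    jitter <- floor(runif(n, 0, 10))
    pmin(lattice + jitter, hi - spacing)
  }
  sites_in <- place_sites(0L, sex_end, n_in)
  sites_out <- place_sites(sex_end, length - spacing, n_out)
  sites <- sort(c(sites_in, sites_out))

  seq_chars <- sample(BASES, length, replace = TRUE)
  for (s in sites) seq_chars[(s + 1):(s + 6)] <- c("G", "A", "A", "T", "T", "C")
  sequence <- paste(seq_chars, collapse = "")

  # Remove accidental GAATTC occurrences outside the planted set.
  for (pass in 1:10) {
    occ <- gregexpr(ECORI_SITE, sequence, fixed = TRUE)[[1]]
    occ <- if (occ[1] == -1) integer(0) else as.integer(occ) - 1L
    stray <- setdiff(occ, sites)
    if (length(stray) == 0L) break
    for (s in stray) {
      # mutate the G; avoid recreating a site by choosing a non-G base
      substr(sequence, s + 1L, s + 1L) <- sample(c("A", "C", "T"), 1)
    }
  }
  occ <- gregexpr(ECORI_SITE, sequence, fixed = TRUE)[[1]]
  occ <- if (occ[1] == -1) integer(0) else as.integer(occ) - 1L
  if (!setequal(occ, sites)) stop("failed to stabilise planted EcoRI sites")

  structure(list(
    sequence = sequence,
    length = as.integer(length),
    ecoRI_sites = as.integer(sites),
    sex_region = c(0L, as.integer(sex_end)),
    seed = as.integer(seed)
  ), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  n_in <- sum(x$ecoRI_sites >= x$sex_region[1] & x$ecoRI_sites < x$sex_region[2])
  cat(sprintf(
    "sim_genome: %s bp, %d EcoRI sites (%d in sex region [%d, %d)), seed %d\n",
    format(x$length, big.mark = ","), length(x$ecoRI_sites), n_in,
    x$sex_region[1], x$sex_region[2], x$seed))
  invisible(x)
}

# 0-based tag window for a site offset s: genome[s+2 .. s+83] in 1-based
# substr coordinates, i.e. the 82 nt starting at the A after the cut G.
tag_window <- function(site) c(start = site + 2L, end = site + 83L)

# Extract the 82-nt reference tag downstream of a site (1-based substr).
reference_tag <- function(genome, site) {
  w <- tag_window(site)
  if (w["end"] > genome$length) return(NA_character_)
  substr(genome$sequence, w["start"], w["end"])
}

# Which site's tag window contains a 0-based genome offset; NA if none.
site_for_offset <- function(genome, offset) {
  for (s in genome$ecoRI_sites) {
    w <- tag_window(s)
    pos1 <- offset + 1L  # 1-based genome coordinate
    if (pos1 >= w["start"] && pos1 <= w["end"]) return(s)
  }
  NA_integer_
}

# 1-based position within the tag (1 = leading A of AATTC) of a 0-based
# genome offset lying in the tag window of `site`.
tag_position <- function(site, offset) {
  as.integer(offset + 1L - (site + 2L) + 1L)
}
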