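#' @importFrom stats rpois rbinom runif setNames aggregate
#' @importFrom utils write.table
NULL

BASES <- c("A", "C", "G", "T")

# Tag geometry: an EcoRI cut (G/AATTC) leaves reads that, after barcode
# removal, start with the 5-nt residual motif and run 82 nt in total.
TAG_LENGTH <- 82L
RESIDUAL_MOTIF <- "AATTC"
MID_LENGTH <- 8L

#' Round half away from zero to a fixed number of decimals
#'
#' Conventional "half-up" rounding (0.5 always rounds away from zero), as
#' used when printing coverage ratios to one decimal. Base `round()` rounds
#' half to even, which differs at exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Hamming distance between equal-length sequences
#'
#' Number of positions at which two strings differ. Used both for grouping
#' reads into tag stacks (radius 2 within individuals) and for matching
#' stack consensi across individuals into catalog loci.
#'
#' @param a,b character scalars (or equal-length vectors, compared pairwise)
#'   of identical nchar.
#' @return integer vector of mismatch counts.
#' @export
#' @examples
#' hamming("AATTC", "AATTC")
#' hamming("AATTCG", "AATTCT")
hamming <- function(a, b) {
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("`a` and `b` must have matching lengths")
  }
  if (any(nchar(a) != nchar(b))) {
    stop("hamming distance requires equal-length sequences")
  }
  mapply(function(x, y) {
    sum(charToRaw(x) != charToRaw(y))
  }, a, b, USE.NAMES = FALSE)
}

# Unique sequences as an integer matrix (one row per sequence, one column
# per position); the workhorse encoding for bulk distance computations.
seq_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  w <- nchar(seqs[1])
  matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = n, ncol = w, byrow = TRUE)
}

# Hamming distances from row `i` of an integer sequence matrix to rows `idx`.
row_hamming <- function(mat, i, idx) {
  if (length(idx) == 0L) return(integer(0))
  ref <- mat[i, ]
  if (length(idx) == 1L) return(sum(mat[idx, ] != ref))
  rowSums(mat[idx, , drop = FALSE] != matrix(ref, nrow = length(idx),
                                             ncol = length(ref), byrow = TRUE))
}

# Random DNA of a given length from a supplied RNG stream.
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Derive a per-stage seed from the run seed; keeps all values < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}

# Sorted diploid genotype string, e.g. "A/G"; missing is "./.".
genotype_string <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), "./.",
         paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
}

is_het_call <- function(g) {
  !is.na(g) & g != "./." & substr(g, 1, 1) != substr(g, 3, 3)
}

is_missing_call <- function(g) {
  is.na(g) | g == "./."
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
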