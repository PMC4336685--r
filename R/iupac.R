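IUPAC_PAIRS <- c(
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M"
)

#' IUPAC ambiguity code for a heterozygous base pair
#'
#' Returns the single-letter ambiguity code for an unordered pair of distinct
#' bases (R = A/G, Y = C/T, S = G/C, W = A/T, K = G/T, M = A/C), the standard
#' shorthand for reporting heterozygous SNP genotypes.
#'
#' @param b1,b2 single bases in `A`, `C`, `G`, `T`; order is irrelevant.
#' @return one-letter character code.
#' @export
#' @examples
#' iupac_code("C", "A")  # "M"
#' iupac_code("T", "A")  # "W"
iupac_code <- function(b1, b2) {
  b1 <- toupper(b1); b2 <- toupper(b2)
  stopifnot(all(b1 %in% BASES), all(b2 %in% BASES))
  if (any(b1 == b2)) stop("IUPAC ambiguity codes require two distinct bases")
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  unname(IUPAC_PAIRS[key])
}
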