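# Standard genetic code, fixed at build time. Codons are ordered with the
# first base cycling slowest over T, C, A, G so the amino-acid string below
# is the classical 64-letter translation table.

.CODON_BASES <- c("T", "C", "A", "G")

.CODONS64 <- paste0(
  rep(.CODON_BASES, each = 16L),
  rep(rep(.CODON_BASES, each = 4L), times = 4L),
  rep(.CODON_BASES, times = 16L)
)

.AA64 <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
)[[1L]]
names(.AA64) <- .CODONS64

STOP_CODONS <- c("TAA", "TAG", "TGA")

SENSE_CODONS <- .CODONS64[.AA64 != "*"]
AA_OF_CODON <- .AA64[SENSE_CODONS]

# synonymous family structure
.FAMILY_LIST <- split(SENSE_CODONS, AA_OF_CODON)
FAMILY_SIZE_AA <- vapply(.FAMILY_LIST, length, integer(1L))
FAMILY_SIZE_CODON <- FAMILY_SIZE_AA[AA_OF_CODON]
names(FAMILY_SIZE_CODON) <- SENSE_CODONS

# the 59 codons of families with >= 2 members (drops ATG and TGG)
SYN_CODONS <- SENSE_CODONS[FAMILY_SIZE_CODON >= 2L]

.THIRD_BASE <- substring(SENSE_CODONS, 3L, 3L)
names(.THIRD_BASE) <- SENSE_CODONS

.CODON_GC <- vapply(strsplit(SENSE_CODONS, ""), function(b) {
  sum(b %in% c("G", "C"))
}, integer(1L))
names(.CODON_GC) <- SENSE_CODONS

# Kyte-Doolittle hydropathy
.KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

.AROMATIC_AA <- c("F", "Y", "W")

#' The standard genetic code table
#'
#' Returns the standard nuclear genetic code as a data frame, one row per
#' codon, with the encoded amino acid (one-letter code, `"*"` for the three
#' stop codons) and the size of the synonymous family the codon belongs to.
#' Codons whose family size is at least 2 are the 59 "synonymous" codons
#' used for RSCU matrices and third-position composition indices; ATG (Met)
#' and TGG (Trp) are single-codon families.
#'
#' @return A data frame with columns `codon`, `aa`, `family_size` (NA for
#'   stop codons) and `synonymous` (logical, family size >= 2).
#' @examples
#' gc <- genetic_code_table()
#' sum(gc$aa != "*")     # 61 sense codons
#' sum(gc$synonymous)    # 59 synonymous codons
#' @export
genetic_code_table <- function() {
  fs <- rep(NA_integer_, 64L)
  names(fs) <- .CODONS64
  fs[SENSE_CODONS] <- FAMILY_SIZE_CODON
  data.frame(
    codon = .CODONS64,
    aa = unname(.AA64),
    family_size = unname(fs),
    synonymous = .CODONS64 %in% SYN_CODONS,
    stringsAsFactors = FALSE
  )
}

.check_codons <- function(codon) {
  bad <- !codon %in% .CODONS64
  if (any(bad)) {
    stop("invalid or ambiguous codon(s): ",
         paste(unique(codon[bad]), collapse = ", "))
  }
  invisible(codon)
}

#' Watson-Crick hydrogen bonds of a codon
#'
#' An A:T pair contributes two hydrogen bonds and a G:C pair three, so a
#' codon carries between 6 (e.g. AAA) and 9 (e.g. GCG) bonds.
#'
#' @param codon Character vector of codons over A/C/G/T.
#' @return Integer vector in 6..9.
#' @examples
#' hbonds_per_codon(c("AAA", "ATG", "GCG"))
#' @export
hbonds_per_codon <- function(codon) {
  codon <- toupper(codon)
  .check_codons(codon)
  n_gc <- vapply(strsplit(codon, ""), function(b) sum(b %in% c("G", "C")),
                 integer(1L))
  6L + n_gc
}

#' Classify codons as cheap or expensive
#'
#' Codons with 6 or 7 hydrogen bonds are "cheap", codons with 8 or 9 are
#' "expensive". Exactly half of the 64 codons fall in each class.
#'
#' @param codon Character vector of codons.
#' @return Character vector, `"cheap"` or `"expensive"`.
#' @examples
#' classify_codon_cost(c("ATG", "TGC"))
#' @export
classify_codon_cost <- function(codon) {
  hb <- hbonds_per_codon(codon)
  ifelse(hb <= 7L, "cheap", "expensive")
}
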