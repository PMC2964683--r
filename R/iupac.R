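# IUPAC nucleotide codes and their expansions to unambiguous bases
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

AMBIGUITY_CODES <- c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N")

.IUPAC_FROM <- "ACGTMRWSYKVHDBN"
.IUPAC_TO   <- "TGCAKYWSRMBDHVN"

# IUPAC code whose expansion is exactly the given allele set
.code_for_alleles <- function(alleles) {
  alleles <- sort(unique(alleles))
  for (code in names(IUPAC_EXPANSION)) {
    if (identical(sort(IUPAC_EXPANSION[[code]]), alleles)) return(code)
  }
  stop("no IUPAC code for allele set: ", paste(alleles, collapse = "/"),
       call. = FALSE)
}

.complement_base <- function(x) {
  chartr(.IUPAC_FROM, .IUPAC_TO, x)
}

#' Reverse complement of a nucleotide string
#'
#' Complements every base (including IUPAC ambiguity codes, e.g. M <-> K)
#' and reverses the result, so the returned string reads 5' to 3' on the
#' opposite strand.
#'
#' @param s A single nucleotide string over the IUPAC alphabet.
#' @return The reverse complement as a single string.
#' @examples
#' reverse_complement("ACGT")  # "ACGT" (self reverse-complementary)
#' reverse_complement("ACM")   # "KGT"
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- toupper(s)
  ch <- .chars(s)
  bad <- !(ch %in% names(IUPAC_EXPANSION))
  if (any(bad))
    stop(sprintf("invalid nucleotide code '%s' at position %d",
                 ch[which(bad)[1L]], which(bad)[1L]), call. = FALSE)
  paste(rev(.chars(chartr(.IUPAC_FROM, .IUPAC_TO, s))), collapse = "")
}
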