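#' Dimer screen for a primer or primer pair
#'
#' Slides the two 5'->3' sequences over every antiparallel ungapped
#' alignment and flags a dimer when the longest run of Watson-Crick
#' complementary pairs reaches `stem_min`, or `end_min` when the run
#' includes either primer's 3'-terminal base (3'-anchored duplexes extend
#' during PCR, so a shorter clamp already matters there).  With `q`
#' omitted the primer is screened against itself (self-dimer).
#'
#' @param p,q Primer strings (A/C/G/T only), 5' to 3'.
#' @param stem_min,end_min Run-length thresholds (bases).
#' @return `TRUE` if a dimer is found.
#' @export
dimer_screen <- function(p, q = p, stem_min = 5L, end_min = 3L) {
  dimer_hit_cpp(.encode_dna(toupper(p)), .encode_dna(toupper(q)),
                as.integer(stem_min), as.integer(end_min))
}

#' Hairpin screen for a primer
#'
#' Flags a hairpin when some window of `stem_min` bases is the antiparallel
#' complement of a downstream window separated by a loop of at least
#' `loop_min` unpaired bases.
#'
#' @param p Primer string (A/C/G/T only), 5' to 3'.
#' @param stem_min,loop_min Minimal stem and loop lengths (bases).
#' @return `TRUE` if a hairpin is found.
#' @export
hairpin_screen <- function(p, stem_min = 4L, loop_min = 3L) {
  hairpin_hit_cpp(.encode_dna(toupper(p)),
                  as.integer(stem_min), as.integer(loop_min))
}
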