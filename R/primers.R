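#' Check a chromosome vector for hard feasibility on a template
#'
#' A chromosome `(Fl1, Pl1, Rl1, Fl2, Pl2, Rl2)` is feasible when all four
#' primer lengths lie within the configured bounds, both product genes are
#' at least the product floor (and inside any explicit range restriction),
#' every primer window fits on the template, the outer forward primer lies
#' strictly upstream and the outer reverse primer strictly downstream of
#' the SNP, and no excluded primer window covers an extra polymorphic site.
#'
#' @param template A `ctpp_template`.
#' @param v Numeric vector of six genes `(Fl1, Pl1, Rl1, Fl2, Pl2, Rl2)`.
#' @param cfg A [constraint_config()].
#' @return `TRUE`, or a character scalar describing the violated condition.
#' @export
vector_feasible <- function(template, v, cfg = constraint_config()) {
  if (length(v) != 6L || anyNA(v)) return("chromosome must be six integers")
  v <- as.integer(round(v))
  Fl1 <- v[1L]; Pl1 <- v[2L]; Rl1 <- v[3L]
  Fl2 <- v[4L]; Pl2 <- v[5L]; Rl2 <- v[6L]
  s <- template$snp_index; L <- template$length
  lens <- v[c(1L, 3L, 4L, 6L)]
  if (any(lens < cfg$len_min | lens > cfg$len_max))
    return("primer length outside configured bounds")
  if (Pl1 < cfg$product_min || Pl2 < cfg$product_min)
    return("product length below the configured minimum")
  if (!is.null(cfg$pl1_range) &&
      (Pl1 < cfg$pl1_range[1L] || Pl1 > cfg$pl1_range[2L]))
    return("product 1 length outside its configured range")
  if (!is.null(cfg$pl2_range) &&
      (Pl2 < cfg$pl2_range[1L] || Pl2 > cfg$pl2_range[2L]))
    return("product 2 length outside its configured range")
  if (s + Rl1 - 1L > L)
    return("reverse primer 1 window extends past the template end")
  if (Pl1 > s + Rl1 - 1L)
    return("product 1 extends past the template start")
  if (Pl1 < Fl1 + Rl1)
    return("product 1 cannot host both primers with pf1 upstream of the SNP")
  if (Fl2 > s)
    return("forward primer 2 window extends past the template start")
  if (Pl2 > L - s + Fl2)
    return("product 2 extends past the template end")
  if (Pl2 < Fl2 + Rl2)
    return("product 2 cannot host both primers with pr2 downstream of the SNP")
  E <- template$extra_snp_indices
  if (length(E)) {
    Fs1 <- s + Rl1 - Pl1; Fe1 <- Fs1 + Fl1 - 1L
    Rs2 <- s - Fl2 + Pl2; Re2 <- Rs2 - Rl2 + 1L
    if (any(E >= Fs1 & E <= Fe1))
      return("forward primer 1 window contains an extra SNP")
    if (any(E >= Re2 & E <= Rs2))
      return("reverse primer 2 window contains an extra SNP")
    if (cfg$extra_snp_strict) {
      if (any(E >= s - Fl2 + 1L & E <= s))
        return("forward primer 2 window contains an extra SNP")
      if (any(E >= s & E <= s + Rl1 - 1L))
        return("reverse primer 1 window contains an extra SNP")
    }
  }
  TRUE
}

#' Length of the outer PCR product from the confronting-primer geometry
#'
#' The two inner primers both terminate on the SNP, so the outer product
#' (outer forward with outer reverse primer) overlaps the two short
#' products and its length follows the identity
#' `Pl3 = Pl1 + Pl2 - Rl1 - Fl2 + 1`.
#'
#' @param pl1,pl2 Lengths of the two allele-specific products (bases).
#' @param rl1 Length of the inner reverse primer (bases).
#' @param fl2 Length of the inner forward primer (bases).
#' @return The outer product length in bases.
#' @examples
#' product3_length(228, 105, 20, 20)  # 294
#' @export
product3_length <- function(pl1, pl2, rl1, fl2) {
  pl1 + pl2 - rl1 - fl2 + 1
}

#' Realize a chromosome vector into four concrete primers
#'
#' Maps the six-gene chromosome onto the template: the inner reverse primer
#' `pr1` occupies `[snp, snp + Rl1 - 1]` and carries the complement of the
#' minor allele at its 3' end; the inner forward primer `pf2` occupies
#' `[snp - Fl2 + 1, snp]` and carries the major allele at its 3' end; the
#' outer primers close products of lengths `Pl1` (ending at pr1's 5' end)
#' and `Pl2` (starting at pf2's 5' end).  Reverse primers are returned 5'
#' to 3' in priming orientation (reverse complement of their template
#' window).
#'
#' Coordinates are reported 1-based inclusive; for reverse primers `start`
#' is the 5' (template-downstream) position and `end` the 3' position, so
#' `end` of pr1 is the SNP itself.
#'
#' @inheritParams vector_feasible
#' @return An object of class `ctpp_primer_set` with elements `pf1`, `pr1`,
#'   `pf2`, `pr2`, `coords` (named list `Fs1, Fe1, Rs1, Re1, Fs2, Fe2, Rs2,
#'   Re2`), `products` (`c(Pl1, Pl2, Pl3)`), `vector`, and the allele
#'   annotations.
#' @export
realize_primer_set <- function(template, v, cfg = constraint_config()) {
  feas <- vector_feasible(template, v, cfg)
  if (!isTRUE(feas)) stop(feas, call. = FALSE)
  v <- as.integer(round(v))
  Fl1 <- v[1L]; Pl1 <- v[2L]; Rl1 <- v[3L]
  Fl2 <- v[4L]; Pl2 <- v[5L]; Rl2 <- v[6L]
  s <- template$snp_index

  Fs1 <- s + Rl1 - Pl1; Fe1 <- Fs1 + Fl1 - 1L
  Rs1 <- s + Rl1 - 1L; Re1 <- s            # primer orientation: start = 5'
  Fs2 <- s - Fl2 + 1L; Fe2 <- s
  Rs2 <- s - Fl2 + Pl2; Re2 <- Rs2 - Rl2 + 1L

  pf1 <- substr(template$sequence, Fs1, Fe1)
  pf2 <- substr(template$sequence_major, Fs2, Fe2)
  pr1 <- reverse_complement(substr(template$sequence_minor, Re1, Rs1))
  pr2 <- reverse_complement(substr(template$sequence, Re2, Rs2))

  # extra ambiguity codes may survive inside inner windows when the strict
  # exclusion is disabled; resolve each to its first expansion
  resolve <- function(p) {
    ch <- .chars(p)
    amb <- ch %in% AMBIGUITY_CODES
    if (any(amb)) {
      warning("ambiguity code inside a primer window resolved to its first ",
              "expansion", call. = FALSE)
      ch[amb] <- vapply(ch[amb], function(x) IUPAC_EXPANSION[[x]][1L], "")
      p <- paste(ch, collapse = "")
    }
    p
  }
  pf1 <- resolve(pf1); pf2 <- resolve(pf2)
  pr1 <- resolve(pr1); pr2 <- resolve(pr2)

  stopifnot(substr(pf2, Fl2, Fl2) == template$allele_major,
            substr(pr1, Rl1, Rl1) == .complement_base(template$allele_minor))

  structure(list(
    pf1 = pf1, pr1 = pr1, pf2 = pf2, pr2 = pr2,
    coords = list(Fs1 = Fs1, Fe1 = Fe1, Rs1 = Rs1, Re1 = Re1,
                  Fs2 = Fs2, Fe2 = Fe2, Rs2 = Rs2, Re2 = Re2),
    products = c(Pl1 = Pl1, Pl2 = Pl2,
                 Pl3 = as.integer(product3_length(Pl1, Pl2, Rl1, Fl2))),
    vector = v,
    allele_major = template$allele_major,
    allele_minor = template$allele_minor
  ), class = "ctpp_primer_set")
}

#' @export
print.ctpp_primer_set <- function(x, ...) {
  cat(sprintf("CTPP primer set (alleles %s/%s):\n",
              x$allele_major, x$allele_minor))
  co <- x$coords
  cat(sprintf("  Pf1 5'-%s-3'  +  %d..%d\n", x$pf1, co$Fs1, co$Fe1))
  cat(sprintf("  Pr1 5'-%s-3'  -  %d..%d\n", x$pr1, co$Rs1, co$Re1))
  cat(sprintf("  Pf2 5'-%s-3'  +  %d..%d\n", x$pf2, co$Fs2, co$Fe2))
  cat(sprintf("  Pr2 5'-%s-3'  -  %d..%d\n", x$pr2, co$Rs2, co$Re2))
  cat(sprintf("  products: %d / %d / %d bp\n",
              x$products[1L], x$products[2L], x$products[3L]))
  invisible(x)
}
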