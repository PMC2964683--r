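#' Parse a SNP-flanked template sequence
#'
#' Accepts either a plain IUPAC-coded sequence in which one ambiguity code
#' marks the SNP to genotype (`"ACGMTGA"`), or the bracket dialect common to
#' dbSNP flank exports (`"ACG[A/C]TGA"`).  In the IUPAC dialect the first
#' ambiguity code is taken as the defined SNP and any further ambiguity
#' positions are recorded as extra polymorphic sites; in the bracket dialect
#' the single `[X/Y]` token marks the SNP and maps to the corresponding
#' IUPAC code.
#'
#' Insertion/deletion alleles (`[-/A]`) and multi-nucleotide alleles are
#' rejected: only true single-nucleotide substitutions are supported.
#'
#' @param text A single flank string (whitespace is ignored).
#' @param dialect `"auto"` (default; bracket if a `[` is present),
#'   `"iupac"`, or `"bracket"`.
#' @param alleles Optional `c(major, minor)` allele pair, both members of
#'   the IUPAC expansion at the SNP.  If omitted the first two expansions in
#'   alphabetical order are used, with a warning, since flank exports do not
#'   record allele frequencies.
#' @param id Optional design identifier carried into reports.
#' @return An object of class `ctpp_template`: a list with elements
#'   `sequence`, `length`, `snp_index` (1-based), `allele_major`,
#'   `allele_minor`, `extra_snp_indices`, and the two allele-resolved
#'   sequences `sequence_major` / `sequence_minor`.
#' @examples
#' parse_template("ACG[A/C]TGA", alleles = c("A", "C"))
#' parse_template("AMGRT", dialect = "iupac", alleles = c("A", "C"))
#' @export
parse_template <- function(text, dialect = c("auto", "iupac", "bracket"),
                           alleles = NULL, id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  dialect <- match.arg(dialect)
  text <- toupper(gsub("[[:space:]]", "", text))
  if (!nzchar(text)) stop("empty template sequence", call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("[", text, fixed = TRUE)) "bracket" else "iupac"

  if (dialect == "bracket") {
    m <- gregexpr("\\[[^][]*\\]", text)[[1L]]
    if (m[1L] == -1L)
      stop("bracket dialect requires one [X/Y] allele token", call. = FALSE)
    if (length(m) > 1L)
      stop("multiple [X/Y] tokens found; exactly one defined SNP is supported",
           call. = FALSE)
    token <- substr(text, m[1L] + 1L, m[1L] + attr(m, "match.length")[1L] - 2L)
    alls <- strsplit(token, "/", fixed = TRUE)[[1L]]
    if (any(alls == "-" | nchar(alls) != 1L))
      stop("insertion/deletion and multi-nucleotide alleles are not supported",
           call. = FALSE)
    if (!all(alls %in% c("A", "C", "G", "T")))
      stop("bracket alleles must be A, C, G or T", call. = FALSE)
    alls <- sort(unique(alls))
    if (length(alls) < 2L)
      stop("the allele token must list at least two distinct alleles",
           call. = FALSE)
    code <- .code_for_alleles(alls)
    pre <- substr(text, 1L, m[1L] - 1L)
    post <- substr(text, m[1L] + attr(m, "match.length")[1L], nchar(text))
    seqchr <- paste0(pre, code, post)
    snp_index <- nchar(pre) + 1L
  } else {
    if (grepl("[", text, fixed = TRUE))
      stop("bracket token found in iupac-dialect input", call. = FALSE)
    seqchr <- text
    snp_index <- NA_integer_  # resolved below from the first ambiguity
  }

  ch <- .chars(seqchr)
  bad <- !(ch %in% names(IUPAC_EXPANSION))
  if (any(bad))
    stop(sprintf("invalid nucleotide code '%s' at position %d",
                 ch[which(bad)[1L]], which(bad)[1L]), call. = FALSE)
  amb <- which(ch %in% AMBIGUITY_CODES)
  if (is.na(snp_index)) {
    if (length(amb) == 0L)
      stop("no IUPAC ambiguity code found; the defined SNP must be marked",
           call. = FALSE)
    snp_index <- amb[1L]
  }
  extra <- setdiff(amb, snp_index)

  expansion <- IUPAC_EXPANSION[[ch[snp_index]]]
  if (length(expansion) < 2L)
    stop("the defined SNP position is not polymorphic", call. = FALSE)
  if (is.null(alleles)) {
    alleles <- sort(expansion)[1:2]
    warning(sprintf(
      "allele order not given; assuming major=%s, minor=%s (alphabetical)",
      alleles[1L], alleles[2L]), call. = FALSE)
  }
  alleles <- toupper(alleles)
  if (length(alleles) != 2L || alleles[1L] == alleles[2L] ||
      !all(alleles %in% expansion))
    stop("alleles must be two distinct members of the IUPAC expansion at ",
         "the SNP (", paste(expansion, collapse = "/"), ")", call. = FALSE)

  seq_major <- seqchr
  substr(seq_major, snp_index, snp_index) <- alleles[1L]
  seq_minor <- seqchr
  substr(seq_minor, snp_index, snp_index) <- alleles[2L]

  structure(list(
    id = id %||% "template",
    sequence = seqchr,
    length = nchar(seqchr),
    snp_index = as.integer(snp_index),
    allele_major = alleles[1L],
    allele_minor = alleles[2L],
    extra_snp_indices = as.integer(extra),
    sequence_major = seq_major,
    sequence_minor = seq_minor
  ), class = "ctpp_template")
}

#' @export
print.ctpp_template <- function(x, ...) {
  cat(sprintf("CTPP template '%s': %d bp, SNP at %d [%s/%s]",
              x$id, x$length, x$snp_index, x$allele_major, x$allele_minor))
  if (length(x$extra_snp_indices))
    cat(sprintf(", %d extra polymorphic site(s) at %s",
                length(x$extra_snp_indices),
                paste(x$extra_snp_indices, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Maximal feasible PCR product lengths for a template
#'
#' Computes the largest product lengths `delta1` (upstream pair, whose
#' reverse primer starts on the SNP) and `delta2` (downstream pair, whose
#' forward primer ends on the SNP) that still fit on the template for some
#' admissible primer length.  Chromosome product genes are drawn between the
#' product-length floor and these bounds.
#'
#' @param template A `ctpp_template`.
#' @param cfg A [constraint_config()].
#' @param len_max,product_min Override the corresponding `cfg` fields.
#' @return Named numeric vector `c(delta1, delta2)`.
#' @export
feasible_bounds <- function(template, cfg = constraint_config(),
                            len_max = cfg$len_max,
                            product_min = cfg$product_min) {
  stopifnot(inherits(template, "ctpp_template"))
  s <- template$snp_index
  L <- template$length
  r1 <- min(len_max, L - s + 1L)
  f2 <- min(len_max, s)
  if (r1 < cfg$len_min)
    stop("template too short downstream of the SNP to place reverse primer 1",
         call. = FALSE)
  if (f2 < cfg$len_min)
    stop("template too short upstream of the SNP to place forward primer 2",
         call. = FALSE)
  delta1 <- s + r1 - 1L
  delta2 <- L - s + f2
  if (delta1 < product_min)
    stop(sprintf(
      "upstream side infeasible: maximal product 1 length %d < minimum %d",
      delta1, product_min), call. = FALSE)
  if (delta2 < product_min)
    stop(sprintf(
      "downstream side infeasible: maximal product 2 length %d < minimum %d",
      delta2, product_min), call. = FALSE)
  c(delta1 = as.integer(delta1), delta2 = as.integer(delta2))
}
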