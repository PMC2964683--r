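#' Read SNP-flanked records from a FASTA file
#'
#' Records may use either the IUPAC dialect (one ambiguity code marks the
#' SNP) or the bracket dialect (`...A[A/C]G...`); record IDs become design
#' IDs.
#'
#' @param path FASTA file (single- or multi-record).
#' @param dialect,alleles Passed to [parse_template()] for every record.
#' @return A list of `ctpp_template` objects.
#' @export
read_flanks <- function(path, dialect = "auto", alleles = NULL) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in ", path, call. = FALSE)
  ids <- names(recs) %||% paste0("record", seq_along(recs))
  ids <- vapply(strsplit(ids, "[[:space:]]+"), `[`, "", 1L)
  out <- lapply(seq_along(recs), function(i)
    parse_template(as.character(recs[[i]]), dialect = dialect,
                   alleles = alleles, id = ids[i]))
  names(out) <- ids
  out
}

.report_primer_table <- function(set, cfg) {
  p <- .set_primers(set)
  co <- set$coords
  data.frame(
    name = c("Pf1", "Pr1", "Pf2", "Pr2"),
    sequence = unname(p),
    length = nchar(unname(p)),
    gc = vapply(unname(p), gc_percent, numeric(1L)),
    tm = vapply(unname(p), tm_bm, numeric(1L), na_molar = cfg$na_molar),
    start = c(co$Fs1, co$Rs1, co$Fs2, co$Rs2),
    end = c(co$Fe1, co$Re1, co$Fe2, co$Re2),
    strand = c("+", "-", "+", "-"),
    stringsAsFactors = FALSE
  )
}

#' Design a CTPP primer set for one SNP-flanked record
#'
#' Parses the record if needed, runs the genetic algorithm, and assembles a
#' self-contained report: per-primer rows (sequence, length, GC%, Tm,
#' coordinates, strand), the three product sizes, pairwise Tm differences,
#' the full fitness breakdown, and an echo of every configuration value the
#' numbers depend on, so each figure in the report can be recomputed from
#' the printed sequences and configuration alone.
#'
#' @param x A `ctpp_template`, or a flank string parseable by
#'   [parse_template()].
#' @param cfg A [constraint_config()].
#' @param ga A [ga_config()].
#' @param id,dialect,alleles Passed to [parse_template()] when `x` is a
#'   string.
#' @return An object of class `ctpp_report`.
#' @export
design_one <- function(x, cfg = constraint_config(), ga = ga_config(),
                       id = NULL, dialect = "auto", alleles = NULL) {
  template <- if (inherits(x, "ctpp_template")) x
              else parse_template(x, dialect = dialect, alleles = alleles,
                                  id = id)
  res <- run_ga(template, cfg, ga)
  structure(list(
    id = id %||% template$id,
    template = template,
    vector = res$best_vector,
    primers = .report_primer_table(res$primer_set, cfg),
    products = res$primer_set$products,
    tm_diffs = res$fitness$detail$tm_diffs,
    fitness = res$fitness,
    converged = res$converged,
    generations = res$generations,
    trace = res$trace,
    cfg = cfg,
    ga = ga
  ), class = "ctpp_report")
}

#' @export
print.ctpp_report <- function(x, ...) {
  cat(.report_text(x), sep = "\n")
  invisible(x)
}

.fmt <- function(x, digits) formatC(x, format = "f", digits = digits)

.report_header <- function(r) {
  cfg <- r$cfg; ga <- r$ga
  t <- r$template
  kv <- c(
    ctppdesign = as.character(utils::packageVersion("ctppdesign")),
    id = r$id,
    template_length = t$length,
    snp_index = t$snp_index,
    allele_major = t$allele_major,
    allele_minor = t$allele_minor,
    extra_snp_indices = paste(t$extra_snp_indices, collapse = ","),
    na_molar = cfg$na_molar,
    weights = paste(cfg$weights, collapse = ","),
    ratios = paste(cfg$ratios, collapse = ","),
    ratio_tolerance = cfg$ratio_tolerance,
    len_bounds = paste(c(cfg$len_min, cfg$len_max), collapse = ","),
    len_diff_max = cfg$len_diff_max,
    gc_bounds = paste(c(cfg$gc_low, cfg$gc_high), collapse = ","),
    tm_bounds = paste(c(cfg$tm_low, cfg$tm_high), collapse = ","),
    tm_diff_max = cfg$tm_diff_max,
    product_min = cfg$product_min,
    dimer_thresholds = paste(c(cfg$dimer_stem_min, cfg$dimer_3p_min),
                             collapse = ","),
    hairpin_thresholds = paste(c(cfg$hairpin_stem_min,
                                 cfg$hairpin_loop_min), collapse = ","),
    extra_snp_strict = cfg$extra_snp_strict,
    population_size = ga$population_size,
    max_generations = ga$max_generations,
    crossover_prob = ga$crossover_prob,
    mutation_prob = ga$mutation_prob,
    seed = ga$seed %||% "NA",
    generations_run = r$generations,
    converged = r$converged,
    vector = paste(r$vector, collapse = ","),
    products = paste(r$products, collapse = ","),
    tm_diffs = paste(.fmt(r$tm_diffs, 4L), collapse = ","),
    defects = paste(sprintf("%s=%d", c("len_diff", "gc_proportion",
                                       "gc_clamp", "tm", "tm_diff", "dimer",
                                       "hairpin", "specificity", "pcr_len"),
                            vapply(c("len_diff", "gc_proportion", "gc_clamp",
                                     "tm", "tm_diff", "dimer", "hairpin",
                                     "specificity", "pcr_len"),
                                   function(k) as.integer(r$fitness[[k]]),
                                   integer(1L))),
                    collapse = ";"),
    avg_tm_diff = .fmt(r$fitness$avg_tm_diff, 6L),
    fitness_total = .fmt(r$fitness$total, 6L)
  )
  paste0("#", names(kv), "\t", unname(kv))
}

.report_text <- function(r) {
  pr <- r$primers
  lines <- c(
    sprintf("CTPP primer design report -- %s", r$id),
    sprintf("template %d bp, SNP at %d [%s/%s], Na+ %g M, seed %s",
            r$template$length, r$template$snp_index,
            r$template$allele_major, r$template$allele_minor,
            r$cfg$na_molar, r$ga$seed %||% "NA"),
    sprintf("fitness %s after %d generation(s)%s",
            .fmt(r$fitness$total, 4L), r$generations,
            if (r$converged) " (all constraints satisfied)" else ""),
    "",
    sprintf("%-4s %-30s %6s %7s %7s %7s %7s %6s",
            "", "sequence (5'->3')", "len", "GC%", "Tm", "start", "end",
            "strand"))
  for (i in seq_len(nrow(pr)))
    lines <- c(lines, sprintf("%-4s %-30s %6d %7s %7s %7d %7d %6s",
                              pr$name[i], pr$sequence[i], pr$length[i],
                              .fmt(pr$gc[i], 2L), .fmt(pr$tm[i], 2L),
                              pr$start[i], pr$end[i], pr$strand[i]))
  c(lines, "",
    sprintf("products: Pf1/Pr1 %d bp, Pf2/Pr2 %d bp, Pf1/Pr2 %d bp",
            r$products[1L], r$products[2L], r$products[3L]),
    sprintf("Tm differences: Pf1/Pr1 %s, Pf2/Pr2 %s, Pf1/Pr2 %s degC",
            .fmt(r$tm_diffs[1L], 4L), .fmt(r$tm_diffs[2L], 4L),
            .fmt(r$tm_diffs[3L], 4L)))
}

#' Write a design report to a file
#'
#' The `tsv` format is lossless: a commented key-value header echoing the
#' template, constraint, and GA configuration, followed by the primer
#' table; [read_report()] round-trips it.  The `text` format is a
#' human-readable layout of the same information.
#'
#' @param report A `ctpp_report`.
#' @param path Output file path.
#' @param format `"tsv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "ctpp_report"))
  if (format == "text") {
    writeLines(.report_text(report), path)
    return(invisible(path))
  }
  pr <- report$primers
  pr$gc <- .fmt(pr$gc, 2L)
  pr$tm <- .fmt(pr$tm, 2L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.report_header(report), con)
  writeLines(paste(colnames(pr), collapse = "\t"), con)
  utils::write.table(pr, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV design report back
#'
#' @param path A file written by [write_report()] with `format = "tsv"`.
#' @return A list with `header` (named character vector of the echoed
#'   configuration) and `primers` (the primer table as a data frame).
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#([^\t]*)\t.*$", "\\1", hdr)
  vals <- sub("^#[^\t]*\t", "", hdr)
  names(vals) <- kv
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  primers <- utils::read.table(
    text = paste(body, collapse = "\n"), sep = "\t", header = TRUE,
    stringsAsFactors = FALSE,
    colClasses = c(name = "character", sequence = "character",
                   length = "integer", gc = "character", tm = "character",
                   start = "integer", end = "integer",
                   strand = "character"))
  list(header = vals, primers = primers)
}

#' Constraint-satisfaction statistics over a batch of designs
#'
#' For `n` designed sets the denominators follow the per-set counting of
#' the method: four primers per set for the per-primer criteria (GC%, GC
#' clamp, Tm, hairpin, specificity), three primer pairings per set for the
#' length-difference and Tm-difference criteria and three product lengths
#' per set for the product criterion, and ten dimer checks per set (six
#' cross pairings plus four self-dimers).  A product counts as satisfied
#' when it exceeds the product floor and corresponds to its ratio.
#'
#' @param reports A list of `ctpp_report` objects.
#' @return A data frame with columns `constraint`, `satisfied`, `total`.
#' @export
batch_statistics <- function(reports) {
  n <- length(reports)
  stopifnot(n >= 1L)
  get <- function(f) vapply(reports, f, numeric(1L))
  df <- data.frame(
    constraint = c("primer length difference", "GC%", "GC clamp", "Tm",
                   "Tm difference", "product length", "dimer", "hairpin",
                   "specificity"),
    satisfied = c(
      sum(get(function(r) 3 - r$fitness$len_diff)),
      sum(get(function(r) 4 - r$fitness$gc_proportion)),
      sum(get(function(r) 4 - r$fitness$gc_clamp)),
      sum(get(function(r) 4 - r$fitness$tm)),
      sum(get(function(r) 3 - r$fitness$tm_diff)),
      sum(get(function(r) sum(r$fitness$detail$product_ok))),
      sum(get(function(r) 10 - r$fitness$dimer)),
      sum(get(function(r) 4 - r$fitness$hairpin)),
      sum(get(function(r) 4 - sum(r$fitness$detail$specificity_repeats)))
    ),
    total = c(3L, 4L, 4L, 4L, 3L, 3L, 10L, 4L, 4L) * n,
    stringsAsFactors = FALSE
  )
  df$satisfied <- as.integer(df$satisfied)
  df
}

#' Design CTPP primer sets for a batch of records
#'
#' Runs an independent, seeded GA per record (record `i` uses
#' `ga$seed + i - 1`, so a single-record rerun with that seed reproduces
#' its batch result) and aggregates Table-style constraint-satisfaction
#' statistics.
#'
#' @param x A list of `ctpp_template` objects, or a path to a FASTA file
#'   of flank records.
#' @param cfg A [constraint_config()].
#' @param ga A [ga_config()]; its `seed` is the master seed (default 1 if
#'   unset).
#' @param dialect,alleles Passed to [read_flanks()] when `x` is a path.
#' @return A list with `reports` (one `ctpp_report` per record) and
#'   `statistics` (see [batch_statistics()]).
#' @export
design_batch <- function(x, cfg = constraint_config(), ga = ga_config(),
                         dialect = "auto", alleles = NULL) {
  templates <- if (is.character(x)) read_flanks(x, dialect, alleles) else x
  stopifnot(length(templates) >= 1L)
  base_seed <- ga$seed %||% 1L
  reports <- lapply(seq_along(templates), function(i) {
    ga_i <- ga
    ga_i$seed <- base_seed + i - 1L
    design_one(templates[[i]], cfg, ga_i)
  })
  names(reports) <- vapply(reports, `[[`, "", "id")
  list(reports = reports, statistics = batch_statistics(reports))
}
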