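.WC <- c(A = "T", C = "G", G = "C", T = "A")

# random 20-mer with exactly 10 G/C bases, a fixed or random G/C 3' base,
# and no self-dimer or hairpin under the configured screens
.rand_clean_primer <- function(cfg, last = NULL, max_tries = 2000L) {
  for (i in seq_len(max_tries)) {
    lastch <- last %||% c("G", "C")[.runif_int(1L, 2L)]
    ch <- character(19L)
    gcpos <- sample.int(19L, 9L)
    ch[gcpos] <- c("G", "C")[sample.int(2L, 9L, replace = TRUE)]
    ch[-gcpos] <- c("A", "T")[sample.int(2L, 10L, replace = TRUE)]
    p <- paste(c(ch, lastch), collapse = "")
    if (!dimer_screen(p, p, cfg$dimer_stem_min, cfg$dimer_3p_min) &&
        !hairpin_screen(p, cfg$hairpin_stem_min, cfg$hairpin_loop_min))
      return(p)
  }
  stop("could not sample a screen-clean primer", call. = FALSE)
}

# four mutually dimer-free primers with the 3'-end alleles required by the
# confronting geometry (all 20-mers with 50% GC, so their melting
# temperatures are identical by construction)
.plant_zero_primers <- function(cfg, max_tries = 2000L) {
  want_last <- list(pf1 = NULL, pr1 = "C", pf2 = "C", pr2 = NULL)
  ps <- list()
  for (nm in names(want_last)) {
    ok <- FALSE
    for (i in seq_len(max_tries)) {
      cand <- .rand_clean_primer(cfg, want_last[[nm]])
      clean <- all(!vapply(ps, function(q)
        dimer_screen(cand, q, cfg$dimer_stem_min, cfg$dimer_3p_min),
        logical(1L)))
      if (clean) { ps[[nm]] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not assemble a mutually dimer-free primer set",
                  call. = FALSE)
  }
  ps
}

#' Generate a synthetic SNP-flanked template
#'
#' Emulates a flank export: a random background of the requested GC
#' fraction with one IUPAC-coded SNP in the middle.  Optional planted
#' features make specific behaviors testable: `plant_zero` embeds a
#' chromosome whose realized primer set satisfies every constraint (four
#' 20-mers of identical length and GC count, hence identical melting
#' temperature, clean under the dimer and hairpin screens, with products
#' 160/260/381 bp inside the ratio tolerance); `plant_repeat` duplicates
#' the 20-mer at the embedded outer-forward window elsewhere on the
#' template, tripping the specificity check; `plant_palindrome` inserts a
#' 12-base stem-loop motif upstream.  `plant_zero` forces the allele pair
#' C/G so that both inner primers carry a 3' G/C clamp.
#'
#' @param flank_length Bases on each side of the SNP (default 500).
#' @param gc_background Background GC fraction of the random sequence.
#' @param alleles `c(major, minor)`; overridden to `c("C", "G")` when
#'   `plant_zero = TRUE`.
#' @param plant_zero,plant_repeat,plant_palindrome Planted features.
#' @param seed Integer seed; generation is deterministic given it.
#' @param cfg A [constraint_config()] used to verify planted features.
#' @param id Record identifier.
#' @param max_tries Resampling attempts before giving up.
#' @return A list with `template` (a `ctpp_template`) and `manifest`
#'   (coordinates and sequences of every planted feature, plus the planted
#'   chromosome `zero_vector` when applicable).
#' @export
generate_template <- function(flank_length = 500L, gc_background = 0.5,
                              alleles = c("A", "C"),
                              plant_zero = FALSE, plant_repeat = FALSE,
                              plant_palindrome = FALSE,
                              seed = 1L, cfg = constraint_config(),
                              id = NULL, max_tries = 25L) {
  stopifnot(flank_length >= cfg$product_min + cfg$len_max,
            gc_background > 0, gc_background < 1)
  if (plant_zero && flank_length < 260L)
    stop("flank_length must be >= 260 to plant a zero-fitness set",
         call. = FALSE)
  if (plant_repeat && flank_length < 300L)
    stop("flank_length must be >= 300 to plant a repeat", call. = FALSE)
  if (plant_palindrome && flank_length < 320L)
    stop("flank_length must be >= 320 to plant a palindrome", call. = FALSE)
  set.seed(seed)
  if (plant_zero) alleles <- c("C", "G")
  alleles <- toupper(alleles)
  snp_code <- .code_for_alleles(alleles)
  L <- 2L * flank_length + 1L
  s <- flank_length + 1L
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc_background) / 2, gc_background / 2,
             gc_background / 2, (1 - gc_background) / 2)
  v0 <- c(Fl1 = 20L, Pl1 = 160L, Rl1 = 20L,
          Fl2 = 20L, Pl2 = 260L, Rl2 = 20L)

  for (try in seq_len(max_tries)) {
    ch <- sample(bases, L, replace = TRUE, prob = probs)
    ch[s] <- snp_code
    manifest <- list(alleles = alleles, seed = seed, snp_index = s)

    if (plant_zero) {
      ps <- .plant_zero_primers(cfg)
      ch[(s - 140L):(s - 121L)] <- .chars(ps$pf1)
      pf2c <- .chars(ps$pf2)
      ch[(s - 19L):(s - 1L)] <- pf2c[1:19]
      pr1t <- .chars(reverse_complement(ps$pr1))  # template-sense window
      ch[(s + 1L):(s + 19L)] <- pr1t[2:20]
      ch[(s + 221L):(s + 240L)] <- .chars(reverse_complement(ps$pr2))
      manifest$zero_vector <- v0
      manifest$zero_windows <- list(pf1 = c(s - 140L, s - 121L),
                                    pr1 = c(s, s + 19L),
                                    pf2 = c(s - 19L, s),
                                    pr2 = c(s + 221L, s + 240L))
      manifest$zero_primers <- ps
    }
    if (plant_repeat) {
      src <- (s - 140L):(s - 121L)
      dst <- (L - 40L):(L - 21L)
      ch[dst] <- ch[src]
      manifest$repeat_seq <- paste(ch[src], collapse = "")
      manifest$repeat_positions <- c(src[1L], dst[1L])
    }
    if (plant_palindrome) {
      motif <- "GGGGAAAACCCC"
      pos <- (s - 300L):(s - 289L)
      ch[pos] <- .chars(motif)
      manifest$palindrome <- list(motif = motif, start = pos[1L])
    }

    template <- parse_template(paste(ch, collapse = ""), dialect = "iupac",
                               alleles = alleles,
                               id = id %||% sprintf("synthetic_%d", seed))

    ok <- TRUE
    if (plant_zero) {
      bd <- evaluate_vector(template, v0, cfg)
      expect_spec <- as.integer(isTRUE(plant_repeat))
      ok <- bd$len_diff == 0L && bd$gc_proportion == 0L &&
        bd$gc_clamp == 0L && bd$tm == 0L && bd$tm_diff == 0L &&
        bd$avg_tm_diff <= cfg$tm_epsilon && bd$dimer == 0L &&
        bd$hairpin == 0L && bd$pcr_len == 0L &&
        bd$specificity == expect_spec
    }
    if (ok && plant_repeat) {
      cnt <- Biostrings::countPattern(
        manifest$repeat_seq, Biostrings::DNAString(template$sequence_major))
      ok <- cnt == 2L
    }
    if (ok) return(list(template = template, manifest = manifest))
  }
  stop("failed to generate a template with verified planted features",
       call. = FALSE)
}

#' Exhaustively enumerate and evaluate all feasible chromosomes
#'
#' Brute-force oracle for validating the genetic algorithm on small
#' instances: enumerates the full chromosome grid (primer genes over
#' `[len_min, len_max]`, product genes over their configured ranges),
#' filters to hard-feasible vectors, evaluates each, and returns the true
#' minimum with all argmins.  Enumeration is lexicographic with the first
#' gene varying fastest; ties are all returned, in enumeration order.
#'
#' @param template A `ctpp_template`.
#' @param cfg A [constraint_config()]; use `pl1_range` / `pl2_range` and
#'   the length bounds to restrict the space.
#' @param max_space Guard: error (rather than silently truncate) when the
#'   grid exceeds this many vectors.
#' @return A list with `min_total`, `argmins` (matrix of minimal
#'   chromosomes, one per row), `n_feasible`, and `n_space`.
#' @export
exhaustive_search <- function(template, cfg = constraint_config(),
                              max_space = 1e6) {
  rng <- .gene_ranges(template, cfg)
  lens <- seq.int(cfg$len_min, cfg$len_max)
  p1 <- seq.int(rng$lo[2L], rng$hi[2L])
  p2 <- seq.int(rng$lo[5L], rng$hi[5L])
  n_space <- length(lens)^4 * length(p1) * length(p2)
  if (n_space > max_space)
    stop(sprintf("search space %g exceeds max_space %g", n_space,
                 max_space), call. = FALSE)
  g <- expand.grid(Fl1 = lens, Pl1 = p1, Rl1 = lens, Fl2 = lens, Pl2 = p2,
                   Rl2 = lens, KEEP.OUT.ATTRS = FALSE)
  s <- template$snp_index
  L <- template$length
  ok <- (s + g$Rl1 - 1L <= L) &
    (g$Pl1 <= s + g$Rl1 - 1L) &
    (g$Pl1 >= g$Fl1 + g$Rl1) &
    (g$Fl2 <= s) &
    (g$Pl2 <= L - s + g$Fl2) &
    (g$Pl2 >= g$Fl2 + g$Rl2)
  E <- template$extra_snp_indices
  if (length(E)) {
    Fs1 <- s + g$Rl1 - g$Pl1
    Fe1 <- Fs1 + g$Fl1 - 1L
    Rs2 <- s - g$Fl2 + g$Pl2
    Re2 <- Rs2 - g$Rl2 + 1L
    for (e in E) {
      ok <- ok & !(e >= Fs1 & e <= Fe1) & !(e >= Re2 & e <= Rs2)
      if (cfg$extra_snp_strict)
        ok <- ok & !(e >= s - g$Fl2 + 1L & e <= s) &
          !(e >= s & e <= s + g$Rl1 - 1L)
    }
  }
  g <- g[ok, , drop = FALSE]
  if (nrow(g) == 0L)
    stop("no feasible chromosome in the restricted space", call. = FALSE)
  totals <- vapply(seq_len(nrow(g)), function(i)
    evaluate_vector(template, as.integer(g[i, ]), cfg)$total, numeric(1L))
  mn <- min(totals)
  argmins <- as.matrix(g[totals == mn, , drop = FALSE])
  dimnames(argmins) <- list(NULL, .gene_names)
  list(min_total = mn, argmins = argmins,
       n_feasible = nrow(g), n_space = n_space)
}

#' Brute-force antiparallel dimer check (independent oracle)
#'
#' Enumerates every antiparallel ungapped alignment of the two 5'->3'
#' strings explicitly, scans each alignment's complementarity profile for
#' runs, and applies the same verdict rule as [dimer_screen()]: a run of
#' `stem_min` anywhere, or `end_min` when the run covers either primer's
#' 3'-terminal base.  Used to validate the production screen by full
#' enumeration at small lengths.
#'
#' @param p,q Primer strings (A/C/G/T), 5' to 3'; `q` defaults to `p`
#'   (self-dimer).
#' @param stem_min,end_min Run-length thresholds.
#' @return `TRUE` if a dimer is found.
#' @export
dimer_bruteforce <- function(p, q = p, stem_min = 5L, end_min = 3L) {
  pc <- .chars(toupper(p))
  qc <- .chars(toupper(q))
  stopifnot(all(pc %in% names(.WC)), all(qc %in% names(.WC)))
  n <- length(pc)
  m <- length(qc)
  qr <- rev(qc)  # qr[1] is q's 3'-terminal base
  for (sft in (-(m - 1L)):(n - 1L)) {
    i <- seq.int(max(1L, sft + 1L), min(n, sft + m))
    j <- i - sft
    comp <- pc[i] == unname(.WC[qr[j]])
    r <- rle(comp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    p3_at <- which(i == n)
    q3_at <- which(j == 1L)
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      len <- r$lengths[k]
      covers3 <-
        (length(p3_at) && starts[k] <= p3_at && p3_at <= ends[k]) ||
        (length(q3_at) && starts[k] <= q3_at && q3_at <= ends[k])
      if (len >= stem_min || (covers3 && len >= end_min)) return(TRUE)
    }
  }
  FALSE
}

#' Brute-force hairpin check (independent oracle)
#'
#' Enumerates every stem/loop decomposition: all stem lengths from
#' `stem_min` up, all upstream/downstream window placements with a loop of
#' at least `loop_min` bases, testing antiparallel Watson-Crick pairing of
#' the two windows.
#'
#' @param p Primer string (A/C/G/T), 5' to 3'.
#' @param stem_min,loop_min Minimal stem and loop lengths.
#' @return `TRUE` if a hairpin is found.
#' @export
hairpin_bruteforce <- function(p, stem_min = 4L, loop_min = 3L) {
  pc <- .chars(toupper(p))
  stopifnot(all(pc %in% names(.WC)))
  n <- length(pc)
  if (2L * stem_min + loop_min > n) return(FALSE)
  for (k in seq.int(stem_min, (n - loop_min) %/% 2L)) {
    for (i in seq_len(n - 2L * k - loop_min + 1L)) {
      for (jj in seq.int(i + k + loop_min, n - k + 1L)) {
        stem1 <- pc[i:(i + k - 1L)]
        stem2 <- pc[jj:(jj + k - 1L)]
        if (all(stem1 == unname(.WC[rev(stem2)]))) return(TRUE)
      }
    }
  }
  FALSE
}
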