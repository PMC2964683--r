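`%||%` <- function(x, y) if (is.null(x)) y else x

# uniform integer draw on [lo, hi]; avoids the sample(x, 1) scalar pitfall
.runif_int <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(hi >= lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# encode an unambiguous primer string as integers A=1, C=2, G=3, T=4
# (Watson-Crick complement is then 5 - x)
.DNA_CODE <- local({
  tab <- integer(128L)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab
})

.encode_dna <- function(s) {
  v <- .DNA_CODE[utf8ToInt(s)]
  if (any(v == 0L))
    stop("sequence contains characters other than A, C, G, T", call. = FALSE)
  v
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
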