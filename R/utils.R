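# Internal helpers shared across modules.

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators route their randomness through this so that a single
#' integer seed makes every simulated dataset bitwise reproducible without
#' clobbering the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Random DNA string of length n
#' @noRd
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of plain character DNA string(s), vectorized
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' All start positions of a fixed motif in a string (1-based), possibly none
#' @noRd
find_motif <- function(subject, motif) {
  hits <- gregexpr(motif, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Substring keeping 1-based inclusive coordinates, clipped to the string
#' @noRd
substr_safe <- function(x, start, end) {
  n <- nchar(x)
  start <- max(1L, start)
  end <- min(n, end)
  if (start > end) "" else substr(x, start, end)
}

opposite_strand <- function(strand) ifelse(strand == "+", "-", "+")

#' Uniform integer in [lo, hi], safe for lo == hi (unlike sample(seq(...)))
#' @noRd
sample_int_range <- function(lo, hi) {
  stopifnot(hi >= lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
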