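# P-element consensus model: the 2907-bp full-length (FP) element, its
# internally deleted variants (KP and friends), and primer-pair bookkeeping
# used by the amplicon / qPCR layer.

# Full-length P-element consensus length (bp).
PELEMENT_LENGTH <- 2907L
# KP internal deletion, 1-based inclusive consensus coordinates.
KP_DELETION <- c(808L, 2560L)
# Terminal inverted repeat length (bp).
TIR_LENGTH <- 31L

#' Build a P-element consensus model
#'
#' Generates a seeded random 2907-bp consensus whose terminal 31-nt segments
#' are perfect inverted repeats (as in the real element), together with the
#' named deletion variants: \code{FP} (full length, no deletion) and
#' \code{KP} (single internal deletion spanning consensus positions
#' 808-2560, 1-based inclusive). Primer pairs are configuration: coordinates
#' of a forward-primer start and reverse-primer end on the consensus.
#'
#' One recognition site per junction-assay enzyme is guaranteed at a fixed
#' distance from each terminus (HhaI/GCGC at 320 bp, TaqI/TCGA at 180 bp),
#' mirroring how the real assay's enzymes were chosen for their conveniently
#' placed sites in the element; both distances lie outside the KP deletion
#' and beyond the nested-primer offset, so every variant remains a usable
#' assay substrate.
#'
#' @param seed Integer seed; the same seed always yields the same consensus.
#' @param primer_pairs Named list of length-2 integer vectors
#'   \code{c(forward_start, reverse_end)} in 1-based consensus coordinates.
#'   The default \code{total_p} pair spans positions 1-2526 so that the
#'   full-length template yields a 2526-bp product; the default
#'   \code{non_kp} pair places its forward primer inside the KP deletion so
#'   KP templates yield no product.
#' @return An object of class \code{element_model}: list with
#'   \code{consensus} (character), \code{variants} (named list of deletion
#'   interval matrices), \code{primer_pairs}, \code{tir_length}.
#' @examples
#' em <- make_element_model(seed = 1)
#' nchar(em$consensus)                     # 2907
#' nchar(variant_sequence(em, "KP"))       # 1154
#' @export
make_element_model <- function(seed = 1L,
                               primer_pairs = list(total_p = c(1L, 2526L),
                                                   non_kp  = c(1500L, 2907L))) {
  with_seed(seed, {
    core <- rand_dna(PELEMENT_LENGTH - TIR_LENGTH)
    tir <- substr(core, 1L, TIR_LENGTH)
    consensus <- paste0(core, revcomp(tir))
  })
  # guaranteed assay sites at fixed distances from both termini
  L <- PELEMENT_LENGTH
  for (site in list(list(motif = "GCGC", d = 320L),
                    list(motif = "TCGA", d = 180L))) {
    substr(consensus, site$d + 1L, site$d + 4L) <- site$motif
    substr(consensus, L - site$d - 3L, L - site$d) <- site$motif
  }
  stopifnot(nchar(consensus) == PELEMENT_LENGTH)
  for (pp in primer_pairs) {
    stopifnot(length(pp) == 2L, pp[1] >= 1L, pp[2] <= PELEMENT_LENGTH, pp[1] < pp[2])
  }
  structure(list(
    consensus = consensus,
    variants = list(
      FP = matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))),
      KP = matrix(KP_DELETION, ncol = 2, dimnames = list(NULL, c("start", "end")))
    ),
    primer_pairs = primer_pairs,
    tir_length = TIR_LENGTH
  ), class = "element_model")
}

#' @export
print.element_model <- function(x, ...) {
  cat(sprintf("P-element model: %d-bp consensus, %d-nt terminal inverted repeats\n",
              nchar(x$consensus), x$tir_length))
  for (v in names(x$variants)) {
    d <- x$variants[[v]]
    if (nrow(d) == 0) {
      cat(sprintf("  variant %-4s full length (%d bp)\n", v, nchar(x$consensus)))
    } else {
      cat(sprintf("  variant %-4s deletion(s) %s (%d bp)\n", v,
                  paste(sprintf("%d-%d", d[, 1], d[, 2]), collapse = ", "),
                  nchar(variant_sequence(x, v))))
    }
  }
  invisible(x)
}

#' Sequence of a named element variant
#'
#' Applies the variant's deletion intervals to the consensus.
#'
#' @param model An \code{element_model}.
#' @param variant Variant name present in \code{model$variants}.
#' @return Nucleotide string of the variant.
#' @export
variant_sequence <- function(model, variant) {
  stopifnot(inherits(model, "element_model"))
  dels <- model$variants[[variant]]
  if (is.null(dels)) stop("unknown variant: ", variant)
  apply_deletions(model$consensus, dels)
}

# Remove 1-based inclusive intervals from a sequence.
apply_deletions <- function(seq, dels) {
  if (is.null(dels) || nrow(dels) == 0) return(seq)
  dels <- dels[order(dels[, 1]), , drop = FALSE]
  keep <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(dels))) {
    keep <- c(keep, substr_safe(seq, cursor, dels[i, 1] - 1L))
    cursor <- dels[i, 2] + 1L
  }
  keep <- c(keep, substr_safe(seq, cursor, nchar(seq)))
  paste(keep, collapse = "")
}

#' Add or replace a deletion variant in an element model
#'
#' @param model An \code{element_model}.
#' @param name Variant name.
#' @param deletions Matrix (or length-2 vector) of 1-based inclusive
#'   consensus deletion intervals; intervals must be disjoint and within
#'   the consensus.
#' @return The updated model.
#' @export
add_variant <- function(model, name, deletions) {
  stopifnot(inherits(model, "element_model"))
  if (is.vector(deletions)) deletions <- matrix(deletions, ncol = 2)
  colnames(deletions) <- c("start", "end")
  stopifnot(all(deletions[, 1] >= 1), all(deletions[, 2] <= nchar(model$consensus)),
            all(deletions[, 1] <= deletions[, 2]))
  d <- deletions[order(deletions[, 1]), , drop = FALSE]
  if (nrow(d) > 1 && any(d[-1, 1] <= d[-nrow(d), 2])) {
    stop("deletion intervals must be disjoint")
  }
  model$variants[[name]] <- d
  model
}
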