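# Variant typing of P-element sequences (FP / KP / other internal
# deletions) by seed-and-extend alignment against the consensus, PCR
# amplicon prediction on deleted templates, and the qPCR ddCt layer.

#' Classify a P-element sequence into FP / KP / other-deleted / unknown
#'
#' Exact k-mer seeds of the query are anchored on the consensus (k-mers
#' occurring more than once in the consensus are skipped as ambiguous) and
#' chained greedily in increasing consensus order; consensus coverage gaps
#' of at least \code{min_gap} bp between adjacent chained anchors are
#' reported as deletion intervals. FP means no deletion; KP means exactly
#' one deletion matching the 808-2560 junctions within \code{tolerance} bp
#' (absorbing junction microhomology ambiguity); any other deletion pattern
#' is "other-deleted"; queries with no anchor are "unknown". Both query
#' strands are tried and the better-covered one is used.
#'
#' @param query Nucleotide string, length >= 50.
#' @param model An \code{element_model}.
#' @param k Seed k-mer length (default 15).
#' @param min_gap Minimum consensus coverage gap called as a deletion (bp).
#' @param tolerance KP junction tolerance (bp, default 3).
#' @return List of class \code{variant_call}: \code{variant} (FP, KP,
#'   other-deleted or unknown), \code{deletions} (matrix of 1-based
#'   inclusive consensus intervals), \code{aligned_fraction} of consensus
#'   covered, \code{strand} of the query relative to the consensus.
#' @export
classify_variant <- function(query, model, k = 15L, min_gap = 20L, tolerance = 3L) {
  stopifnot(inherits(model, "element_model"), nchar(query) >= 50L)
  cons <- model$consensus

  fwd <- chain_anchors(query, cons, k)
  rev <- chain_anchors(revcomp(query), cons, k)
  use_rev <- rev$covered > fwd$covered
  aln <- if (use_rev) rev else fwd

  if (is.null(aln$anchors) || nrow(aln$anchors) == 0) {
    return(structure(list(variant = "unknown",
                          deletions = matrix(integer(0), ncol = 2,
                                             dimnames = list(NULL, c("start", "end"))),
                          aligned_fraction = 0,
                          strand = NA_character_),
                     class = "variant_call"))
  }

  dels <- anchor_gaps(aln$anchors, k, min_gap)
  variant <- if (nrow(dels) == 0) {
    "FP"
  } else if (nrow(dels) == 1 &&
             abs(dels[1, 1] - KP_DELETION[1]) <= tolerance &&
             abs(dels[1, 2] - KP_DELETION[2]) <= tolerance) {
    "KP"
  } else {
    "other-deleted"
  }
  structure(list(variant = variant, deletions = dels,
                 aligned_fraction = aln$covered / nchar(cons),
                 strand = if (use_rev) "-" else "+"),
            class = "variant_call")
}

#' @export
print.variant_call <- function(x, ...) {
  cat(sprintf("variant_call: %s (%.1f%% of consensus aligned%s)\n",
              x$variant, 100 * x$aligned_fraction,
              if (is.na(x$strand)) "" else paste0(", strand ", x$strand)))
  if (nrow(x$deletions) > 0) {
    cat("  deletions:",
        paste(sprintf("%d-%d", x$deletions[, 1], x$deletions[, 2]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Anchor all unique query k-mers on the consensus and keep a greedy chain
# with strictly increasing consensus positions.
chain_anchors <- function(query, cons, k) {
  nq <- nchar(query)
  if (nq < k) return(list(anchors = NULL, covered = 0))
  qpos <- seq_len(nq - k + 1L)
  qmers <- substring(query, qpos, qpos + k - 1L)
  cpos_all <- seq_len(nchar(cons) - k + 1L)
  cmers <- substring(cons, cpos_all, cpos_all + k - 1L)
  multi <- unique(cmers[duplicated(cmers)])
  hit <- match(qmers, cmers)
  valid <- !is.na(hit) & !(qmers %in% multi)
  if (!any(valid)) return(list(anchors = NULL, covered = 0))
  anchors <- data.frame(q = qpos[valid], c = cpos_all[hit[valid]])
  # greedy chain: strictly increasing consensus coordinate
  keep <- logical(nrow(anchors))
  last_c <- -Inf
  for (i in seq_len(nrow(anchors))) {
    if (anchors$c[i] > last_c) { keep[i] <- TRUE; last_c <- anchors$c[i] }
  }
  anchors <- anchors[keep, , drop = FALSE]
  # covered consensus bases (union of k-mer footprints)
  ir <- IRanges::reduce(IRanges::IRanges(anchors$c, anchors$c + k - 1L))
  list(anchors = anchors, covered = sum(IRanges::width(ir)))
}

# Deletion intervals from coverage gaps between adjacent chained anchors:
# a consensus jump exceeding the query jump by >= min_gap bp.
anchor_gaps <- function(anchors, k, min_gap) {
  dels <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (nrow(anchors) < 2) return(dels)
  for (i in seq_len(nrow(anchors) - 1L)) {
    dq <- anchors$q[i + 1L] - anchors$q[i]
    dc <- anchors$c[i + 1L] - anchors$c[i]
    if (dc - dq >= min_gap) {
      dels <- rbind(dels, c(anchors$c[i] + dq, anchors$c[i + 1L] - 1L))
    }
  }
  dels
}

#' Predict PCR products of a primer pair on a deleted template
#'
#' Primer positions are given in consensus coordinates; the product is
#' computed on the variant implied by the template's deletions (determined
#' with \code{\link{classify_variant}}). If either primer's annealing
#' coordinate falls inside a deletion there is no product -- the basis of
#' "non-KP" primer designs whose forward primer sits inside the KP
#' deletion.
#'
#' @param template Nucleotide string of the template element.
#' @param primer_pair Length-2 vector: forward-primer start and
#'   reverse-primer end, 1-based consensus coordinates.
#' @param model An \code{element_model}.
#' @return Integer vector of product lengths (empty when no product).
#' @export
amplicon_products <- function(template, primer_pair, model) {
  stopifnot(length(primer_pair) == 2L,
            primer_pair[1] >= 1L, primer_pair[2] <= nchar(model$consensus),
            primer_pair[1] < primer_pair[2])
  call <- classify_variant(template, model)
  if (call$variant == "unknown") return(integer(0))
  dels <- call$deletions
  f <- primer_pair[1]; r <- primer_pair[2]
  if (nrow(dels) > 0) {
    inside <- function(p) any(p >= dels[, 1] & p <= dels[, 2])
    if (inside(f) || inside(r)) return(integer(0))
    deleted_within <- sum(pmax(0L, pmin(dels[, 2], r) - pmax(dels[, 1], f) + 1L))
  } else {
    deleted_within <- 0L
  }
  as.integer(r - f + 1L - deleted_within)
}

#' Read a qPCR Ct table
#'
#' @param path TSV file with header \code{strain target replicate ct}.
#' @return Data frame with those columns.
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_qpcr_table(tab)
}

#' Validate a qPCR Ct table
#' @param tab Data frame with strain/target/replicate/ct columns.
#' @return The table, invisibly usable; errors on violation.
#' @export
validate_qpcr_table <- function(tab) {
  stopifnot(all(c("strain", "target", "replicate", "ct") %in% names(tab)),
            all(tab$ct > 0))
  tab
}

#' Relative copy number by the ddCt method
#'
#' Per strain, dCt = mean Ct(target) - mean Ct(reference gene); relative
#' abundance = 2^-(dCt_strain - dCt_reference_strain), so the reference
#' strain maps to 1. Amplification efficiency is fixed at 2.0 (perfect
#' doubling per cycle).
#'
#' @param table qPCR table (see \code{\link{read_qpcr_table}}).
#' @param target Target name to quantify.
#' @param reference_gene Single-copy normalizer gene name.
#' @param reference_strain Strain whose abundance defines 1.0.
#' @return Named numeric vector of relative abundances per strain.
#' @export
relative_copy_number <- function(table, target, reference_gene = "RP49",
                                 reference_strain = NULL) {
  validate_qpcr_table(table)
  strains <- unique(table$strain)
  if (is.null(reference_strain)) reference_strain <- strains[1]
  if (!reference_strain %in% strains) {
    stop("reference strain '", reference_strain, "' absent from the table")
  }
  dct <- vapply(strains, function(s) {
    t_rows <- table$ct[table$strain == s & table$target == target]
    r_rows <- table$ct[table$strain == s & table$target == reference_gene]
    if (length(t_rows) == 0) stop("strain '", s, "' has no '", target, "' rows")
    if (length(r_rows) == 0) stop("strain '", s, "' has no '", reference_gene, "' rows")
    mean(t_rows) - mean(r_rows)
  }, numeric(1))
  rel <- 2^(-(dct - dct[[reference_strain]]))
  stats::setNames(rel, strains)
}

#' KP share of total P-element copies
#'
#' @param kp_rel Relative KP copy number.
#' @param total_rel Relative total-P copy number; must be positive.
#' @return Percentage 100 * kp_rel / total_rel, capped at 100.
#' @export
kp_fraction <- function(kp_rel, total_rel) {
  stopifnot(kp_rel >= 0)
  if (total_rel <= 0) stop("total P copy number must be positive")
  min(100, 100 * kp_rel / total_rel)
}
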