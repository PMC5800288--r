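# Element-derived piRNA quantification: miRNA removal (the normalization
# denominator), 24-35 nt size filter, strand-aware exact mapping to the
# element consensus, RPM normalization and positional profiles.

#' Size-filter small-RNA reads
#'
#' Retains reads whose length lies in [\code{min_len}, \code{max_len}]
#' inclusive (default 24-35 nt, the piRNA size class).
#'
#' @param reads Character vector of read sequences.
#' @param min_len,max_len Inclusive length bounds.
#' @return The retained reads.
#' @export
size_filter <- function(reads, min_len = 24L, max_len = 35L) {
  n <- nchar(reads)
  reads[n >= min_len & n <= max_len]
}

#' Remove miRNA reads and count them
#'
#' Reads exactly matching any miRNA sequence on either strand are removed;
#' their count is the RPM normalization denominator.
#'
#' @param reads Character vector of read sequences.
#' @param mirna_set Character vector of miRNA sequences.
#' @return List: \code{reads} (retained), \code{mirna_count}.
#' @export
remove_mirnas <- function(reads, mirna_set = decoy_mirnas()) {
  if (length(mirna_set) == 0 || length(reads) == 0) {
    return(list(reads = reads, mirna_count = 0L))
  }
  targets <- unique(c(mirna_set, revcomp(mirna_set)))
  is_mirna <- reads %in% targets
  list(reads = reads[!is_mirna], mirna_count = sum(is_mirna))
}

#' Map small-RNA reads to the element consensus
#'
#' Each read is searched against the consensus forward strand (sense) and
#' its reverse complement (antisense) allowing up to \code{max_mismatch}
#' mismatches (default 0, exact). A hit is recorded at the read's 5'-end
#' consensus position: the match start for sense reads, the match end for
#' antisense reads. A read with several hits is counted once at a
#' deterministically chosen hit -- the lowest consensus coordinate, sense
#' taking precedence over antisense on ties.
#'
#' @param reads Character vector of read sequences.
#' @param element_model An \code{element_model}.
#' @param max_mismatch Mismatch tolerance, 0-3 (default 0).
#' @return Object of class \code{smallrna_profile}: per-position
#'   \code{sense} and \code{antisense} count vectors over consensus
#'   coordinates, \code{total} mapped element reads, \code{n_input} reads
#'   searched; \code{mirna_count} and \code{rpm} are NA until set by
#'   \code{\link{rpm_normalize}} / \code{\link{quantify_pirnas}}.
#' @export
map_to_element <- function(reads, element_model, max_mismatch = 0L) {
  stopifnot(inherits(element_model, "element_model"),
            max_mismatch >= 0L, max_mismatch <= 3L)
  cons <- element_model$consensus
  L <- nchar(cons)
  sense <- integer(L); antisense <- integer(L)

  if (length(reads) > 0) {
    tab <- table(reads)
    uniq <- names(tab)
    rc_uniq <- revcomp(uniq)
    cons_dna <- Biostrings::DNAString(cons)
    for (u in seq_along(uniq)) {
      hit <- best_element_hit(uniq[u], rc_uniq[u], cons, cons_dna, max_mismatch)
      if (!is.null(hit)) {
        k <- as.integer(tab[u])
        if (hit$strand == "sense") sense[hit$pos] <- sense[hit$pos] + k
        else antisense[hit$pos] <- antisense[hit$pos] + k
      }
    }
  }

  structure(list(sense = sense, antisense = antisense,
                 total = sum(sense) + sum(antisense),
                 n_input = length(reads),
                 mirna_count = NA_integer_, rpm = NA_real_,
                 sample = NA_character_),
            class = "smallrna_profile")
}

# Lowest-coordinate hit, sense before antisense; positions are 5'-end
# consensus coordinates. NULL when the read does not match.
best_element_hit <- function(read, read_rc, cons, cons_dna, max_mismatch) {
  if (max_mismatch == 0L) {
    s_hits <- find_motif(cons, read)
    a_hits <- find_motif(cons, read_rc)
  } else {
    s_hits <- Biostrings::start(Biostrings::matchPattern(
      read, cons_dna, max.mismatch = max_mismatch))
    a_hits <- Biostrings::start(Biostrings::matchPattern(
      read_rc, cons_dna, max.mismatch = max_mismatch))
  }
  if (length(s_hits) == 0 && length(a_hits) == 0) return(NULL)
  len <- nchar(read)
  # candidate positions: sense 5' end = match start; antisense 5' end =
  # match end on the consensus
  cand_pos <- c(s_hits, a_hits + len - 1L)
  cand_strand <- c(rep("sense", length(s_hits)), rep("antisense", length(a_hits)))
  ord <- order(cand_pos, cand_strand != "sense")
  list(pos = cand_pos[ord[1]], strand = cand_strand[ord[1]])
}

#' Reads-per-million-miRNA-reads normalization
#'
#' @param element_count Mapped element piRNA reads.
#' @param mirna_count miRNA reads (denominator); must be positive.
#' @return RPM value: element_count * 1e6 / mirna_count.
#' @export
rpm_normalize <- function(element_count, mirna_count) {
  stopifnot(element_count >= 0)
  if (is.na(mirna_count) || mirna_count <= 0) {
    stop("cannot normalize: miRNA count is zero")
  }
  element_count * 1e6 / mirna_count
}

#' Quantify element-derived piRNAs in a small-RNA read set
#'
#' Canonical pipeline order: miRNA removal first (the denominator counts
#' every removed miRNA read regardless of length), then the 24-35 nt size
#' filter, then strand-aware consensus mapping and RPM normalization.
#'
#' @param reads Character vector of reads (or a \code{smallrna_library}).
#' @param element_model An \code{element_model}.
#' @param mirna_set miRNA sequences removed and counted (default bundled
#'   decoy set).
#' @param min_len,max_len Size-filter bounds (default 24-35).
#' @param max_mismatch Mapping mismatch tolerance (default 0).
#' @param sample Optional sample label stored in the profile.
#' @return A \code{smallrna_profile} with mirna_count and rpm set.
#' @export
quantify_pirnas <- function(reads, element_model, mirna_set = decoy_mirnas(),
                            min_len = 24L, max_len = 35L, max_mismatch = 0L,
                            sample = NA_character_) {
  if (inherits(reads, "smallrna_library")) reads <- reads$reads
  dem <- remove_mirnas(reads, mirna_set)
  kept <- size_filter(dem$reads, min_len, max_len)
  profile <- map_to_element(kept, element_model, max_mismatch)
  profile$mirna_count <- dem$mirna_count
  profile$rpm <- rpm_normalize(profile$total, dem$mirna_count)
  profile$sample <- sample
  profile
}

#' @export
print.smallrna_profile <- function(x, ...) {
  cat(sprintf("smallrna_profile%s: %d element reads (%d sense / %d antisense)",
              if (is.na(x$sample)) "" else paste0(" [", x$sample, "]"),
              x$total, sum(x$sense), sum(x$antisense)))
  if (!is.na(x$mirna_count)) {
    cat(sprintf(", %d miRNA reads, %.2f RPM", x$mirna_count, x$rpm))
  }
  cat("\n")
  invisible(x)
}

#' Positional profile as a data frame
#'
#' @param profile A \code{smallrna_profile}.
#' @return Data frame: position, sense, antisense (per consensus position).
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "smallrna_profile"))
  data.frame(position = seq_along(profile$sense),
             sense = profile$sense, antisense = profile$antisense)
}
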