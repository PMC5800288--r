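# Insertion-site calling from paired-end junction reads: element-anchored
# flank extraction, seed-and-extend flank mapping, site consolidation,
# occupancy normalization and transcriptional-state assignment.

#' Extract genomic flanks from element-anchored junction read pairs
#'
#' A pair is kept only if one mate carries an exact match
#' (\code{>= min_element_match} bases) to a P-element terminus on either
#' strand. Because the element's 31-nt terminal inverted repeats make the
#' two termini identical over any window up to 31 bp, element orientation
#' is resolved by comparing up to 60 junction-proximal element bases
#' against the two possible terminal contexts; pairs whose element segment
#' lies entirely within the inverted repeat are discarded as
#' orientation-ambiguous. Element- and adapter-derived bases are trimmed;
#' flanks shorter than 20 bp are discarded.
#'
#' @param pairs Data frame with columns read1, read2.
#' @param element_model An \code{element_model}.
#' @param adapter Adapter sequence to trim after the flank.
#' @param min_element_match Minimum exact terminal element match (default 20).
#' @return Data frame: flank (junction-proximal end first), terminus
#'   ("E_suffix" when the element segment reads toward the consensus 3'
#'   terminus, "RC_suffix" toward the reverse-complement terminus), and the
#'   source row index \code{pair}.
#' @export
extract_junction_reads <- function(pairs, element_model,
                                   adapter = JUNCTION_ADAPTER,
                                   min_element_match = 20L) {
  stopifnot(inherits(element_model, "element_model"))
  cons <- element_model$consensus
  rc_cons <- revcomp(cons)
  m <- as.integer(min_element_match)
  ctx_len <- 60L
  ctx_e <- substr(cons, nchar(cons) - ctx_len + 1L, nchar(cons))
  ctx_rc <- substr(rc_cons, nchar(rc_cons) - ctx_len + 1L, nchar(rc_cons))
  motif_e <- substr(cons, nchar(cons) - m + 1L, nchar(cons))
  motif_rc <- substr(rc_cons, nchar(rc_cons) - m + 1L, nchar(rc_cons))

  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    hit <- NULL
    for (read in c(pairs$read1[i], pairs$read2[i])) {
      hit <- locate_junction(read, motif_e, motif_rc, ctx_e, ctx_rc, m, adapter)
      if (!is.null(hit)) break
    }
    if (!is.null(hit) && nchar(hit$flank) >= 20L) {
      out[[i]] <- data.frame(flank = hit$flank, terminus = hit$terminus,
                             pair = i, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(flank = character(0), terminus = character(0),
                      pair = integer(0), stringsAsFactors = FALSE)
  }
  res
}

# Find the element/genome junction in one read; NULL if absent/ambiguous.
locate_junction <- function(read, motif_e, motif_rc, ctx_e, ctx_rc, m, adapter) {
  same_motif <- motif_e == motif_rc   # true whenever m <= TIR length
  pos_e <- find_motif(read, motif_e)
  pos_rc <- if (same_motif) integer(0) else find_motif(read, motif_rc)
  if (length(pos_e) == 0 && length(pos_rc) == 0) return(NULL)

  # the true junction is at the end of the element segment: use the last
  # terminal-motif occurrence in the read
  cand <- c(pos_e, pos_rc)
  start <- max(cand)
  junction <- start + m - 1L  # last element base

  # orient by the longest available element context ending at the junction
  elem_seg_len <- junction  # element bases available in the read
  w <- min(60L, elem_seg_len)
  seg <- substr(read, junction - w + 1L, junction)
  match_e <- seg == substr(ctx_e, nchar(ctx_e) - w + 1L, nchar(ctx_e))
  match_rc <- seg == substr(ctx_rc, nchar(ctx_rc) - w + 1L, nchar(ctx_rc))
  if (match_e == match_rc) return(NULL)  # no match or ambiguous (within TIR)

  flank <- substr(read, junction + 1L, nchar(read))
  flank <- trim_adapter(flank, adapter)
  if (nchar(flank) == 0) return(NULL)
  list(flank = flank, terminus = if (match_e) "E_suffix" else "RC_suffix")
}

# Remove an adapter occurrence (seeded by its first 12 bases) and any
# partial adapter prefix at the read end.
trim_adapter <- function(seq, adapter) {
  seed <- substr(adapter, 1L, min(12L, nchar(adapter)))
  hit <- find_motif(seq, seed)
  if (length(hit) > 0) return(substr(seq, 1L, hit[1] - 1L))
  n <- nchar(seq)
  for (k in seq(min(11L, n), 1L)) {
    if (substr(seq, n - k + 1L, n) == substr(adapter, 1L, k)) {
      return(substr(seq, 1L, n - k))
    }
  }
  seq
}

#' Map extracted flanks to the genome
#'
#' Exact lookup of the junction-proximal \code{k}-mer (both strands),
#' extended over the full flank allowing up to \code{max_mismatch}
#' mismatches. Flanks with several equally good loci are reported unmapped
#' (ambiguous), as are flanks shorter than \code{k}. The reported position
#' is the genome base adjacent to the element, so both junctions of one
#' insertion map to the same coordinate.
#'
#' @param flanks Data frame from \code{\link{extract_junction_reads}}, or a
#'   character vector of flank sequences.
#' @param genome A \code{genome_model}.
#' @param k Seed length (default 31).
#' @param max_mismatch Mismatches tolerated in the extension (default 2).
#' @return Data frame: flank row index, chrom, position, flank_strand,
#'   mapped (logical). Unmapped rows carry NA coordinates.
#' @export
map_flanks <- function(flanks, genome, k = 31L, max_mismatch = 2L) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.character(flanks)) {
    flanks <- data.frame(flank = flanks, terminus = NA_character_,
                         pair = seq_along(flanks), stringsAsFactors = FALSE)
  }
  n <- nrow(flanks)
  res <- data.frame(flank_idx = seq_len(n),
                    chrom = rep(NA_character_, n),
                    position = rep(NA_integer_, n),
                    flank_strand = rep(NA_character_, n),
                    mapped = rep(FALSE, n), stringsAsFactors = FALSE)
  if (n == 0) return(res)

  # map unique flank sequences once, then propagate
  uniq <- unique(flanks$flank)
  lookup <- lapply(uniq, map_one_flank, genome = genome, k = k,
                   max_mismatch = max_mismatch)
  names(lookup) <- uniq
  for (i in seq_len(n)) {
    hit <- lookup[[flanks$flank[i]]]
    if (!is.null(hit)) {
      res$chrom[i] <- hit$chrom
      res$position[i] <- hit$position
      res$flank_strand[i] <- hit$strand
      res$mapped[i] <- TRUE
    }
  }
  res
}

map_one_flank <- function(flank, genome, k, max_mismatch) {
  if (nchar(flank) < k) return(NULL)
  seed_fwd <- substr(flank, 1L, k)
  seed_rev <- revcomp(seed_fwd)
  flank_dna <- Biostrings::DNAString(flank)
  len <- nchar(flank)
  cands <- list()

  for (chrom in names(genome$chromosomes)) {
    subject <- Biostrings::DNAString(genome$chromosomes[[chrom]])
    # + strand: flank aligns left-to-right starting at the seed hit
    for (s in find_motif(genome$chromosomes[[chrom]], seed_fwd)) {
      if (s + len - 1L > length(subject)) next
      ref <- as.character(Biostrings::subseq(subject, s, s + len - 1L))
      mm <- count_mismatch(flank, ref)
      if (mm <= max_mismatch) {
        cands[[length(cands) + 1L]] <- list(chrom = chrom, position = s,
                                            strand = "+", mm = mm)
      }
    }
    # - strand: the flank's first base sits at the highest coordinate
    for (s in find_motif(genome$chromosomes[[chrom]], seed_rev)) {
      q <- s + k - 1L           # genome coord of the flank's first base
      if (q - len + 1L < 1L) next
      ref <- revcomp(as.character(Biostrings::subseq(subject, q - len + 1L, q)))
      mm <- count_mismatch(flank, ref)
      if (mm <= max_mismatch) {
        cands[[length(cands) + 1L]] <- list(chrom = chrom, position = q + 1L,
                                            strand = "-", mm = mm)
      }
    }
  }
  if (length(cands) == 0) return(NULL)
  mms <- vapply(cands, `[[`, numeric(1), "mm")
  best <- which(mms == min(mms))
  if (length(best) > 1L) return(NULL)  # ambiguous multi-mapper
  cands[[best]]
}

count_mismatch <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Consolidate mapped junction reads into insertion sites
#'
#' Mapped positions on the same chromosome with the same element
#' orientation lying within \code{merge_window} of each other are merged
#' into a single site located at the read-weighted modal position (ties
#' broken toward the smaller coordinate); supporting-read counts are
#' summed.
#'
#' @param mapped Data frame with columns chrom, position, element_strand
#'   (one row per mapped read).
#' @param merge_window Maximum gap (bp) merged into one site (default 10).
#' @return Data frame of class columns: site_id, chrom, position,
#'   element_strand, count.
#' @export
cluster_sites <- function(mapped, merge_window = 10L) {
  mapped <- mapped[!is.na(mapped$position), , drop = FALSE]
  if (nrow(mapped) == 0) {
    return(data.frame(site_id = character(0), chrom = character(0),
                      position = integer(0), element_strand = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  mapped <- mapped[order(mapped$chrom, mapped$element_strand, mapped$position), ]
  groups <- split(mapped, paste(mapped$chrom, mapped$element_strand))
  sites <- list()
  for (g in groups) {
    pos <- g$position
    brk <- c(0L, which(diff(pos) > merge_window), length(pos))
    for (j in seq_len(length(brk) - 1L)) {
      chunk <- pos[(brk[j] + 1L):brk[j + 1L]]
      tab <- table(chunk)
      modal <- as.integer(names(tab)[which.max(tab)])  # ties -> smallest
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = g$chrom[1], position = modal,
        element_strand = g$element_strand[1],
        count = length(chunk), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, sites)
  out <- out[order(out$chrom, out$position, out$element_strand), , drop = FALSE]
  out <- cbind(site_id = sprintf("site%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Occupancy normalization of called sites
#'
#' Divides each site's supporting-read count by the total element-supporting
#' reads over all called sites; the resulting occupancies sum to 1.
#'
#' @param sites Site table from \code{\link{cluster_sites}}.
#' @return The table with an \code{occupancy} column added.
#' @export
compute_occupancy <- function(sites) {
  total <- sum(sites$count)
  if (is.na(total) || total <= 0) stop("no supporting reads: cannot normalize occupancy")
  sites$occupancy <- sites$count / total
  sites
}

#' Assign transcriptional region state to sites
#'
#' A site is \code{active} when the covering transcription-track interval
#' has score > 0, \code{silent} when the score is 0, and \code{unknown}
#' when no interval covers its position.
#'
#' @param sites Site table with chrom and position columns.
#' @param genome A \code{genome_model}.
#' @return The table with a \code{region_state} column added.
#' @export
assign_region_state <- function(sites, genome) {
  stopifnot(inherits(genome, "genome_model"))
  sites$region_state <- rep("unknown", nrow(sites))
  if (nrow(sites) == 0 || nrow(genome$track) == 0) return(sites)
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$position, sites$position))
  gr_track <- track_granges(genome)
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_track, select = "first")
  covered <- !is.na(hits)
  score <- S4Vectors::mcols(gr_track)$score[hits[covered]]
  sites$region_state[covered] <- ifelse(score > 0, "active", "silent")
  sites
}

#' Read-weighted region-state fractions
#'
#' Percentages of element-supporting reads falling in active, silent and
#' unknown regions; the three components sum to 100.
#'
#' @param sites Site table with count and region_state columns.
#' @return Named numeric vector (active, silent, unknown), in percent.
#' @export
region_state_fractions <- function(sites) {
  stopifnot(nrow(sites) >= 1, "region_state" %in% names(sites))
  total <- sum(sites$count)
  if (total <= 0) stop("no supporting reads")
  f <- function(state) 100 * sum(sites$count[sites$region_state == state]) / total
  c(active = f("active"), silent = f("silent"), unknown = f("unknown"))
}

#' Call insertion sites from a junction read-pair table
#'
#' End-to-end caller: flank extraction, mapping, site consolidation,
#' occupancy normalization and region-state assignment. Element orientation
#' is derived from the terminal context and the flank's mapping strand: a
#' read whose element segment runs toward the consensus 3' terminus
#' ("E_suffix") implies the element lies on the same strand as its mapped
#' flank; a reverse-complement-terminus read implies the opposite strand.
#'
#' @param pairs Data frame with read1/read2 columns (or a
#'   \code{junction_library}, whose pair table is used).
#' @param genome A \code{genome_model}.
#' @param element_model An \code{element_model}.
#' @param adapter Adapter sequence.
#' @param min_element_match Minimum terminal element match (default 20).
#' @param k Mapping seed length (default 31).
#' @param max_mismatch Extension mismatch tolerance (default 2).
#' @param merge_window Site merge window (default 10).
#' @return Site table: site_id, chrom, position, element_strand, count,
#'   occupancy, region_state.
#' @export
call_insertions <- function(pairs, genome, element_model,
                            adapter = JUNCTION_ADAPTER,
                            min_element_match = 20L, k = 31L,
                            max_mismatch = 2L, merge_window = 10L) {
  if (inherits(pairs, "junction_library")) pairs <- pairs$pairs
  flanks <- extract_junction_reads(pairs, element_model, adapter, min_element_match)
  mapped <- map_flanks(flanks, genome, k, max_mismatch)
  keep <- mapped$mapped
  mapped <- mapped[keep, , drop = FALSE]
  terminus <- flanks$terminus[keep]
  mapped$element_strand <- ifelse(terminus == "E_suffix",
                                  mapped$flank_strand,
                                  opposite_strand(mapped$flank_strand))
  sites <- cluster_sites(mapped, merge_window)
  if (nrow(sites) == 0) return(sites)
  sites <- compute_occupancy(sites)
  assign_region_state(sites, genome)
}
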