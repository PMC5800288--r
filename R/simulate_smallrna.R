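# Small-RNA read simulator: element-derived piRNAs from cluster-embedded
# insertions, a decoy miRNA population (the RPM denominator) and random
# degradation fragments. Reads are emitted adapter-trimmed, i.e. at their
# RNA length (all <= 50 nt, the sequencing read length).

#' Load the bundled synthetic decoy miRNA set
#'
#' Synthetic 21-23 nt sequences standing in for the miRNA complement used
#' as the RPM normalization denominator (and, by extension, for the other
#' functional-RNA fragments removed before piRNA quantification).
#'
#' @return Named character vector of miRNA sequences.
#' @export
decoy_mirnas <- function() {
  path <- system.file("extdata", "synthetic_decoy_mirnas.fasta",
                      package = "zygopir", mustWork = TRUE)
  xs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(xs), names(xs))
}

#' Simulate a small-RNA library for one line
#'
#' Element-derived piRNAs are produced only by cluster-embedded insertions.
#' For a unistrand cluster the precursor transcript yields piRNAs antisense
#' to the element when the element opposes precursor transcription (the
#' predominant configuration) and sense piRNAs otherwise; cleavage-derived
#' sense piRNAs are added at \code{sense_fraction} of the antisense yield.
#' Dual-strand clusters produce both strands at the full rate. Per-insertion
#' yields are Poisson with mean \code{pirna_rate(rank)} scaled by occupancy;
#' piRNA lengths are uniform on 24-35 nt and windows are drawn only from
#' consensus segments present in the inserted variant, so every read maps
#' exactly back to the consensus. Embryo mode multiplies piRNA rates by
#' \code{embryo_scale} and draws \code{embryo_mirna_factor} times more
#' miRNA reads, emulating the near-absence of zygotic piRNAs against the
#' large maternal miRNA pool immediately after fertilization.
#'
#' @param genome A \code{genome_model}.
#' @param insertions Planted insertions.
#' @param element_model An \code{element_model}.
#' @param pirna_rate Function(rank) giving the expected antisense piRNA
#'   yield of an occupancy-1 insertion in the cluster of that activity
#'   rank; default 2000 reads for active (top-15) clusters, 200 otherwise.
#' @param sense_fraction Cleavage-derived sense production as a fraction of
#'   antisense production in unistrand clusters (default 0.5).
#' @param n_mirna_reads miRNA reads drawn from the decoy set (default 2e5).
#' @param n_junk_reads Random genomic degradation fragments, 18-50 nt.
#' @param embryo_mode Logical; apply embryo scaling.
#' @param embryo_scale piRNA rate multiplier in embryo mode (default 5e-4).
#' @param embryo_mirna_factor miRNA multiplier in embryo mode (default 5).
#' @param mirna_set Decoy miRNA sequences (default bundled set).
#' @param seed Integer seed.
#' @return List of class \code{smallrna_library}: \code{reads} (character
#'   vector) and \code{truth} (per-insertion sense/antisense counts, totals,
#'   n_mirna, n_junk, expected RPM, seed, params).
#' @export
simulate_small_rnas <- function(genome, insertions, element_model,
                                pirna_rate = function(rank) ifelse(rank <= 15, 2000, 200),
                                sense_fraction = 0.5,
                                n_mirna_reads = 2e5,
                                n_junk_reads = 1000L,
                                embryo_mode = FALSE,
                                embryo_scale = 5e-4,
                                embryo_mirna_factor = 5,
                                mirna_set = decoy_mirnas(),
                                seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(element_model, "element_model"),
            sense_fraction >= 0)
  clusters <- annotate_clusters(genome$clusters)
  scale <- if (embryo_mode) embryo_scale else 1
  n_mirna <- as.integer(round(n_mirna_reads * if (embryo_mode) embryo_mirna_factor else 1))

  with_seed(seed, {
    reads <- character(0)
    truth_rows <- vector("list", max(1L, nrow(insertions)))

    membership <- if (nrow(insertions) > 0) {
      assign_membership(
        data.frame(chrom = insertions$chrom, position = insertions$position,
                   element_strand = insertions$strand, stringsAsFactors = FALSE),
        clusters)
    } else NULL

    for (i in seq_len(nrow(insertions))) {
      ins <- insertions[i, ]
      memb <- membership[i, ]
      n_sense <- 0L; n_anti <- 0L
      if (!is.na(memb$cluster_id)) {
        cl <- clusters[clusters$cluster_id == memb$cluster_id, ]
        base <- pirna_rate(cl$rank) * ins$occupancy * scale
        if (cl$strandness == "dual") {
          n_anti <- stats::rpois(1L, base)
          n_sense <- stats::rpois(1L, base)
        } else if (memb$cluster_orientation == "-") {
          # element antisense to precursor: precursor carries element
          # antisense sequence; cleavage adds sense piRNAs on top
          n_anti <- stats::rpois(1L, base)
          n_sense <- stats::rpois(1L, base * sense_fraction)
        } else {
          n_sense <- stats::rpois(1L, base)
        }
        reads <- c(reads,
                   draw_pirna_reads(element_model, ins$variant, n_sense, "sense"),
                   draw_pirna_reads(element_model, ins$variant, n_anti, "antisense"))
      }
      truth_rows[[i]] <- data.frame(
        insertion_id = ins$insertion_id,
        cluster_id = memb$cluster_id %||% NA_character_,
        n_sense = n_sense, n_antisense = n_anti, stringsAsFactors = FALSE
      )
    }
    truth_ins <- if (nrow(insertions) > 0) do.call(rbind, truth_rows) else
      data.frame(insertion_id = character(0), cluster_id = character(0),
                 n_sense = integer(0), n_antisense = integer(0),
                 stringsAsFactors = FALSE)

    mirna_reads <- if (n_mirna > 0)
      unname(mirna_set[sample.int(length(mirna_set), n_mirna, replace = TRUE)])
    else character(0)

    junk_reads <- character(0)
    if (n_junk_reads > 0) {
      lens <- nchar(genome$chromosomes)
      junk_reads <- vapply(seq_len(n_junk_reads), function(b) {
        chrom <- sample(names(lens), 1L)
        len <- sample_int_range(18L, 50L)
        start <- sample_int_range(1L, lens[[chrom]] - len)
        substr(genome$chromosomes[[chrom]], start, start + len - 1L)
      }, character(1))
    }

    all_reads <- sample(c(reads, mirna_reads, junk_reads))  # shuffled
  })

  total_sense <- sum(truth_ins$n_sense)
  total_anti <- sum(truth_ins$n_antisense)
  structure(list(
    reads = all_reads,
    truth = list(insertions = truth_ins,
                 total_sense = total_sense, total_antisense = total_anti,
                 total_element = total_sense + total_anti,
                 n_mirna = n_mirna, n_junk = as.integer(n_junk_reads),
                 expected_rpm = if (n_mirna > 0)
                   (total_sense + total_anti) * 1e6 / n_mirna else NA_real_,
                 seed = seed,
                 params = list(sense_fraction = sense_fraction,
                               embryo_mode = embryo_mode,
                               embryo_scale = embryo_scale))
  ), class = "smallrna_library")
}

# Draw n piRNA-length windows from the variant's consensus segments;
# antisense reads are reverse complements. Windows never span a deletion
# junction, so each read has an exact consensus match; they also avoid the
# terminal inverted repeats, whose reads are strand-ambiguous by
# construction (a tail-derived antisense read is identical to a
# head-derived sense read).
draw_pirna_reads <- function(element_model, variant, n, strand) {
  if (n == 0) return(character(0))
  cons <- element_model$consensus
  dels <- element_model$variants[[variant]]
  segs <- present_segments(nchar(cons), dels)
  tir <- element_model$tir_length
  segs$start <- pmax(segs$start, tir + 1L)
  segs$end <- pmin(segs$end, nchar(cons) - tir)
  segs <- segs[segs$start <= segs$end, , drop = FALSE]
  lens <- sample(24:35, n, replace = TRUE)
  reads <- vapply(seq_len(n), function(j) {
    L <- lens[j]
    ok <- segs[segs$end - segs$start + 1L >= L, , drop = FALSE]
    if (nrow(ok) == 0) stop("variant too short for a ", L, "-nt read")
    w <- ok[sample.int(nrow(ok), 1L, prob = ok$end - ok$start + 1L), ]
    s <- sample_int_range(w$start, w$end - L + 1L)
    substr(cons, s, s + L - 1L)
  }, character(1))
  if (strand == "antisense") revcomp(reads) else reads
}

# Consensus intervals retained by a variant's deletions.
present_segments <- function(len, dels) {
  if (is.null(dels) || nrow(dels) == 0) {
    return(data.frame(start = 1L, end = len))
  }
  dels <- dels[order(dels[, 1]), , drop = FALSE]
  starts <- c(1L, dels[, 2] + 1L)
  ends <- c(dels[, 1] - 1L, len)
  keep <- starts <= ends
  data.frame(start = starts[keep], end = ends[keep])
}

#' Write a small-RNA library as single-end FASTQ
#'
#' @param library A \code{smallrna_library}.
#' @param path Output FASTQ path.
#' @return Invisibly, the path.
#' @export
write_smallrna_fastq <- function(library, path) {
  stopifnot(inherits(library, "smallrna_library"))
  write_fastq(library$reads, sprintf("sr%07d", seq_along(library$reads)), path)
  invisible(path)
}
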