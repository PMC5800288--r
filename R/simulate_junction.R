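# Junction-library simulator: restriction digestion of a pooled fly line,
# adapter ligation at the genomic cut, element-side anchoring (the nested
# PCR step is reproduced by size selection plus anchoring, not simulated
# base by base) and paired-end sequencing of the element/genome junctions.

JUNCTION_ADAPTER <- "ACACTCTTTCCCTACACGACGCTCTTCCGA"  # fixed bundled 30-mer

#' Simulate a paired-end P-element junction library for one pooled line
#'
#' Each of \code{pool_size} individuals carries each planted insertion
#' independently with probability equal to its occupancy. For every carried
#' insertion, both element/genome junctions are digested with each enzyme:
#' the restriction fragment runs from the nearest site inside the element,
#' across the junction, to the nearest site in the flanking genome, and is
#' adapter-ligated at the genomic cut. Fragments outside \code{size_range}
#' are discarded (gel size selection). The sequenced template models the
#' nested element-specific PCR: it begins at an element primer
#' \code{primer_offset} bases from the terminus (a junction is amplifiable
#' only when its internal restriction cut lies at least that far inside the
#' element) and ends at the adapter. Read 1 starts at the element-side end
#' of the template; read 2 is the reverse complement of the other end; both
#' are truncated at the template end when shorter than \code{read_length}.
#' Substitution errors are applied uniformly at \code{error_rate}.
#'
#' @param genome A \code{genome_model}.
#' @param insertions Planted insertions (see \code{\link{plant_insertions}}).
#' @param element_model An \code{element_model}.
#' @param enzymes Restriction recognition sequences (defaults HhaI = GCGC,
#'   TaqI = TCGA).
#' @param read_length Read length (bp), default 250.
#' @param pool_size Number of pooled individuals, default 40.
#' @param mean_depth_per_individual Expected read pairs per junction
#'   fragment per carrying individual (Poisson).
#' @param size_range Restriction-fragment size-selection window (bp),
#'   default 300-600.
#' @param primer_offset Distance (bp) from the element-specific nested
#'   primer to the element terminus; the sequenced template carries exactly
#'   this much element sequence before the junction (default 100).
#' @param error_rate Per-base substitution error probability.
#' @param adapter Adapter sequence ligated at the genomic cut.
#' @param n_background_pairs Element-free genomic read pairs added as
#'   background noise.
#' @param seed Integer seed.
#' @return List of class \code{junction_library}: \code{pairs} (data.frame
#'   read1, read2, insertion_id with "background" for noise pairs) and
#'   \code{truth} (per-insertion data.frame: insertion_id, n_fragments
#'   passing size selection, n_carriers, n_pairs emitted, n_recoverable
#'   pairs whose element-anchored mate exposes the junction plus >= 20 bp
#'   of flank, n_mappable pairs additionally exposing the >= 31 bp of
#'   flank needed to seed the mapper; plus the call parameters and seed).
#' @export
simulate_junction_library <- function(genome, insertions, element_model,
                                      enzymes = c("GCGC", "TCGA"),
                                      read_length = 250L,
                                      pool_size = 40L,
                                      mean_depth_per_individual = 2,
                                      size_range = c(300L, 600L),
                                      primer_offset = 100L,
                                      error_rate = 0,
                                      adapter = JUNCTION_ADAPTER,
                                      n_background_pairs = 0L,
                                      seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(element_model, "element_model"),
            read_length >= 50L, pool_size >= 1L, error_rate >= 0, error_rate < 1,
            size_range[1] <= size_range[2])

  with_seed(seed, {
    truth_rows <- vector("list", nrow(insertions))
    read1 <- character(0); read2 <- character(0); origin <- character(0)

    for (i in seq_len(nrow(insertions))) {
      ins <- insertions[i, ]
      frags <- junction_fragments(genome, ins, element_model, enzymes,
                                  size_range, primer_offset)
      n_carriers <- sum(stats::runif(pool_size) < ins$occupancy)
      n_pairs <- 0L; n_recoverable <- 0L; n_mappable <- 0L
      n_frag_mappable <- 0L
      for (fr in frags) {
        # recoverable: junction and >= 20 bp of flank visible in read 1,
        # plus enough element sequence to anchor and orient (> TIR length);
        # mappable additionally needs >= 31 bp of flank to seed the mapper.
        # Both are deterministic properties of the fragment.
        flank_in_r1 <- max(0L, min(read_length, nchar(fr$seq)) - fr$elem_len)
        is_recov <- fr$elem_len > element_model$tir_length && flank_in_r1 >= 20L
        is_map <- is_recov && flank_in_r1 >= 31L
        if (is_map) n_frag_mappable <- n_frag_mappable + 1L
        n <- stats::rpois(1L, n_carriers * mean_depth_per_individual)
        if (n > 0) {
          template <- paste0(fr$seq, adapter)
          r1 <- substr(template, 1L, min(read_length, nchar(template)))
          r2 <- revcomp(substr_safe(template, nchar(template) - read_length + 1L,
                                    nchar(template)))
          read1 <- c(read1, rep(r1, n))
          read2 <- c(read2, rep(r2, n))
          origin <- c(origin, rep(ins$insertion_id, n))
          n_pairs <- n_pairs + n
          if (is_recov) n_recoverable <- n_recoverable + n
          if (is_map) n_mappable <- n_mappable + n
        }
      }
      truth_rows[[i]] <- data.frame(
        insertion_id = ins$insertion_id, chrom = ins$chrom,
        position = ins$position, strand = ins$strand,
        occupancy = ins$occupancy, n_fragments = length(frags),
        n_fragments_mappable = n_frag_mappable,
        n_carriers = n_carriers, n_pairs = n_pairs,
        n_recoverable = n_recoverable, n_mappable = n_mappable,
        stringsAsFactors = FALSE
      )
    }

    if (n_background_pairs > 0) {
      lens <- nchar(genome$chromosomes)
      for (b in seq_len(n_background_pairs)) {
        chrom <- sample(names(lens), 1L)
        len <- sample_int_range(size_range[1], size_range[2])
        start <- sample_int_range(1L, lens[[chrom]] - len)
        frag <- substr(genome$chromosomes[[chrom]], start, start + len - 1L)
        template <- paste0(frag, adapter)
        read1 <- c(read1, substr(template, 1L, min(read_length, nchar(template))))
        read2 <- c(read2, revcomp(substr_safe(template,
                                              nchar(template) - read_length + 1L,
                                              nchar(template))))
        origin <- c(origin, "background")
      }
    }

    if (error_rate > 0 && length(read1) > 0) {
      read1 <- add_substitution_errors(read1, error_rate)
      read2 <- add_substitution_errors(read2, error_rate)
    }
  })

  truth <- do.call(rbind, truth_rows) %||%
    data.frame(insertion_id = character(0), n_pairs = integer(0))
  structure(list(
    pairs = data.frame(read1 = read1, read2 = read2, insertion_id = origin,
                       stringsAsFactors = FALSE),
    truth = list(insertions = truth, seed = seed,
                 params = list(enzymes = enzymes, read_length = read_length,
                               pool_size = pool_size,
                               mean_depth_per_individual = mean_depth_per_individual,
                               size_range = size_range,
                               primer_offset = primer_offset,
                               error_rate = error_rate,
                               adapter = adapter,
                               n_background_pairs = n_background_pairs))
  ), class = "junction_library")
}

# All size-selected, amplifiable junction templates of one insertion. Each
# is returned oriented from the element side: exactly primer_offset element
# bases ending at the terminus (a suffix of the inserted sequence or of its
# reverse complement), then the genomic flank read away from the junction.
# Size selection applies to the underlying restriction fragment; the
# template requires the internal cut to lie beyond the nested primer.
junction_fragments <- function(genome, ins, element_model, enzymes,
                               size_range, primer_offset = 100L) {
  chrom_seq <- genome$chromosomes[[ins$chrom]]
  elem <- variant_sequence(element_model, ins$variant)
  inserted <- if (ins$strand == "+") elem else revcomp(elem)
  p <- ins$position  # element sits between p-1 and p
  out <- list()
  window <- 5000L    # flank search window; fragments longer than this are
                     # far beyond any size-selection window

  for (enz in enzymes) {
    sites_elem <- find_motif(inserted, enz)
    if (length(sites_elem) == 0) next

    # Right junction: restriction fragment from the last internal cut to
    # the first site downstream of the junction; template starts at the
    # element primer primer_offset bases before the terminus.
    cut <- max(sites_elem) + nchar(enz)  # first base after the motif
    elem_r <- nchar(inserted) - cut + 1L # element bases in the fragment
    right_flank_window <- substr_safe(chrom_seq, p, p + window)
    fs <- find_motif(right_flank_window, enz)
    if (length(fs) > 0 && elem_r >= primer_offset) {
      flank <- substr(right_flank_window, 1L, fs[1] - 1L)
      frag_len <- elem_r + nchar(flank)
      if (frag_len >= size_range[1] && frag_len <= size_range[2]) {
        elem_part <- substr(inserted, nchar(inserted) - primer_offset + 1L,
                            nchar(inserted))
        out[[length(out) + 1L]] <- list(seq = paste0(elem_part, flank),
                                        elem_len = primer_offset,
                                        frag_len = frag_len,
                                        side = "right", enzyme = enz)
      }
    }

    # Left junction: restriction fragment from the first site upstream of
    # the junction to the first internal cut; template read from the
    # element side is revcomp(element prefix) + revcomp(left flank).
    cut_end <- min(sites_elem) - 1L  # last element base before the motif
    left_window_start <- max(1L, p - 1L - window)
    left_flank_window <- substr_safe(chrom_seq, left_window_start, p - 1L)
    fs <- find_motif(left_flank_window, enz)
    if (length(fs) > 0 && cut_end >= primer_offset) {
      flank_fwd <- substr_safe(left_flank_window,
                               max(fs) + nchar(enz), nchar(left_flank_window))
      frag_len <- cut_end + nchar(flank_fwd)
      if (frag_len >= size_range[1] && frag_len <= size_range[2]) {
        elem_part <- revcomp(substr(inserted, 1L, primer_offset))
        out[[length(out) + 1L]] <- list(seq = paste0(elem_part, revcomp(flank_fwd)),
                                        elem_len = primer_offset,
                                        frag_len = frag_len,
                                        side = "left", enzyme = enz)
      }
    }
  }
  out
}

# Uniform substitution errors over a character vector of reads.
add_substitution_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(stats::runif(n) < rate)
    if (length(hit) == 0) return(r)
    chars <- strsplit(r, "", fixed = TRUE)[[1]]
    for (j in hit) {
      chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write a junction library as paired FASTQ files
#'
#' @param library A \code{junction_library}.
#' @param prefix Output path prefix; files \code{<prefix>_R1.fastq} and
#'   \code{<prefix>_R2.fastq} are written.
#' @return Invisibly, the two file paths.
#' @export
write_junction_fastq <- function(library, prefix) {
  stopifnot(inherits(library, "junction_library"))
  ids <- sprintf("pair%06d %s", seq_len(nrow(library$pairs)), library$pairs$insertion_id)
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  write_fastq(library$pairs$read1, ids, paths[1])
  write_fastq(library$pairs$read2, ids, paths[2])
  invisible(paths)
}

# FASTQ writer on top of Biostrings (constant Q40 qualities).
write_fastq <- function(reads, ids, path) {
  xs <- Biostrings::DNAStringSet(reads)
  names(xs) <- ids
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(xs, path, format = "fastq", qualities = quals)
}

#' Read paired FASTQ junction files back into a pair table
#'
#' @param r1_path,r2_path Paths to the two mate files.
#' @return Data frame with columns read1, read2.
#' @export
read_junction_fastq <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  stopifnot(length(r1) == length(r2))
  data.frame(read1 = as.character(r1), read2 = as.character(r2),
             stringsAsFactors = FALSE)
}
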