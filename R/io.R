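# File interfaces for the genome model and annotation tables: FASTA via
# Biostrings, clusters as BED6+3 (extra columns: sense percentage,
# cluster-unique piRNA count, activity rank), transcription track as
# BED-with-score, sites as BED6 + TSV.

#' Write genome chromosomes as FASTA
#' @param genome A \code{genome_model}.
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  xs <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read genome chromosomes from FASTA
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(xs), sub("\\s.*$", "", names(xs)))
}

#' Write piRNA clusters as BED6+3
#'
#' Columns: chrom, 0-based start, end, cluster id, score (unique-piRNA
#' count), precursor strand, then sense percentage, unique-piRNA count and
#' activity rank (0 when not yet ranked).
#'
#' @param clusters Cluster data.frame (1-based inclusive coordinates).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_clusters_bed <- function(clusters, path) {
  bed <- data.frame(
    chrom = clusters$chrom,
    start = clusters$start - 1L,   # BED is 0-based half-open
    end = clusters$end,
    name = clusters$cluster_id,
    score = clusters$unique_pirnas,
    strand = clusters$precursor_strand,
    sense_pct = clusters$sense_pct,
    unique_pirnas = clusters$unique_pirnas,
    rank = if ("rank" %in% names(clusters)) clusters$rank else 0L
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read piRNA clusters from BED6+3
#'
#' Uses rtracklayer's BED reader with the three extra columns when
#' available, falling back to a plain tab read otherwise.
#'
#' @param path BED6+3 path written by \code{\link{write_clusters_bed}}.
#' @return Cluster data.frame with 1-based inclusive coordinates.
#' @export
read_clusters_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(sense_pct = "numeric",
                                            unique_pirnas = "integer",
                                            rank = "integer"))
    df <- data.frame(
      cluster_id = S4Vectors::mcols(gr)$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      sense_pct = S4Vectors::mcols(gr)$sense_pct,
      unique_pirnas = S4Vectors::mcols(gr)$unique_pirnas,
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    df <- data.frame(cluster_id = raw[[4]], chrom = raw[[1]],
                     start = raw[[2]] + 1L, end = raw[[3]],
                     sense_pct = raw[[7]], unique_pirnas = raw[[8]],
                     stringsAsFactors = FALSE)
  }
  df$antisense_pct <- 100 - df$sense_pct
  df$precursor_strand <- ifelse(df$sense_pct >= df$antisense_pct, "+", "-")
  df
}

#' Write the transcription track as BED with score
#' @param track Track data.frame (chrom, start, end, score; 1-based).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_track_bed <- function(track, path) {
  bed <- data.frame(chrom = track$chrom, start = track$start - 1L,
                    end = track$end,
                    name = sprintf("seg%05d", seq_len(nrow(track))),
                    score = track$score, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write called insertion sites as BED6 plus an annotation TSV
#'
#' The BED name column carries the site id and the score column the
#' supporting-read count; the TSV adds occupancy, region state and cluster
#' annotation columns.
#'
#' @param sites Annotated site table.
#' @param bed_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the written paths.
#' @export
write_sites <- function(sites, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = sites$chrom, start = sites$position - 1L,
                      end = sites$position, name = sites$site_id,
                      score = sites$count, strand = sites$element_strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(sites, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}
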