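# Synthetic genome model: chromosomes, piRNA-cluster annotation and a
# transcription track with expression scores. Coordinates are 1-based
# inclusive in every user-facing table; interval arithmetic is delegated
# to IRanges/GenomicRanges.

#' Generate a synthetic multi-chromosome genome with piRNA-cluster and
#' transcription-track annotation
#'
#' Chromosomes are seeded random nucleotide sequences (restriction sites
#' therefore occur at the ~4^-4 density expected of a 4-letter alphabet,
#' giving realistic restriction-fragment length variation). Clusters are
#' non-overlapping intervals with randomized sense/antisense piRNA strand
#' fractions and distinct cluster-unique piRNA counts. The transcription
#' track tiles each chromosome with alternating expressed (score > 0) and
#' silent (score = 0) intervals, emulating a tissue expression track.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_clusters Number of piRNA clusters to place.
#' @param paper_emulation If \code{TRUE}, place exactly 142 clusters (the
#'   number of annotated piRNA clusters in the D. melanogaster genome),
#'   overriding \code{n_clusters}.
#' @param cluster_length_range Length range (bp) from which cluster sizes
#'   are drawn uniformly.
#' @param track_segment_range Length range (bp) of transcription-track
#'   segments.
#' @param seed Integer seed.
#' @return Object of class \code{genome_model}: list with
#'   \code{chromosomes} (named character vector), \code{clusters}
#'   (data.frame: cluster_id, chrom, start, end, sense_pct, antisense_pct,
#'   unique_pirnas, precursor_strand) and \code{track} (data.frame: chrom,
#'   start, end, score).
#' @export
make_genome <- function(n_chromosomes = 5L, chrom_length = 1e6, n_clusters = 30L,
                        paper_emulation = FALSE,
                        cluster_length_range = c(2000L, 10000L),
                        track_segment_range = c(5000L, 50000L),
                        seed = 1L) {
  if (paper_emulation) n_clusters <- 142L
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_length <- as.integer(chrom_length)
  stopifnot(n_chromosomes >= 1L, chrom_length >= 1000L, n_clusters >= 0L)

  with_seed(seed, {
    chroms <- vapply(seq_len(n_chromosomes), function(i) rand_dna(chrom_length),
                     character(1))
    names(chroms) <- paste0("chr", seq_len(n_chromosomes))

    clusters <- place_clusters(names(chroms), chrom_length, n_clusters,
                               cluster_length_range)
    track <- make_track(names(chroms), chrom_length, track_segment_range)
  })

  gm <- structure(list(chromosomes = chroms, clusters = clusters, track = track),
                  class = "genome_model")
  validate_genome(gm)
  gm
}

# Non-overlapping cluster placement by rejection sampling; fails explicitly
# when the requested clusters cannot be placed.
place_clusters <- function(chrom_ids, chrom_length, n_clusters, length_range) {
  empty <- data.frame(cluster_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      sense_pct = numeric(0), antisense_pct = numeric(0),
                      unique_pirnas = integer(0), precursor_strand = character(0),
                      stringsAsFactors = FALSE)
  if (n_clusters == 0L) return(empty)
  if (n_clusters * min(length_range) > length(chrom_ids) * chrom_length) {
    stop("cannot place ", n_clusters, " clusters: total cluster length exceeds genome size")
  }
  placed <- vector("list", n_clusters)
  occupied <- lapply(chrom_ids, function(x) IRanges::IRanges())
  names(occupied) <- chrom_ids
  attempts <- 0L
  max_attempts <- 1000L * n_clusters
  i <- 1L
  while (i <= n_clusters) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("cluster placement failed after ", max_attempts,
           " attempts; genome too small for ", n_clusters, " clusters")
    }
    len <- sample_int_range(length_range[1], length_range[2])
    chrom <- if (length(chrom_ids) == 1L) chrom_ids else sample(chrom_ids, 1L)
    if (len >= chrom_length) next
    start <- sample.int(chrom_length - len, 1L)
    cand <- IRanges::IRanges(start = start, end = start + len - 1L)
    if (length(IRanges::findOverlaps(cand, occupied[[chrom]])) > 0) next
    occupied[[chrom]] <- c(occupied[[chrom]], cand)
    placed[[i]] <- list(chrom = chrom, start = start, end = start + len - 1L)
    i <- i + 1L
  }
  sense_pct <- round(stats::runif(n_clusters, 0, 100), 1)
  df <- data.frame(
    cluster_id = sprintf("pic%03d", seq_len(n_clusters)),
    chrom = vapply(placed, `[[`, character(1), "chrom"),
    start = vapply(placed, function(p) as.integer(p$start), integer(1)),
    end = vapply(placed, function(p) as.integer(p$end), integer(1)),
    sense_pct = sense_pct,
    antisense_pct = 100 - sense_pct,
    unique_pirnas = sample.int(1e6, n_clusters),  # distinct by construction
    stringsAsFactors = FALSE
  )
  # Precursor strand: the strand carrying the majority of cluster piRNAs.
  df$precursor_strand <- ifelse(df$sense_pct >= df$antisense_pct, "+", "-")
  df[order(df$chrom, df$start), , drop = FALSE]
}

# Alternating expressed/silent segments covering each chromosome end to end.
make_track <- function(chrom_ids, chrom_length, segment_range) {
  rows <- list()
  for (chrom in chrom_ids) {
    pos <- 1L
    expressed <- sample(c(TRUE, FALSE), 1L)
    while (pos <= chrom_length) {
      len <- sample_int_range(segment_range[1], segment_range[2])
      end <- min(chrom_length, pos + len - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = end,
        score = if (expressed) sample.int(100L, 1L) else 0L,
        stringsAsFactors = FALSE
      )
      pos <- end + 1L
      expressed <- !expressed
    }
  }
  do.call(rbind, rows)
}

#' Validate genome-model invariants
#'
#' Checks that cluster and track intervals lie within chromosome bounds,
#' that track intervals are non-overlapping per chromosome, and that
#' expression scores are non-negative.
#' @param genome A \code{genome_model}.
#' @return The genome, invisibly; errors on violation.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  lens <- nchar(genome$chromosomes)
  for (df in list(genome$clusters, genome$track)) {
    if (nrow(df) == 0) next
    stopifnot(all(df$chrom %in% names(genome$chromosomes)),
              all(df$start >= 1L),
              all(df$end <= lens[df$chrom]),
              all(df$start <= df$end))
  }
  if (nrow(genome$track) > 0) {
    stopifnot(all(genome$track$score >= 0))
    sp <- split(genome$track, genome$track$chrom)
    for (tr in sp) {
      ir <- IRanges::IRanges(tr$start, tr$end)
      if (any(IRanges::countOverlaps(ir, ir) > 1L)) {
        stop("transcription track intervals overlap on ", tr$chrom[1])
      }
    }
  }
  invisible(genome)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bp total, %d piRNA cluster(s), %d track interval(s)\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              nrow(x$clusters), nrow(x$track)))
  invisible(x)
}

# GRanges views of the annotation tables (internal).
clusters_granges <- function(genome) {
  df <- genome$clusters
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         cluster_id = df$cluster_id)
}

track_granges <- function(genome) {
  df <- genome$track
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         score = df$score)
}

#' Plant P-element insertions into a synthetic genome
#'
#' Each requested insertion is placed at a position satisfying its target
#' class: \code{in-cluster} (inside some piRNA cluster),
#' \code{active-region} (transcription-track score > 0),
#' \code{silent-region} (score = 0) or \code{uniform} (anywhere). Insertion
#' points are unique; element strand is drawn at random unless given.
#' Occupancy is the fraction of individuals of the pooled line carrying the
#' insertion (insertional polymorphism).
#'
#' @param genome A \code{genome_model}.
#' @param spec Data frame with columns \code{target_class},
#'   \code{variant}, \code{occupancy} and optionally \code{strand}.
#' @param margin Minimum distance (bp) from chromosome ends, so junction
#'   fragments always have flanking sequence to extend into.
#' @param seed Integer seed.
#' @return Data frame of planted insertions: insertion_id, chrom, position
#'   (1-based point; the element sits between position-1 and position),
#'   strand, variant, occupancy, target_class.
#' @export
plant_insertions <- function(genome, spec, margin = 2000L, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  empty <- data.frame(insertion_id = character(0), chrom = character(0),
                      position = integer(0), strand = character(0),
                      variant = character(0), occupancy = numeric(0),
                      target_class = character(0), stringsAsFactors = FALSE)
  if (is.null(spec) || nrow(spec) == 0) return(empty)
  stopifnot(all(c("target_class", "variant", "occupancy") %in% names(spec)),
            all(spec$occupancy > 0 & spec$occupancy <= 1),
            all(spec$target_class %in% c("in-cluster", "active-region",
                                         "silent-region", "uniform")))
  lens <- nchar(genome$chromosomes)

  with_seed(seed, {
    taken <- character(0)
    rows <- vector("list", nrow(spec))
    for (i in seq_len(nrow(spec))) {
      cls <- spec$target_class[i]
      pos <- NULL
      for (try in seq_len(1000L)) {
        cand <- sample_position(genome, cls, margin, lens)
        key <- paste(cand$chrom, cand$position)
        if (!key %in% taken) { pos <- cand; taken <- c(taken, key); break }
      }
      if (is.null(pos)) stop("could not place a unique '", cls, "' insertion")
      strand <- if ("strand" %in% names(spec) && !is.na(spec$strand[i])) {
        spec$strand[i]
      } else sample(c("+", "-"), 1L)
      rows[[i]] <- data.frame(
        insertion_id = sprintf("ins%03d", i),
        chrom = pos$chrom, position = pos$position, strand = strand,
        variant = spec$variant[i], occupancy = spec$occupancy[i],
        target_class = cls, stringsAsFactors = FALSE
      )
    }
  })
  do.call(rbind, rows)
}

sample_position <- function(genome, target_class, margin, lens) {
  pick_interval <- function(df) {
    if (nrow(df) == 0) stop("no region of class '", target_class, "' in this genome")
    lo <- pmax(df$start, margin)
    hi <- pmin(df$end, lens[df$chrom] - margin)
    feasible <- which(lo <= hi)  # intervals admitting a margin-respecting point
    if (length(feasible) == 0) {
      stop("no placeable position in any '", target_class, "' interval")
    }
    j <- if (length(feasible) == 1L) feasible else sample(feasible, 1L)
    list(chrom = df$chrom[j], position = sample_int_range(lo[j], hi[j]))
  }
  switch(target_class,
    "in-cluster" = pick_interval(genome$clusters),
    "active-region" = pick_interval(genome$track[genome$track$score > 0, , drop = FALSE]),
    "silent-region" = pick_interval(genome$track[genome$track$score == 0, , drop = FALSE]),
    "uniform" = {
      ids <- names(genome$chromosomes)
      chrom <- if (length(ids) == 1L) ids else sample(ids, 1L)
      list(chrom = chrom, position = sample_int_range(margin, lens[[chrom]] - margin))
    },
    stop("unknown target class: ", target_class)
  )
}
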