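# piRNA-cluster classification and insertion-site cluster annotation:
# dual-strand vs unistrand calls from strand fractions, activity ranking by
# cluster-unique piRNA counts, membership/orientation assignment and
# cluster-read fractions.

#' Classify a piRNA cluster as dual-strand or unistrand
#'
#' A cluster is dual-stranded when both its sense and antisense piRNA
#' fractions strictly exceed 20.0 percent; otherwise it is unistrand with
#' the majority strand as precursor.
#'
#' @param sense_pct,antisense_pct Strand percentages; must sum to 100.
#' @param threshold Minor-strand percentage above which a cluster is
#'   dual-stranded (default 20).
#' @return "dual" or "uni".
#' @export
classify_strandness <- function(sense_pct, antisense_pct, threshold = 20) {
  if (abs(sense_pct + antisense_pct - 100) > 1e-6) {
    stop("sense and antisense percentages must sum to 100 (got ",
         sense_pct + antisense_pct, ")")
  }
  if (min(sense_pct, antisense_pct) > threshold) "dual" else "uni"
}

#' Annotate a cluster table with strandness, activity rank and precursor strand
#'
#' @param clusters Cluster data.frame (cluster_id, chrom, start, end,
#'   sense_pct, antisense_pct, unique_pirnas).
#' @param threshold Dual-strand minor-strand threshold (default 20).
#' @param n_active Number of top-ranked clusters labeled active (default 15).
#' @return The table with strandness, precursor_strand, rank and activity
#'   columns set.
#' @export
annotate_clusters <- function(clusters, threshold = 20, n_active = 15L) {
  if (nrow(clusters) == 0) {
    clusters$strandness <- character(0); clusters$rank <- integer(0)
    clusters$activity <- character(0)
    return(clusters)
  }
  clusters$strandness <- vapply(seq_len(nrow(clusters)), function(i)
    classify_strandness(clusters$sense_pct[i], clusters$antisense_pct[i], threshold),
    character(1))
  clusters$precursor_strand <- ifelse(clusters$sense_pct >= clusters$antisense_pct,
                                      "+", "-")
  rank_activity(clusters, n_active = n_active)
}

#' Rank clusters by cluster-unique piRNA count and label activity
#'
#' Stable descending sort by \code{unique_pirnas}; ties are broken by
#' lexicographic cluster id. Ranks 1..\code{n_active} are labeled
#' \code{active}, the rest \code{low}.
#'
#' @param clusters Cluster data.frame with unique_pirnas and cluster_id.
#' @param n_active Active-cluster cutoff (default 15, the top-15 rule).
#' @return The table with integer \code{rank} and \code{activity} columns.
#' @export
rank_activity <- function(clusters, n_active = 15L) {
  stopifnot("unique_pirnas" %in% names(clusters))
  ord <- order(-clusters$unique_pirnas, clusters$cluster_id)
  rank <- integer(nrow(clusters))
  rank[ord] <- seq_len(nrow(clusters))
  clusters$rank <- rank
  clusters$activity <- ifelse(rank <= n_active, "active", "low")
  clusters
}

#' Assign cluster membership and orientation to insertion sites
#'
#' A site whose insertion point lies within a cluster interval receives
#' that cluster's id (overlaps resolved toward the smallest interval). For
#' unistrand clusters the site's orientation relative to the precursor is
#' recorded ("+" = element sense to precursor transcription, "-" =
#' antisense); orientation is left NA for dual-strand clusters, whose both
#' strands are transcribed.
#'
#' @param sites Site table with chrom, position and element_strand columns.
#' @param clusters Annotated cluster table (see
#'   \code{\link{annotate_clusters}}).
#' @return The site table with cluster_id, cluster_strandness,
#'   cluster_activity and cluster_orientation columns added.
#' @export
assign_membership <- function(sites, clusters) {
  n <- nrow(sites)
  sites$cluster_id <- rep(NA_character_, n)
  sites$cluster_strandness <- rep(NA_character_, n)
  sites$cluster_activity <- rep(NA_character_, n)
  sites$cluster_orientation <- rep(NA_character_, n)
  if (nrow(sites) == 0 || nrow(clusters) == 0) return(sites)
  stopifnot(all(c("strandness", "activity") %in% names(clusters)))
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$position, sites$position))
  gr_clust <- GenomicRanges::GRanges(clusters$chrom,
                                     IRanges::IRanges(clusters$start, clusters$end))
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_clust)
  if (length(hits) == 0) return(sites)
  width <- clusters$end - clusters$start + 1L
  for (i in unique(S4Vectors::queryHits(hits))) {
    cand <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    j <- cand[order(width[cand], clusters$cluster_id[cand])][1]  # smallest interval
    sites$cluster_id[i] <- clusters$cluster_id[j]
    sites$cluster_strandness[i] <- clusters$strandness[j]
    sites$cluster_activity[i] <- clusters$activity[j]
    if (clusters$strandness[j] == "uni") {
      sites$cluster_orientation[i] <-
        ifelse(sites$element_strand[i] == clusters$precursor_strand[j], "+", "-")
    }
  }
  sites
}

#' Fraction of element-supporting reads falling in piRNA clusters
#'
#' @param sites Site table with count and cluster_id columns.
#' @return Percentage in [0, 100].
#' @export
cluster_read_fraction <- function(sites) {
  stopifnot(nrow(sites) >= 1, all(c("count", "cluster_id") %in% names(sites)))
  total <- sum(sites$count)
  if (total <= 0) stop("no supporting reads")
  100 * sum(sites$count[!is.na(sites$cluster_id)]) / total
}

#' Count insertion sites by cluster class
#'
#' Tabulates distinct in-cluster insertion sites by strandness and activity
#' of the host cluster; unistrand cells are additionally split by element
#' orientation relative to precursor transcription.
#'
#' @param sites Site table with membership columns (see
#'   \code{\link{assign_membership}}).
#' @return Data frame: strandness, activity, orientation (NA for
#'   dual-strand cells), n_sites. All class combinations are present, with
#'   zero counts where empty.
#' @export
count_by_class <- function(sites) {
  cells <- rbind(
    expand.grid(strandness = "dual", activity = c("active", "low"),
                orientation = NA_character_, stringsAsFactors = FALSE),
    expand.grid(strandness = "uni", activity = c("active", "low"),
                orientation = c("+", "-"), stringsAsFactors = FALSE)
  )
  inside <- sites[!is.na(sites$cluster_id), , drop = FALSE]
  cells$n_sites <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- inside$cluster_strandness == cells$strandness[i] &
      inside$cluster_activity == cells$activity[i]
    if (!is.na(cells$orientation[i])) {
      sel <- sel & !is.na(inside$cluster_orientation) &
        inside$cluster_orientation == cells$orientation[i]
    }
    sum(sel)
  }, integer(1))
  cells
}
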