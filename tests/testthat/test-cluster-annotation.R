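test_that("strandness follows the strict 20% rule", {
  expect_equal(classify_strandness(30, 70), "dual")
  expect_equal(classify_strandness(20.0, 80.0), "uni")   # strict inequality
  expect_equal(classify_strandness(20.1, 79.9), "dual")
  expect_equal(classify_strandness(0, 100), "uni")
  expect_error(classify_strandness(30, 60), "sum to 100")
})

test_that("activity ranking takes the top 15 with lexicographic tie-break", {
  mk <- function(n, counts) {
    data.frame(cluster_id = sprintf("pic%03d", seq_len(n)),
               chrom = "chr1", start = seq_len(n) * 100,
               end = seq_len(n) * 100 + 50,
               sense_pct = 50, antisense_pct = 50,
               unique_pirnas = counts, stringsAsFactors = FALSE)
  }
  cl30 <- rank_activity(mk(30, sample(1000:2000, 30)))
  expect_equal(sum(cl30$activity == "active"), 15)
  expect_equal(sort(cl30$rank), 1:30)
  expect_equal(cl30$cluster_id[cl30$rank == 1],
               cl30$cluster_id[which.max(cl30$unique_pirnas)])

  cl10 <- rank_activity(mk(10, 10:1))
  expect_equal(sum(cl10$activity == "active"), 10)

  # tie at the 15/16 boundary: smaller id wins; verified over the small-case
  # enumeration of both id orders
  counts <- c(sort(1000 + 1:14, decreasing = TRUE), 500, 500)
  for (perm in list(1:16, 16:1)) {
    cl <- mk(16, counts)[perm, ]
    ranked <- rank_activity(cl)
    tied <- ranked[ranked$unique_pirnas == 500, ]
    expect_equal(ranked$activity[ranked$cluster_id == min(tied$cluster_id)][1],
                 "active")
    expect_equal(sum(ranked$activity == "active"), 15)
  }
})

test_that("membership, orientation and overlap tie-break are assigned correctly", {
  clusters <- data.frame(
    cluster_id = c("big", "small", "uniplus"),
    chrom = "chr1",
    start = c(1000, 1400, 5000), end = c(2000, 1600, 6000),
    sense_pct = c(50, 50, 90), antisense_pct = c(50, 50, 10),
    unique_pirnas = c(300, 200, 100),
    stringsAsFactors = FALSE
  )
  clusters <- annotate_clusters(clusters)
  expect_equal(clusters$strandness, c("dual", "dual", "uni"))
  expect_equal(clusters$precursor_strand[3], "+")

  sites <- data.frame(
    site_id = c("s1", "s2", "s3", "s4"),
    chrom = "chr1",
    position = c(1500, 1100, 5500, 90000),
    element_strand = c("+", "+", "-", "+"),
    count = c(10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
  ann <- assign_membership(sites, clusters)
  expect_equal(ann$cluster_id, c("small", "big", "uniplus", NA))  # smallest wins
  # minus-strand element inside a plus-precursor unistrand cluster: antisense
  expect_equal(ann$cluster_orientation[3], "-")
  expect_true(is.na(ann$cluster_orientation[1]))  # dual: orientation not classified
})

test_that("antisense insertions in a unistrand cluster are all called antisense", {
  g <- fixture_genome
  clusters <- annotate_clusters(g$clusters)
  uni <- clusters[clusters$strandness == "uni", ][1, ]
  spec <- ins_spec(rep("in-cluster", 6),
                   strands = rep(zygopir:::opposite_strand(uni$precursor_strand), 6))
  # force placement into the chosen cluster
  g1 <- g
  g1$clusters <- g$clusters[g$clusters$cluster_id == uni$cluster_id, , drop = FALSE]
  ins <- plant_insertions(g1, spec, margin = 100, seed = 7)
  sites <- data.frame(site_id = ins$insertion_id, chrom = ins$chrom,
                      position = ins$position, element_strand = ins$strand,
                      count = 1, stringsAsFactors = FALSE)
  ann <- assign_membership(sites, clusters)
  expect_equal(ann$cluster_id, rep(uni$cluster_id, 6))
  expect_equal(ann$cluster_orientation, rep("-", 6))
})

test_that("cluster read fraction is the in-cluster read share", {
  sites <- data.frame(count = c(40, 60, 60),
                      cluster_id = c("c1", NA, NA))
  expect_equal(cluster_read_fraction(sites), 25)
  sites$cluster_id <- NA
  expect_equal(cluster_read_fraction(sites), 0)
  sites$cluster_id <- "c1"
  expect_equal(cluster_read_fraction(sites), 100)
  # planted 4:1 out:in read mass
  planted <- data.frame(count = c(100, 400), cluster_id = c("c1", NA))
  expect_equal(cluster_read_fraction(planted), 20)
})

test_that("class counts partition the in-cluster sites", {
  sites <- data.frame(
    site_id = paste0("s", 1:4),
    cluster_id = c("a", "b", "c", NA),
    cluster_strandness = c("dual", "dual", "uni", NA),
    cluster_activity = c("active", "active", "low", NA),
    cluster_orientation = c(NA, NA, "+", NA),
    stringsAsFactors = FALSE
  )
  tab <- count_by_class(sites)
  expect_equal(tab$n_sites[tab$strandness == "dual" & tab$activity == "active"], 2)
  expect_equal(tab$n_sites[tab$strandness == "uni" & tab$activity == "low" &
                             tab$orientation == "+"], 1)
  expect_equal(sum(tab$n_sites), 3)  # equals number of in-cluster sites

  empty <- count_by_class(sites[0, ])
  expect_true(all(empty$n_sites == 0))
})
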