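test_that("pairs without element sequence are discarded, flanks trimmed exactly", {
  g <- fixture_genome
  em <- fixture_element

  # constructed read: element terminus + known flank + adapter
  flank <- substr(g$chromosomes[["chr1"]], 5001, 5150)
  read1 <- paste0(substr(em$consensus, 2758, 2907), flank,
                  zygopir:::JUNCTION_ADAPTER)
  pairs <- data.frame(read1 = read1, read2 = "ACGTACGTACGTACGTACGTACGT",
                      stringsAsFactors = FALSE)
  fl <- extract_junction_reads(pairs, em)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$flank, flank)
  expect_equal(fl$terminus, "E_suffix")

  # element-free pairs are discarded
  junk <- data.frame(read1 = substr(g$chromosomes[["chr1"]], 1, 250),
                     read2 = substr(g$chromosomes[["chr2"]], 1, 250),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(extract_junction_reads(junk, em)), 0)
})

test_that("error-free extraction retains exactly the recoverable truth pairs", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec(rep("uniform", 6), variants = c("FP", "KP"),
                                      occupancies = c(1, .5)), seed = 71)
  lib <- simulate_junction_library(g, ins, em, error_rate = 0,
                                   n_background_pairs = 30, seed = 72)
  fl <- extract_junction_reads(lib$pairs, em)
  expect_equal(nrow(fl), sum(lib$truth$insertions$n_recoverable))
})

test_that("flank mapping finds unique loci and rejects ambiguous ones", {
  g <- fixture_genome
  # verbatim flank from a unique locus
  flank <- substr(g$chromosomes[["chr2"]], 20001, 20100)
  mp <- map_flanks(flank, g)
  expect_true(mp$mapped)
  expect_equal(mp$chrom, "chr2")
  expect_equal(mp$position, 20001)
  expect_equal(mp$flank_strand, "+")

  # reverse-complement flank maps on the minus strand, position adjacent
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(flank)))
  mp_rc <- map_flanks(rc, g)
  expect_true(mp_rc$mapped)
  expect_equal(mp_rc$flank_strand, "-")
  expect_equal(mp_rc$position, 20101)  # base adjacent above the flank start

  # a sequence planted identically on both chromosomes is ambiguous
  g2 <- g
  seg <- substr(g2$chromosomes[["chr1"]], 1001, 1100)
  substr(g2$chromosomes[["chr2"]], 50001, 50100) <- seg
  expect_false(map_flanks(seg, g2)$mapped)

  # shorter than the seed: unmapped
  expect_false(map_flanks(substr(flank, 1, 25), g)$mapped)
})

test_that("site consolidation merges jittered positions at the modal point", {
  mk <- function(pos, strand = "+", chrom = "chr1") {
    data.frame(chrom = chrom, position = pos, element_strand = strand,
               stringsAsFactors = FALSE)
  }
  s1 <- cluster_sites(mk(c(rep(1000, 40), rep(1003, 2))))
  expect_equal(nrow(s1), 1)
  expect_equal(s1$position, 1000)
  expect_equal(s1$count, 42)

  s2 <- cluster_sites(mk(c(1000, 1100)))
  expect_equal(nrow(s2), 2)

  # random jitter +/- 2 bp around 3 planted sites: exactly 3 sites
  set.seed(5)
  planted <- c(5000, 9000, 13000)
  jit <- unlist(lapply(planted, function(p) p + sample(-2:2, 30, replace = TRUE)))
  s3 <- cluster_sites(mk(jit))
  expect_equal(nrow(s3), 3)
  expect_true(all(abs(sort(s3$position) - planted) <= 2))

  # opposite orientations never merge
  both <- rbind(mk(2000, "+"), mk(2001, "-"))
  expect_equal(nrow(cluster_sites(both)), 2)
})

test_that("occupancies are read fractions summing to one", {
  sites <- data.frame(site_id = c("a", "b"), chrom = "chr1",
                      position = c(1, 2), element_strand = "+",
                      count = c(50, 150), stringsAsFactors = FALSE)
  oc <- compute_occupancy(sites)
  expect_equal(oc$occupancy, c(0.25, 0.75))
  expect_equal(sum(oc$occupancy), 1)
  expect_equal(compute_occupancy(sites[1, , drop = FALSE])$occupancy, 1)
  sites$count <- 0L
  expect_error(compute_occupancy(sites), "no supporting reads")
})

test_that("region states follow the transcription track, unknown off-track", {
  g <- fixture_genome
  g$track <- data.frame(chrom = "chr1", start = c(1, 1001), end = c(1000, 2000),
                        score = c(5, 0), stringsAsFactors = FALSE)
  sites <- data.frame(site_id = c("a", "b", "c"), chrom = "chr1",
                      position = c(500, 1500, 9999), element_strand = "+",
                      count = c(75, 25, 0), stringsAsFactors = FALSE)
  st <- assign_region_state(sites, g)
  expect_equal(st$region_state, c("active", "silent", "unknown"))

  fr <- region_state_fractions(st[1:2, ])
  expect_equal(unname(fr), c(75, 25, 0))
  expect_equal(sum(fr), 100, tolerance = 1e-9)

  st$count <- c(0, 10, 0)
  expect_equal(unname(region_state_fractions(st)), c(0, 100, 0))
})

test_that("end-to-end calling recovers planted sites exactly on clean reads", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec(rep("uniform", 8), variants = c("FP", "KP"),
                                      strands = c("+", "-")), seed = 81)
  lib <- simulate_junction_library(g, ins, em, error_rate = 0,
                                   mean_depth_per_individual = 3, seed = 82)
  sites <- call_insertions(lib, g, em)
  detectable <- lib$truth$insertions[lib$truth$insertions$n_mappable > 0, ]
  expect_gt(nrow(detectable), 0)
  expect_equal(nrow(sites), nrow(detectable))
  for (i in seq_len(nrow(detectable))) {
    hit <- sites[sites$chrom == detectable$chrom[i] &
                   abs(sites$position - detectable$position[i]) <= 10, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$element_strand, detectable$strand[i])
  }
  expect_equal(sum(sites$occupancy), 1)
})

test_that("calling is invariant under read shuffling", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec(rep("uniform", 4)), seed = 91)
  lib <- simulate_junction_library(g, ins, em, seed = 92)
  sites1 <- call_insertions(lib$pairs, g, em)
  set.seed(1)
  shuffled <- lib$pairs[sample.int(nrow(lib$pairs)), ]
  sites2 <- call_insertions(shuffled, g, em)
  expect_equal(sites1[, c("chrom", "position", "element_strand", "count")],
               sites2[, c("chrom", "position", "element_strand", "count")])
})
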