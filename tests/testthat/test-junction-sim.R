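test_that("every emitted junction read pair is element-anchored", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec(rep("uniform", 4)), seed = 21)
  lib <- simulate_junction_library(g, ins, em, error_rate = 0, seed = 22)

  expect_gt(nrow(lib$pairs), 0)
  # the template starts at the nested element primer: read 1 begins with
  # 100 element bases ending at a terminus (either orientation)
  cons <- em$consensus
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  suffix_e <- substr(cons, 2907 - 99, 2907)
  suffix_rc <- substr(rc, 2907 - 99, 2907)
  prefixes <- substr(lib$pairs$read1, 1, 100)
  expect_true(all(prefixes %in% c(suffix_e, suffix_rc)))
})

test_that("reads respect read length and fragments respect size selection", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec(rep("uniform", 6), variants = c("FP", "KP")),
                          seed = 31)
  lib <- simulate_junction_library(g, ins, em, read_length = 250, seed = 32)
  expect_true(all(nchar(lib$pairs$read1) <= 250))
  expect_true(all(nchar(lib$pairs$read2) <= 250))

  # size selection on the underlying restriction fragments
  for (i in seq_len(nrow(ins))) {
    frags <- zygopir:::junction_fragments(g, ins[i, ], em, c("GCGC", "TCGA"),
                                          c(300L, 600L), 100L)
    for (fr in frags) {
      expect_gte(fr$frag_len, 300)
      expect_lte(fr$frag_len, 600)
      expect_equal(fr$elem_len, 100)
    }
  }
})

test_that("truth bookkeeping is complete: every pair has one origin", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec(rep("uniform", 5), occupancies = c(1, .5, .25, 1, .75)),
                          seed = 41)
  lib <- simulate_junction_library(g, ins, em, n_background_pairs = 25, seed = 42)
  tr <- lib$truth$insertions
  expect_equal(sum(tr$n_pairs) + 25, nrow(lib$pairs))
  expect_equal(sum(lib$pairs$insertion_id == "background"), 25)
  expect_true(all(tr$n_recoverable <= tr$n_pairs))
  expect_true(all(tr$n_mappable <= tr$n_recoverable))
})

test_that("occupancy drives read counts (binomial expectation)", {
  g <- fixture_genome
  em <- fixture_element
  depth <- 5
  ins <- plant_insertions(g, ins_spec(rep("uniform", 8),
                                      occupancies = rep(c(1, 0.5), 4)), seed = 51)
  lib <- simulate_junction_library(g, ins, em, mean_depth_per_individual = depth,
                                   pool_size = 40, seed = 52)
  tr <- lib$truth$insertions
  tr <- tr[tr$n_fragments > 0, ]
  expect_true(any(tr$occupancy == 1) && any(tr$occupancy == 0.5))
  for (i in seq_len(nrow(tr))) {
    # read-based occupancy estimate: reads per fragment per individual-depth
    est <- tr$n_pairs[i] / (tr$n_fragments[i] * 40 * depth)
    # binomial carrier noise plus Poisson read noise
    sd_i <- sqrt(tr$occupancy[i] * (1 - tr$occupancy[i]) / 40 +
                   tr$occupancy[i] / (40 * tr$n_fragments[i] * depth))
    expect_lte(abs(est - tr$occupancy[i]), 3 * sd_i + 1e-9)
  }
})

test_that("simulation is reproducible and FASTQ output round-trips", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec("uniform"), seed = 61)
  lib1 <- simulate_junction_library(g, ins, em, seed = 62)
  lib2 <- simulate_junction_library(g, ins, em, seed = 62)
  expect_identical(lib1$pairs, lib2$pairs)

  prefix <- tempfile()
  write_junction_fastq(lib1, prefix)
  back <- read_junction_fastq(paste0(prefix, "_R1.fastq"),
                              paste0(prefix, "_R2.fastq"))
  expect_equal(back$read1, lib1$pairs$read1)
  expect_equal(back$read2, lib1$pairs$read2)
})
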