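test_that("size filter keeps the 24-35 nt piRNA class inclusively", {
  reads <- vapply(20:40, function(L) strrep("A", L), character(1))
  kept <- size_filter(reads)
  expect_equal(length(kept), 12)  # integers in [24, 35]
  expect_false(strrep("A", 23) %in% kept)
  expect_true(strrep("A", 35) %in% kept)
  expect_true(strrep("A", 24) %in% kept)
})

test_that("miRNA removal counts both strands and tolerates an empty set", {
  mirnas <- decoy_mirnas()
  expect_gte(length(mirnas), 20)
  expect_true(all(nchar(mirnas) >= 21 & nchar(mirnas) <= 23))

  reads <- c(rep(mirnas[1], 3),
             as.character(Biostrings::reverseComplement(
               Biostrings::DNAString(mirnas[2]))),
             "ACGTACGTACGTACGTACGTACGTACGT")
  res <- remove_mirnas(reads, mirnas)
  expect_equal(res$mirna_count, 4)
  expect_equal(length(res$reads), 1)

  res0 <- remove_mirnas(reads, character(0))
  expect_equal(res0$mirna_count, 0)
  expect_equal(res0$reads, reads)
})

test_that("mapping records hits at 5' consensus positions, strand-aware", {
  em <- fixture_element
  cons <- em$consensus
  sense_read <- substr(cons, 100, 128)
  anti_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(cons, 200, 226))))
  prof <- map_to_element(c(sense_read, anti_read), em)
  expect_equal(prof$sense[100], 1)
  expect_equal(sum(prof$sense), 1)
  expect_equal(prof$antisense[226], 1)  # antisense 5' end = match end
  expect_equal(prof$total, 2)

  none <- map_to_element("TTTTTTTTTTTTTTTTTTTTTTTTTTT", em)
  expect_equal(none$total, 0)
})

test_that("simulated library quantification conserves truth exactly", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec(rep("in-cluster", 4),
                                      variants = c("FP", "KP"),
                                      occupancies = c(1, 0.5)), seed = 201)
  srl <- simulate_small_rnas(g, ins, em, n_mirna_reads = 20000,
                             n_junk_reads = 500, seed = 202)
  expect_true(all(nchar(srl$reads) <= 50))

  prof <- quantify_pirnas(srl, em)
  expect_equal(prof$total, srl$truth$total_element)
  expect_equal(sum(prof$sense), srl$truth$total_sense)
  expect_equal(sum(prof$antisense), srl$truth$total_antisense)
  expect_equal(prof$mirna_count, srl$truth$n_mirna)
  expect_equal(prof$rpm, prof$total * 1e6 / prof$mirna_count, tolerance = 1e-12)

  # piRNA read lengths always within the 24-35 class
  pir_lens <- nchar(srl$reads)
  expect_true(all(pir_lens >= 18 & pir_lens <= 50))

  # profile conserves reads: column sums equal totals
  pt <- profile_table(prof)
  expect_equal(sum(pt$sense) + sum(pt$antisense), prof$total)
})

test_that("insertions outside clusters produce no element piRNAs", {
  g <- fixture_genome
  em <- fixture_element
  # places far from clusters: uniform draws checked against clusters
  ins <- plant_insertions(g, ins_spec(rep("silent-region", 2)), seed = 203)
  in_cluster <- vapply(seq_len(nrow(ins)), function(i) {
    any(g$clusters$chrom == ins$chrom[i] &
          g$clusters$start <= ins$position[i] &
          g$clusters$end >= ins$position[i])
  }, logical(1))
  ins <- ins[!in_cluster, , drop = FALSE]
  srl <- simulate_small_rnas(g, ins, em, n_mirna_reads = 1000,
                             n_junk_reads = 0, seed = 204)
  expect_equal(srl$truth$total_element, 0)
  expect_equal(length(srl$reads), 1000)
})

test_that("RPM follows its closed form, is linear, and fails on zero denominator", {
  expect_equal(rpm_normalize(500, 1e6), 500)
  expect_equal(rpm_normalize(0, 12345), 0)
  expect_error(rpm_normalize(10, 0), "zero")
  expect_equal(rpm_normalize(2 * 700, 1e5), 2 * rpm_normalize(700, 1e5))
  expect_equal(rpm_normalize(700, 2e5), rpm_normalize(700, 1e5) / 2)
})

test_that("miRNA removal and size filtering commute when miRNA lengths are outside 24-35", {
  mirnas <- decoy_mirnas()   # 21-23 nt, all below the piRNA class
  em <- fixture_element
  reads <- c(mirnas[1:5], substr(em$consensus, 50, 79),
             strrep("G", 40), substr(em$consensus, 500, 527))
  a <- size_filter(remove_mirnas(reads, mirnas)$reads)
  b <- remove_mirnas(size_filter(reads), mirnas)$reads
  expect_equal(sort(a), sort(b))
})

test_that("doubling piRNA rates doubles RPM within sampling error", {
  g <- fixture_genome
  em <- fixture_element
  ins <- plant_insertions(g, ins_spec(rep("in-cluster", 3)), seed = 205)
  r1 <- simulate_small_rnas(g, ins, em, pirna_rate = function(r) ifelse(r <= 15, 1000, 100),
                            n_mirna_reads = 10000, n_junk_reads = 0, seed = 206)
  r2 <- simulate_small_rnas(g, ins, em, pirna_rate = function(r) ifelse(r <= 15, 2000, 200),
                            n_mirna_reads = 10000, n_junk_reads = 0, seed = 207)
  p1 <- quantify_pirnas(r1, em)
  p2 <- quantify_pirnas(r2, em)
  # Poisson relative error at these totals is ~2-3%; allow 4 sd
  expect_equal(p2$rpm / p1$rpm, 2,
               tolerance = 4 * sqrt(1 / p1$total + 1 / p2$total))
})
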