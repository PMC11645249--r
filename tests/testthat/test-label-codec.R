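test_that("longest CDS filter keeps the longest isoform with id tie-break", {
  ann <- annotation_set(tibble::tibble(
    seqid = "s", gene_id = "g1",
    transcript_id = c("tLong", "tLong", "tShort"),
    strand = "+",
    start = c(0L, 300L, 0L), end = c(150L, 600L, 300L)))  # 450 vs 300
  kept <- longest_cds_filter(ann)
  expect_equal(unique(kept$transcript_id), "tLong")
  # tie on summed length 300: lexicographically smallest id wins
  tie <- annotation_set(tibble::tibble(
    seqid = "s", gene_id = "g1", transcript_id = c("tB", "tA"),
    strand = "+", start = c(0L, 500L), end = c(300L, 800L)))
  expect_equal(unique(longest_cds_filter(tie)$transcript_id), "tA")
  # single isoform unchanged
  single <- toy_annotation(0L, 30L)
  expect_equal(coord_frame(longest_cds_filter(single)), coord_frame(single))
})

test_that("single-exon CDS gets the worked labeling", {
  # IR IR IR START E1 E2 E0 E1 E2 E0 E1 STOP IR IR
  rec <- genome_record("CCCATGAAATAACC")
  ann <- toy_annotation(3L, 12L)
  lab <- encode_reference_labels(ann, rec, "forward")
  expect_equal(as.integer(lab),
               c(1, 1, 1, 14, 6, 7, 5, 6, 7, 5, 6, 15, 1, 1))
  expect_true(validate_grammar(lab)$valid)
})

test_that("two-exon CDS labels exon borders and intron frame", {
  toy <- toy_two_exon()
  lab <- encode_reference_labels(toy$annotation, toy$record, "forward")
  # exon1 "ATGA" -> START E1 E2 DSS0; intron (16 bases) -> I1; exon2 "AATAA"
  # -> ASS1 E2 E0 E1 STOP
  expect_equal(as.integer(lab)[4:8], c(14, 6, 7, 11, 2 + 1))
  expect_true(all(as.integer(lab)[8:23] == 3))  # I1
  expect_equal(as.integer(lab)[24:28], c(9, 7, 5, 6, 15))
  expect_true(validate_grammar(lab)$valid)
  # decoding inverts the encoding
  dec <- decode_state_path(lab)
  expect_equal(coord_frame(dec), coord_frame(toy$annotation))
})

test_that("zero genes encode to all-IR and decode to an empty set", {
  rec <- genome_record("ACGTACGTACGT")
  lab <- encode_reference_labels(annotation_set(NULL), rec, "forward")
  expect_true(all(as.integer(lab) == 1L))
  expect_equal(nrow(decode_state_path(lab)), 0L)
})

test_that("non-canonical transcripts are skipped with a warning", {
  rec <- genome_record("CCCATGAAATAACC")
  bad <- toy_annotation(3L, 11L)  # length 8, not mod 3
  expect_warning(lab <- encode_reference_labels(bad, rec, "forward"),
                 "not a canonical")
  expect_true(all(as.integer(lab) == 1L))
  # same-strand overlapping genes: later-starting one dropped
  rec2 <- genome_record("CCCATGAAATAACCATGAAATAACC")
  ov <- annotation_set(tibble::tibble(
    seqid = "seq", gene_id = c("gA", "gB"),
    transcript_id = c("gA.t1", "gB.t1"), strand = "+",
    start = c(3L, 5L), end = c(12L, 14L)))
  expect_warning(encode_reference_labels(ov, rec2, "forward"), "overlaps")
})

test_that("encode -> decode is the identity on simulated annotations (property)", {
  for (seed in 1:12) {
    sim <- simulate_genome(simulation_config(
      genome_length = 50000, coding_fraction = 0.08, mean_intron = 150,
      mean_exon = 60, mean_exons_per_gene = 3, seed = seed))
    expect_true(validate_grammar(sim$labels_forward)$valid)
    expect_true(validate_grammar(sim$labels_reverse)$valid)
    dec <- dplyr::bind_rows(
      as_tibble(decode_state_path(sim$labels_forward)),
      as_tibble(decode_state_path(sim$labels_reverse)))
    expect_equal(coord_frame(annotation_set(dec)), coord_frame(sim$annotation))
  }
})

test_that("codon-position labels are periodic within a CDS (frame conservation)", {
  sim <- simulate_genome(simulation_config(
    genome_length = 50000, coding_fraction = 0.08, mean_intron = 150,
    mean_exon = 60, mean_exons_per_gene = 4, seed = 99))
  lab <- as.integer(sim$labels_forward)
  # codon position of each coding state, in transcript order
  cp_of <- c(NA, NA, NA, NA, 0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 2)
  coding <- which(lab >= 5)
  if (length(coding)) {
    cp <- cp_of[lab[coding]]
    expect_true(all(diff(cp) %% 3 == 1 | diff(cp) %% 3 == -2))
  }
})

test_that("strict decoding errors on ungrammatical paths, lenient skips", {
  bad <- label_seq(c(1, 14, 6, 15, 1, 5, 5, 1))  # IR->E0 junk after gene
  expect_error(decode_state_path(bad), "position")
  lenient <- decode_state_path(label_seq(c(1, 14, 6, 2, 15, 1)), strict = FALSE)
  expect_equal(nrow(lenient), 0L)
  expect_equal(attr(lenient, "n_skipped"), 1L)
})

test_that("label runs give a compact BED-like view", {
  runs <- label_runs(label_seq(c(1, 1, 14, 6, 15, 1)))
  expect_equal(runs$state[1:2], c("IR", "START"))
  expect_equal(runs$start[1], 0L)
  expect_equal(runs$end[nrow(runs)], 6L)
})
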