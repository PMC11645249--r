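test_that("tile plans cover every base of both strands exactly once", {
  rec <- genome_record(paste(rep("ACGT", 300), collapse = ""))  # 1200 bases
  plan <- plan_tiles(rec, 500L)
  expect_equal(nrow(plan), 6L)  # 3 tiles x 2 strands
  for (s in c("forward", "reverse")) {
    p <- plan[plan$strand == s, ]
    expect_equal(p$start, c(0L, 500L, 1000L))
    expect_equal(p$end, c(500L, 1000L, 1200L))
    cov <- unlist(Map(seq, p$start, p$end - 1L))
    expect_equal(sort(cov), 0:1199)
  }
  # record shorter than one tile -> a single tile
  small <- plan_tiles(genome_record("ACGTACGT"), 500L)
  expect_equal(nrow(small), 2L)
  expect_equal(unique(small$end), 8L)
  # random lengths: coverage property
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(10:2000, 1)
    L <- sample(7:600, 1)
    rec <- genome_record(paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
    p <- plan_tiles(rec, L)
    fwd <- p[p$strand == "forward", ]
    expect_equal(sum(fwd$end - fwd$start), n)
    expect_true(all(diff(fwd$start) == L))
  }
})

test_that("spliced-stop filter removes exactly the genes with an intron-spanning stop", {
  # gene A: CDS ATG AAA TAA split as "ATGA" | intron | "AATAA" -> codons
  # ATG AAA TAA: fine. gene B: CDS ATG TAA GTAA split to create internal TAA.
  toy <- toy_two_exon()
  keep <- filter_spliced_stops(toy$annotation, toy$record)
  expect_equal(nrow(keep), 2L)
  expect_equal(attr(keep, "n_filtered"), 0L)
  # build a gene whose spliced CDS is ATG TAA TAA (internal stop across exons)
  seq <- paste0("CC", "ATGT", "GTAAGCCCCCAG", "AATAA", "CC")
  rec <- genome_record(seq, "toy2")
  ann <- toy_annotation(c(2L, 18L), c(6L, 23L), seqid = "toy2")
  filt <- filter_spliced_stops(ann, rec)
  expect_equal(nrow(filt), 0L)
  expect_equal(attr(filt, "n_filtered"), 1L)
})

test_that("gene assembly merges strands, maps coordinates and keeps ids stable", {
  sim <- simulate_genome(simulation_config(
    genome_length = 60000, coding_fraction = 0.05, mean_intron = 150,
    mean_exon = 60, mean_exons_per_gene = 3, seed = 8))
  g1 <- assemble_genes(sim$labels_forward, sim$labels_reverse, sim$record)
  g2 <- assemble_genes(sim$labels_forward, sim$labels_reverse, sim$record)
  expect_identical(as_tibble(g1), as_tibble(g2))
  expect_equal(coord_frame(g1), coord_frame(sim$annotation))
  # ids are sequential in coordinate order
  ord <- g1[order(g1$start), ]
  expect_equal(unique(ord$gene_id)[1], "g1")
})

test_that("overlapping genes on opposite strands are both reported", {
  # reverse-strand gene nested inside the intron of a forward two-exon gene
  seq <- paste0("CCC", "ATGA", "GTAAG", "CC",
                reverse_complement("ATGAAATAA"),  # minus-strand CDS
                "CCC", "AG", "AATAA", "CC")
  rec <- genome_record(seq, "nest")
  fwd_ann <- toy_annotation(c(3L, 28L), c(7L, 33L), seqid = "nest")
  rev_ann <- annotation_set(tibble::tibble(
    seqid = "nest", gene_id = "gR", transcript_id = "gR.t1", strand = "-",
    start = 14L, end = 23L))
  labf <- encode_reference_labels(fwd_ann, rec, "forward")
  labr <- encode_reference_labels(rev_ann, rec, "reverse")
  genes <- assemble_genes(labf, labr, rec)
  expect_equal(nrow(dplyr::distinct(genes[, c("gene_id", "strand")])), 2L)
  expect_setequal(unique(genes$strand), c("+", "-"))
  # the spans really overlap
  spans <- dplyr::summarise(dplyr::group_by(genes, .data$gene_id),
                            s = min(start), e = max(end))
  expect_lt(max(spans$s), min(spans$e))
})

test_that("whole-genome prediction with clean probabilities is exact and deterministic", {
  # decode-only pipeline check: replace the network with a model trained...
  # no - use an untrained model but clean simulated probabilities through the
  # lower-level strand decoder, then the full pipeline on a trained stub is
  # covered by the acceptance suite. Here: tiles + stitching via the
  # label-level API.
  sim <- simulate_genome(simulation_config(
    genome_length = 120000, coding_fraction = 0.03, mean_intron = 200,
    mean_exon = 80, mean_exons_per_gene = 3, seed = 19))
  h <- build_transitions()
  # tile the forward strand manually with clean probabilities: paths from
  # independent tiles, stitched, must reproduce the planted genes away from
  # boundaries; a boundary inside a gene is exercised in the second-pass test
  X <- simulate_class_probabilities(sim$labels_forward)
  mask <- sequence_constraint_masks(sim$record, "forward")
  lik <- emission_likelihoods(X, mask, h$epsilon)
  path <- viterbi_parallel(lik, h, 4992)
  expect_identical(as.integer(path), as.integer(sim$labels_forward))
})

test_that("in-gene tile boundaries trigger the second pass, which acts locally", {
  sim <- simulate_genome(simulation_config(
    genome_length = 90000, coding_fraction = 0.04, mean_intron = 1000,
    mean_exon = 90, mean_exons_per_gene = 3, seed = 33))
  ann <- sim$annotation
  # pick a forward gene and a tile length whose boundary cuts it; the oracle
  # supplies degraded (blended) planted probabilities so decoding inside one
  # truncated tile cannot see the whole gene
  spans <- dplyr::summarise(dplyr::group_by(as_tibble(ann), .data$gene_id),
                            s = min(.data$start), e = max(.data$end),
                            strand = .data$strand[1], .groups = "drop")
  g <- spans[spans$strand == "+" & spans$e - spans$s > 2000, ][1, ]
  expect_false(is.na(g$gene_id))
  # put the first tile boundary inside a CDS exon of the gene, the hardest
  # placement for independent per-tile decoding
  gex <- dplyr::filter(as_tibble(ann), .data$gene_id == g$gene_id)
  mid <- (g$s + g$e) / 2
  k <- which.min(abs((gex$start + gex$end) / 2 - mid))
  L <- as.integer((gex$start[k] + gex$end[k]) %/% 2)  # boundary mid-exon
  probs_fwd <- simulate_class_probabilities(sim$labels_forward)
  probs_rev <- simulate_class_probabilities(sim$labels_reverse)
  # emulate what a sequence model does at tile edges: predictions close to a
  # tile edge lose their context and decay toward uniform — the reason
  # in-gene boundaries need the merged-window second pass at all
  edge_damp <- function(P) {
    T <- nrow(P)
    d <- pmin(seq_len(T) - 1L, T - seq_len(T))
    w <- pmin(d / 600, 1)
    P * w + (1 - w) / 15
  }
  oracle_model <- function(X, ctx) {
    src <- if (ctx$strand == "forward") probs_fwd else probs_rev
    edge_damp(src[(ctx$start + 1):ctx$end, , drop = FALSE])
  }
  h <- build_transitions(epsilon = 0.01)
  with_2p <- run_genome_prediction(sim$record, oracle_model, h,
                                   tile_length = L, second_pass = TRUE)
  without_2p <- run_genome_prediction(sim$record, oracle_model, h,
                                      tile_length = L, second_pass = FALSE)
  sig <- function(genes) {
    gg <- as_tibble(genes)
    gg <- gg[gg$start >= g$s & gg$end <= g$e & gg$strand == "+", ]
    paste(sort(paste(gg$start, gg$end)), collapse = ";")
  }
  truth <- as_tibble(ann)
  truth <- truth[truth$gene_id == g$gene_id, ]
  truth_sig <- paste(sort(paste(truth$start, truth$end)), collapse = ";")
  expect_gte(with_2p$report$n_second_pass, 1L)
  expect_equal(sig(with_2p$genes), truth_sig)     # recovered intact
  # the second pass never changes predictions farther than one tile from a
  # boundary it fired on: short genes well away from every boundary are
  # identical between the two runs
  far <- function(p) {
    gg <- as_tibble(p$genes)
    d <- pmin(gg$start %% L, L - (gg$end %% L))
    coord_frame(annotation_set(
      gg[gg$end - gg$start < L & d > L %/% 2, , drop = FALSE]))
  }
  expect_equal(far(with_2p), far(without_2p))
})

test_that("decode-only prediction with clean probabilities is exact and byte-stable", {
  sim <- simulate_genome(simulation_config(
    genome_length = 90000, coding_fraction = 0.04, mean_intron = 200,
    mean_exon = 70, mean_exons_per_gene = 3, seed = 29))
  pf <- simulate_class_probabilities(sim$labels_forward)
  pr <- simulate_class_probabilities(sim$labels_reverse)
  oracle_model <- function(X, ctx) {
    src <- if (ctx$strand == "forward") pf else pr
    src[(ctx$start + 1):ctx$end, , drop = FALSE]
  }
  h <- build_transitions()
  g1 <- tempfile(fileext = ".gtf")
  g2 <- tempfile(fileext = ".gtf")
  p1 <- run_genome_prediction(sim$record, oracle_model, h, out_gtf = g1,
                              tile_length = 30000L)
  p2 <- run_genome_prediction(sim$record, oracle_model, h, out_gtf = g2,
                              tile_length = 30000L)
  expect_identical(readLines(g1), readLines(g2))  # byte-identical rerun
  expect_equal(coord_frame(p1$genes), coord_frame(sim$annotation))
})

test_that("GTF output of predictions passes the independent sequence validator", {
  sim <- simulate_genome(simulation_config(
    genome_length = 100000, coding_fraction = 0.04, mean_intron = 200,
    mean_exon = 70, mean_exons_per_gene = 3, seed = 23))
  genes <- assemble_genes(sim$labels_forward, sim$labels_reverse, sim$record)
  genes <- filter_spliced_stops(genes, sim$record)
  fa <- tempfile(fileext = ".fa")
  gtf <- tempfile(fileext = ".gtf")
  write_fasta(sim$record, fa)
  write_annotation(genes, gtf)
  expect_true(oracle_validate_gtf(gtf, fa))
})
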