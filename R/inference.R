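#' Plan inference tiles
#'
#' Partitions every record into tiles of `tile_length` per strand (the last
#' tile may be short). Tiles cover each strand exactly once and are processed
#' independently on the first pass.
#'
#' @param records A [genome_record()] or list of them.
#' @param tile_length Tile size in bases (default 500,004 — divisible by the
#'   default window granularity of 9).
#' @return A tibble of class `tile_plan`: `seqid`, `strand`, `start`, `end`
#'   (0-based half-open, strand-local coordinates), `tile`.
#' @export
plan_tiles <- function(records, tile_length = 500004L) {
  if (inherits(records, "genome_record")) records <- list(records)
  tile_length <- as.integer(tile_length)
  if (tile_length < 2L) stop("tile_length must be >= 2")
  out <- list()
  for (rec in records) {
    starts <- seq.int(0L, max(rec$length - 1L, 0L), by = tile_length)
    for (strand in c("forward", "reverse")) {
      out[[length(out) + 1L]] <- tibble(
        seqid = rec$sequence_id, strand = strand, start = starts,
        end = pmin(starts + tile_length, rec$length),
        tile = seq_along(starts))
    }
  }
  plan <- dplyr::bind_rows(out)
  class(plan) <- c("tile_plan", class(plan))
  plan
}

# Viterbi labels for one tile given strand-local sequence + encoding.
# `model` is an exonstate_model, or a function(X, ctx) -> T x 15 probability
# matrix (ctx = list(start, end, strand)) — the decode-only entry point for
# precomputed class probabilities.
.decode_tile <- function(model, hmm, seq, rpt, init_ir, final_ir,
                         segment_length, ctx = NULL) {
  X <- cpp_encode_sequence(seq, rpt)
  probs <- if (is.function(model)) model(X, ctx) else
    predict_class_probabilities(model, X)
  mask <- cpp_constraint_mask(seq)
  lik <- emission_likelihoods(probs, mask, hmm$epsilon)
  params <- .with_boundary(hmm, init_ir, final_ir)
  as.integer(viterbi_parallel(lik, params, segment_length))
}

# full-strand label vector with tiled first pass + second-pass boundary
# resolution
.predict_strand <- function(record, model, hmm, strand, tile_length,
                            segment_length, second_pass, no_softmask) {
  T <- record$length
  if (strand == "forward") {
    seq <- record$sequence
    rpt <- record$repeat_track
  } else {
    seq <- cpp_reverse_complement(record$sequence)
    rpt <- rev(record$repeat_track)
  }
  if (no_softmask) rpt <- integer(T)
  starts <- seq.int(0L, max(T - 1L, 0L), by = tile_length)
  ends <- pmin(starts + tile_length, T)
  labels <- integer(T)
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- ends[k]
    labels[(a + 1L):b] <- .decode_tile(
      model, hmm, substring(seq, a + 1L, b), rpt[(a + 1L):b],
      init_ir = a == 0L, final_ir = b == T, segment_length,
      ctx = list(start = a, end = b, strand = strand))
  }
  n_second <- 0L
  n_unresolved <- 0L
  if (second_pass && length(starts) > 1L) {
    for (k in seq_len(length(starts) - 1L)) {
      bnd <- ends[k]  # boundary between tile k and k+1 (0-based)
      if (labels[bnd] == 1L && labels[bnd + 1L] == 1L) next
      n_second <- n_second + 1L
      a <- starts[k]; b <- ends[k + 1L]
      merged <- .decode_tile(
        model, hmm, substring(seq, a + 1L, b), rpt[(a + 1L):b],
        init_ir = a == 0L, final_ir = b == T, segment_length,
        ctx = list(start = a, end = b, strand = strand))
      # replace the central half of the merged window: second half of tile k,
      # first half of tile k+1
      len_k <- ends[k] - starts[k]
      len_k1 <- ends[k + 1L] - starts[k + 1L]
      lo <- a + len_k %/% 2L            # 0-based start of replacement
      hi <- a + len_k + (len_k1 + 1L) %/% 2L
      labels[(lo + 1L):hi] <- merged[(lo - a + 1L):(hi - a)]
      # unresolved = the junction is still ungrammatical (an in-gene junction
      # with consistent labels is the expected healthy outcome)
      if (cpp_grammar_violation(labels[bnd:(bnd + 1L)], FALSE) != 0L) {
        n_unresolved <- n_unresolved + 1L
      }
    }
  }
  out <- label_seq(labels, strand, record$sequence_id)
  attr(out, "n_second_pass") <- n_second
  attr(out, "n_unresolved") <- n_unresolved
  out
}

#' Assemble gene models from two strand label paths
#'
#' Decodes both strands (leniently: malformed candidates at unresolved tile
#' junctions are skipped and counted), maps reverse-strand genes back to
#' forward coordinates, and assigns sequential, rerun-stable gene ids. Genes
#' on opposite strands may overlap or nest.
#'
#' @param labels_forward,labels_reverse [label_seq()] objects for the two
#'   strands (the reverse one in reverse-complement coordinates).
#' @param record The [genome_record()] they refer to.
#' @return An [annotation_set()] with attribute `n_skipped`.
#' @export
assemble_genes <- function(labels_forward, labels_reverse, record) {
  fw <- decode_state_path(labels_forward, record$sequence_id, strict = FALSE)
  rv <- decode_state_path(labels_reverse, record$sequence_id, strict = FALSE)
  both <- dplyr::bind_rows(fw, rv)
  n_skipped <- (attr(fw, "n_skipped") %||% 0L) + (attr(rv, "n_skipped") %||% 0L)
  if (nrow(both) == 0L) {
    out <- annotation_set(NULL)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  gstart <- dplyr::summarise(
    dplyr::group_by(both, .data$gene_id, .data$strand),
    s = min(.data$start), .groups = "drop")
  gstart <- dplyr::arrange(gstart, .data$s, .data$strand)
  new_id <- setNames(sprintf("g%d", seq_len(nrow(gstart))),
                     paste(gstart$gene_id, gstart$strand))
  both$gene_id <- unname(new_id[paste(both$gene_id, both$strand)])
  both$transcript_id <- paste0(both$gene_id, ".t1")
  out <- annotation_set(both)
  attr(out, "n_skipped") <- n_skipped
  out
}

# spliced CDS of one transcript on its strand: concatenate exons in ascending
# genomic order, then reverse-complement the whole splice for minus-strand
# transcripts (reversal re-orders the exons into transcript order)
.spliced_cds <- function(tx, record) {
  ord <- order(tx$start)
  cds <- paste(.substr_vec(record$sequence, tx$start[ord], tx$end[ord]),
               collapse = "")
  if (tx$strand[1] == "-") cds <- cpp_reverse_complement(cds)
  cds
}

#' Remove genes with stop codons spliced across an intron
#'
#' The HMM prevents in-frame stops within an exon but not stops whose codon
#' spans an intron; such genes are filtered here after assembly.
#'
#' @param genes An [annotation_set()].
#' @param records The [genome_record()] (or list, keyed by sequence id) the
#'   genes live on.
#' @return The filtered [annotation_set()] with attribute `n_filtered`.
#' @export
filter_spliced_stops <- function(genes, records) {
  genes <- annotation_set(genes)
  if (inherits(records, "genome_record")) {
    records <- setNames(list(records), records$sequence_id)
  } else if (is.null(names(records))) {
    names(records) <- vapply(records, `[[`, character(1), "sequence_id")
  }
  if (nrow(genes) == 0L) {
    attr(genes, "n_filtered") <- 0L
    return(genes)
  }
  keys <- unique(genes[, c("seqid", "transcript_id")])
  drop <- character(0)
  for (i in seq_len(nrow(keys))) {
    tx <- dplyr::filter(genes, .data$seqid == keys$seqid[i],
                        .data$transcript_id == keys$transcript_id[i])
    cds <- .spliced_cds(tx, records[[keys$seqid[i]]])
    n <- nchar(cds)
    if (n %% 3L != 0L) next
    codons <- substring(cds, seq(1L, n - 3L, by = 3L), seq(3L, n - 3L, by = 3L))
    if (length(codons) && any(codons %in% .STOP_CODONS)) {
      drop <- c(drop, keys$transcript_id[i])
    }
  }
  out <- annotation_set(dplyr::filter(genes, !(.data$transcript_id %in% drop)))
  attr(out, "n_filtered") <- length(drop)
  out
}

#' Whole-genome gene prediction
#'
#' Orchestrates the full inference pipeline on both strands of every record:
#' input encoding, network class probabilities, sequence constraint masks,
#' segment-parallel Viterbi per tile, second-pass re-prediction of merged
#' two-tile windows at boundaries that fall inside a gene, gene assembly,
#' the spliced-stop post-filter, and (optionally) GTF output. Deterministic
#' given the model weights.
#'
#' @param genome A FASTA path, a [genome_record()], or a list of records.
#' @param model A trained `exonstate_model`, or a function
#'   `(X, ctx) -> T x 15 probability matrix` for decode-only use with
#'   precomputed class probabilities (`ctx` carries `start`, `end`, `strand`
#'   of the tile in strand-local coordinates).
#' @param hmm A [build_transitions()] object.
#' @param out_gtf Optional path; when given, predictions are written as GTF.
#' @param tile_length First-pass tile size (default 500,004 bases).
#' @param segment_length Viterbi segment size.
#' @param second_pass Re-predict merged two-tile windows at in-gene tile
#'   boundaries.
#' @param no_softmask Zero out the repeat input track.
#' @return A list of class `genome_prediction` with `genes` (an
#'   [annotation_set()]) and `report` (run statistics).
#' @export
run_genome_prediction <- function(genome, model, hmm, out_gtf = NULL,
                                  tile_length = 500004L,
                                  segment_length = 4992L, second_pass = TRUE,
                                  no_softmask = FALSE) {
  records <- if (is.character(genome)) read_genome(genome)
             else if (inherits(genome, "genome_record")) list(genome)
             else genome
  all_genes <- list()
  report <- list(n_second_pass = 0L, n_unresolved = 0L, n_skipped = 0L,
                 n_filtered_spliced_stop = 0L, tile_length = tile_length)
  offset <- 0L
  for (rec in records) {
    lf <- .predict_strand(rec, model, hmm, "forward", tile_length,
                          segment_length, second_pass, no_softmask)
    lr <- .predict_strand(rec, model, hmm, "reverse", tile_length,
                          segment_length, second_pass, no_softmask)
    genes <- assemble_genes(lf, lr, rec)
    genes <- filter_spliced_stops(genes, rec)
    report$n_second_pass <- report$n_second_pass +
      attr(lf, "n_second_pass") + attr(lr, "n_second_pass")
    report$n_unresolved <- report$n_unresolved +
      attr(lf, "n_unresolved") + attr(lr, "n_unresolved")
    report$n_skipped <- report$n_skipped + (attr(genes, "n_skipped") %||% 0L)
    report$n_filtered_spliced_stop <- report$n_filtered_spliced_stop +
      (attr(genes, "n_filtered") %||% 0L)
    if (nrow(genes) > 0L && offset > 0L) {
      # keep gene ids unique across records
      genes$gene_id <- sprintf("g%d", offset + as.integer(sub("^g", "", genes$gene_id)))
      genes$transcript_id <- paste0(genes$gene_id, ".t1")
    }
    offset <- offset + length(unique(genes$gene_id))
    all_genes[[length(all_genes) + 1L]] <- genes
  }
  genes <- annotation_set(dplyr::bind_rows(all_genes))
  report$n_genes <- length(unique(genes$transcript_id))
  if (!is.null(out_gtf)) write_annotation(genes, out_gtf)
  structure(list(genes = genes, report = report), class = "genome_prediction")
}

#' @export
print.genome_prediction <- function(x, ...) {
  cat(sprintf(
    "<genome_prediction> %d genes (%d second-pass boundaries, %d spliced-stop filtered)\n",
    x$report$n_genes, x$report$n_second_pass,
    x$report$n_filtered_spliced_stop))
  invisible(x)
}
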