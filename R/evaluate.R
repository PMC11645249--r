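.metrics_row <- function(level, tp, fp, fn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  tibble(level = level, tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), precision = prec, recall = rec, f1 = f1)
}

#' Exon-level accuracy
#'
#' A predicted exon is a true positive iff its (`seqid`, `start`, `end`,
#' `strand`) match a reference exon exactly; exons are deduplicated within
#' each set before counting.
#'
#' @param pred,ref [annotation_set()] objects on the same assembly (reference
#'   reduced to one transcript per gene, see [longest_cds_filter()]).
#' @return A one-row metrics tibble: `level`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
exon_level_metrics <- function(pred, ref) {
  p <- dplyr::distinct(as_tibble(pred)[, c("seqid", "strand", "start", "end")])
  r <- dplyr::distinct(as_tibble(ref)[, c("seqid", "strand", "start", "end")])
  tp <- nrow(dplyr::inner_join(p, r, by = c("seqid", "strand", "start", "end")))
  .metrics_row("exon", tp, nrow(p) - tp, nrow(r) - tp)
}

.gene_signatures <- function(ann) {
  ann <- longest_cds_filter(ann)
  if (nrow(ann) == 0L) return(character(0))
  sig <- dplyr::summarise(
    dplyr::group_by(ann, .data$seqid, .data$strand, .data$transcript_id),
    sig = paste(.data$start, .data$end, sep = "-", collapse = ";"),
    .groups = "drop")
  unique(paste(sig$seqid, sig$strand, sig$sig))
}

#' Gene-level accuracy
#'
#' A predicted gene matches iff its full ordered set of CDS intervals and its
#' strand are identical to a reference gene's. Both sides are reduced to one
#' transcript per gene (longest CDS) first.
#'
#' @inheritParams exon_level_metrics
#' @return A one-row metrics tibble.
#' @export
gene_level_metrics <- function(pred, ref) {
  p <- .gene_signatures(pred)
  r <- .gene_signatures(ref)
  tp <- length(intersect(p, r))
  .metrics_row("gene", tp, length(p) - tp, length(r) - tp)
}

#' Exon- and gene-level evaluation of a prediction
#'
#' @inheritParams exon_level_metrics
#' @return A two-row tibble of class `exonstate_metrics` (`level` = `"exon"`,
#'   `"gene"`), with TP/FP/FN counts, precision, recall and F1 (0/0 counts as
#'   0).
#' @export
#' @examples
#' a <- annotation_set(tibble::tibble(
#'   seqid = "s", gene_id = "g1", transcript_id = "t1", strand = "+",
#'   start = c(0L, 100L), end = c(30L, 160L)))
#' evaluate_annotations(a, a)
evaluate_annotations <- function(pred, ref) {
  out <- dplyr::bind_rows(exon_level_metrics(pred, ref),
                          gene_level_metrics(pred, ref))
  class(out) <- c("exonstate_metrics", class(out))
  out
}

#' Normalize stop-codon inclusion in terminal CDS intervals
#'
#' Some annotation dialects exclude the stop codon from the CDS. When the
#' genome sequence is available, transcripts whose CDS does not end in a stop
#' codon but is immediately followed by one (on its strand) get their terminal
#' exon extended by 3 bases, so both comparison sides use the stop-included
#' convention.
#'
#' @param annotation An [annotation_set()].
#' @param record The [genome_record()] the annotation refers to.
#' @return The normalized [annotation_set()].
#' @export
normalize_stop_inclusion <- function(annotation, record) {
  ann <- as_tibble(annotation_set(annotation))
  if (nrow(ann) == 0L) return(annotation_set(ann))
  for (tid in unique(ann$transcript_id)) {
    idx <- which(ann$transcript_id == tid)
    tx <- ann[idx, ]
    cds <- .spliced_cds(tx, record)
    n <- nchar(cds)
    if (substring(cds, n - 2L, n) %in% .STOP_CODONS) next
    if (tx$strand[1] == "+") {
      j <- idx[which.max(tx$end)]
      nxt <- .substr_vec(record$sequence, ann$end[j], ann$end[j] + 3L)
      if (nxt %in% .STOP_CODONS) ann$end[j] <- ann$end[j] + 3L
    } else {
      j <- idx[which.min(tx$start)]
      nxt <- cpp_reverse_complement(
        .substr_vec(record$sequence, ann$start[j] - 3L, ann$start[j]))
      if (nxt %in% .STOP_CODONS) ann$start[j] <- ann$start[j] - 3L
    }
  }
  annotation_set(ann)
}
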