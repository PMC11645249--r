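#' Keep only the transcript with the longest coding sequence per gene
#'
#' The per-base labeling assigns a single state to every position, so genes
#' with multiple isoforms are reduced to one transcript: the one with the
#' maximal summed CDS length. Ties are broken toward the lexicographically
#' smallest transcript id.
#'
#' @param annotation An [annotation_set()].
#' @return An [annotation_set()] with exactly one transcript per gene.
#' @export
longest_cds_filter <- function(annotation) {
  annotation <- annotation_set(annotation)
  if (nrow(annotation) == 0L) return(annotation)
  lens <- dplyr::summarise(
    dplyr::group_by(annotation, .data$seqid, .data$gene_id, .data$transcript_id),
    cds_len = sum(.data$end - .data$start), .groups = "drop")
  keep <- dplyr::slice(
    dplyr::group_by(lens, .data$seqid, .data$gene_id),
    order(-.data$cds_len, .data$transcript_id)[1])
  keep <- dplyr::ungroup(keep)
  out <- dplyr::semi_join(
    annotation, keep, by = c("seqid", "gene_id", "transcript_id"))
  annotation_set(out, source_path = attr(annotation, "source_path"))
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.substr_vec <- function(seq, start0, end0) {
  # 0-based half-open extraction
  substring(seq, start0 + 1L, end0)
}

# strand-local CDS intervals (ascending = transcript order) for one transcript
.strand_intervals <- function(starts, ends, strand, T) {
  if (strand %in% c("forward", "+")) {
    ord <- order(starts)
    list(start = starts[ord], end = ends[ord])
  } else {
    s2 <- T - ends
    e2 <- T - starts
    ord <- order(s2)
    list(start = s2[ord], end = e2[ord])
  }
}

#' Encode a reference annotation as a per-base label sequence
#'
#' Applies the fixed labeling conventions: the first base of the start codon
#' is `START`, the last base of the stop codon is `STOP`, first/last bases of
#' non-initial/non-terminal coding exons are `ASS_i`/`DSS_i`, remaining coding
#' bases are `E_i` with `i` the codon position of the base, intron bases are
#' `I_j` with `j` the codon position of the next coding base, and everything
#' else is `IR`. The stop codon is included in the CDS labeling.
#'
#' Transcripts whose CDS length is not a multiple of 3, that lack canonical
#' start/stop/GT-AG signals, or that contain an exon shorter than 3 bases are
#' skipped with a warning, as is the later-starting gene of a same-strand
#' overlapping pair.
#'
#' @param annotation An [annotation_set()], one transcript per gene (see
#'   [longest_cds_filter()]).
#' @param record The [genome_record()] the annotation refers to.
#' @param strand `"forward"` or `"reverse"`; reverse-strand labels are encoded
#'   in reverse-complement coordinates.
#' @return A [label_seq()] of length `record$length`.
#' @export
encode_reference_labels <- function(annotation, record,
                                    strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  annotation <- annotation_set(annotation)
  T <- record$length
  seq <- if (strand == "forward") record$sequence else
    cpp_reverse_complement(record$sequence)
  labels <- rep(1L, T)  # IR

  want <- if (strand == "forward") "+" else "-"
  ann <- dplyr::filter(annotation, .data$strand == want,
                       .data$seqid == record$sequence_id)
  if (nrow(ann) == 0L) {
    return(label_seq(labels, strand, record$sequence_id))
  }

  txs <- split(ann, ann$transcript_id)
  iv <- lapply(txs, function(tx)
    .strand_intervals(tx$start, tx$end, want, T))
  ord <- order(vapply(iv, function(x) x$start[1], numeric(1)))
  txs <- txs[ord]
  iv <- iv[ord]

  last_end <- -1L
  for (k in seq_along(txs)) {
    tid <- names(txs)[k]
    st <- iv[[k]]$start
    en <- iv[[k]]$end
    if (st[1] < last_end) {
      warning(sprintf(
        "transcript '%s' overlaps a previously encoded same-strand gene; skipped",
        tid))
      next
    }
    n_ex <- length(st)
    total <- sum(en - st)
    cds <- paste(.substr_vec(seq, st, en), collapse = "")
    ok <- total %% 3L == 0L && total >= 6L && all(en - st >= 3L) &&
      startsWith(cds, "ATG") &&
      substring(cds, total - 2L, total) %in% .STOP_CODONS
    if (ok && n_ex > 1L) {
      don <- .substr_vec(seq, en[-n_ex], en[-n_ex] + 2L)
      acc <- .substr_vec(seq, st[-1] - 2L, st[-1])
      ok <- all(don == "GT") && all(acc == "AG") && all(st[-1] - en[-n_ex] >= 4L)
    }
    if (!ok) {
      warning(sprintf(
        "transcript '%s' is not a canonical frame-consistent CDS; skipped", tid))
      next
    }
    pos <- unlist(Map(function(a, b) a:(b - 1L), st, en), use.names = FALSE)
    cp <- (seq_along(pos) - 1L) %% 3L
    lab <- 5L + cp                                    # E0/E1/E2
    exon_of <- rep(seq_len(n_ex), en - st)
    first_of_exon <- c(TRUE, diff(exon_of) == 1L)
    last_of_exon <- c(diff(exon_of) == 1L, TRUE)
    lab[first_of_exon & exon_of > 1L] <- 8L + cp[first_of_exon & exon_of > 1L]   # ASS
    lab[last_of_exon & exon_of < n_ex] <- 11L + cp[last_of_exon & exon_of < n_ex] # DSS
    lab[1] <- 14L                                     # START
    lab[length(lab)] <- 15L                           # STOP
    labels[pos + 1L] <- lab
    if (n_ex > 1L) {
      for (j in seq_len(n_ex - 1L)) {
        nf <- cp[match(j + 1L, exon_of)]              # frame of next coding base
        labels[(en[j] + 1L):st[j + 1L]] <- 2L + nf    # I0/I1/I2
      }
    }
    last_end <- en[n_ex]
  }
  label_seq(labels, strand, record$sequence_id)
}

#' Decode a label path into gene models
#'
#' The inverse of [encode_reference_labels()]: maximal `START`..`STOP` runs
#' become single-transcript genes, with `DSS`/`ASS` border states delimiting
#' introns. Reverse-strand paths are mapped back to forward-genome
#' coordinates.
#'
#' @param path A [label_seq()].
#' @param sequence_id Sequence id for the output (defaults to the path's).
#' @param strict If `TRUE`, an ungrammatical path is an error naming the first
#'   offending position. If `FALSE`, structurally invalid gene candidates are
#'   skipped and counted (attribute `n_skipped`), which is what whole-genome
#'   inference uses at tile junctions.
#' @return An [annotation_set()] with genes `g1`, `g2`, ... in coordinate
#'   order.
#' @export
decode_state_path <- function(path, sequence_id = NULL, strict = TRUE) {
  labels <- as.integer(path)
  strand <- attr(path, "strand") %||% "forward"
  sequence_id <- sequence_id %||% attr(path, "sequence_id") %||% "seq"
  T <- length(labels)
  if (strict) {
    v <- cpp_grammar_violation(labels, FALSE)
    if (v != 0L) {
      stop(sprintf("ungrammatical label path at position %d", v))
    }
  }
  starts <- which(labels == 14L)
  stops <- which(labels == 15L)
  genes <- list()
  n_skipped <- 0L
  i <- 1L
  last_e <- 0L
  while (i <= length(starts)) {
    s <- starts[i]
    if (s <= last_e) { i <- i + 1L; next }
    e <- stops[stops > s][1]
    if (is.na(e)) break
    slice <- labels[s:e]
    ok <- cpp_grammar_violation(slice, FALSE) == 0L && !any(slice == 1L) &&
      sum(slice == 14L) == 1L
    if (!ok) {
      n_skipped <- n_skipped + 1L
      i <- i + 1L
      next
    }
    ass <- which(slice %in% 8:10)
    dss <- which(slice %in% 11:13)
    ex_s <- sort(c(1L, ass)) + s - 1L      # 1-based strand positions
    ex_e <- sort(c(dss, e - s + 1L)) + s - 1L
    # strand-local 0-based half-open intervals
    st0 <- ex_s - 1L
    en0 <- ex_e
    if (strand == "reverse") {
      tmp <- T - en0
      en0 <- T - st0
      st0 <- tmp
      ord <- order(st0)
      st0 <- st0[ord]
      en0 <- en0[ord]
    }
    genes[[length(genes) + 1L]] <- tibble(
      seqid = sequence_id, strand = if (strand == "forward") "+" else "-",
      start = st0, end = en0)
    last_e <- e
    i <- i + 1L
  }
  if (length(genes) == 0L) {
    out <- annotation_set(NULL)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  ord <- order(vapply(genes, function(g) min(g$start), integer(1)))
  rows <- dplyr::bind_rows(lapply(seq_along(ord), function(j) {
    g <- genes[[ord[j]]]
    g$gene_id <- sprintf("g%d", j)
    g$transcript_id <- sprintf("g%d.t1", j)
    g
  }))
  out <- annotation_set(rows)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Run-length view of a label sequence
#'
#' A compact BED-like tibble of maximal runs of identical states, useful for
#' debugging label encodings and decoded paths.
#'
#' @param path A [label_seq()].
#' @return A tibble with `state`, `start` (0-based), `end` (half-open).
#' @export
label_runs <- function(path) {
  r <- rle(as.integer(path))
  e <- cumsum(r$lengths)
  tibble(state = .STATES[r$values], start = c(0L, e[-length(e)]), end = e)
}
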