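#' Construct an annotation set
#'
#' An annotation set is a tibble of CDS intervals, one row per coding exon,
#' with columns `seqid`, `gene_id`, `transcript_id`, `strand` (`"+"`/`"-"`),
#' `start` and `end`. Coordinates are 0-based half-open internally; GTF input
#' and output converts to and from the 1-based inclusive convention at the I/O
#' boundary only.
#'
#' @param cds A data frame with the columns above.
#' @param source_path Optional path the annotation was read from.
#' @return A tibble of class `annotation_set`, sorted by
#'   (`seqid`, `start`, `gene_id`, `transcript_id`).
#' @export
annotation_set <- function(cds = NULL, source_path = NA_character_) {
  if (is.null(cds) || nrow(as.data.frame(cds)) == 0L) {
    cds <- tibble(seqid = character(), gene_id = character(),
                  transcript_id = character(), strand = character(),
                  start = integer(), end = integer())
  }
  cds <- as_tibble(cds)[, c("seqid", "gene_id", "transcript_id",
                            "strand", "start", "end")]
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  if (any(cds$end <= cds$start)) stop("CDS intervals must have end > start")
  if (!all(cds$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  cds <- dplyr::arrange(cds, .data$seqid, .data$start,
                        .data$gene_id, .data$transcript_id)
  # CDS intervals within a transcript must be non-overlapping
  chk <- dplyr::group_by(cds, .data$seqid, .data$transcript_id)
  bad <- dplyr::summarise(chk,
    ov = any(head(.data$end, -1) > tail(.data$start, -1)), .groups = "drop")
  if (any(bad$ov)) {
    stop(sprintf("overlapping CDS intervals in transcript '%s'",
                 bad$transcript_id[which(bad$ov)[1]]))
  }
  attr(cds, "source_path") <- source_path
  class(cds) <- c("annotation_set", class(cds))
  cds
}

#' Read a GTF or GFF3 annotation
#'
#' Extracts CDS features grouped by transcript. GTF files must carry
#' `gene_id`/`transcript_id` attributes; GFF3 files resolve the
#' CDS -> mRNA -> gene `Parent` chain. 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read annotation file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    return(annotation_set(NULL, source_path = path))
  }
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  is_cds <- !is.na(mc$type) & toupper(as.character(mc$type)) == "CDS"
  cds <- gr[is_cds]
  if (length(cds) == 0L) return(annotation_set(NULL, source_path = path))
  mcc <- S4Vectors::mcols(cds)

  if ("transcript_id" %in% names(mcc) && !all(is.na(mcc$transcript_id))) {
    tx <- as.character(mcc$transcript_id)
    gid <- if ("gene_id" %in% names(mcc)) as.character(mcc$gene_id) else tx
  } else if ("Parent" %in% names(mcc)) {
    # Parent is a CharacterList; take the first parent of each CDS
    par <- vapply(mcc$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
    tx <- sub("^(transcript|mRNA):", "", par)
    # map transcript -> gene via mRNA/transcript features
    mcall <- S4Vectors::mcols(gr)
    is_tx <- !is.na(mcall$type) &
      tolower(as.character(mcall$type)) %in% c("mrna", "transcript")
    tx_id <- sub("^(transcript|mRNA):", "", as.character(mcall$ID[is_tx]))
    tx_par <- vapply(mcall$Parent[is_tx],
                     function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
    tx_gene <- sub("^gene:", "", tx_par)
    gid <- tx_gene[match(tx, tx_id)]
    gid[is.na(gid)] <- tx[is.na(gid)]
  } else {
    stop(sprintf("CDS features in '%s' carry no transcript id", path))
  }
  if (any(is.na(tx) | tx == "")) {
    stop(sprintf("CDS feature without transcript id in '%s'", path))
  }
  annotation_set(tibble(
    seqid = as.character(GenomicRanges::seqnames(cds)),
    gene_id = gid,
    transcript_id = tx,
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds)
  ), source_path = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GTF frame column per exon: bases to skip until the next codon start,
# computed in transcript (5'->3') order
.gtf_frames <- function(starts, ends, strand) {
  ord <- if (strand == "+") order(starts) else order(-starts)
  len <- (ends - starts)[ord]
  cum <- c(0L, cumsum(len))[seq_along(len)]
  fr <- (3L - (cum %% 3L)) %% 3L
  fr[order(ord)]
}

#' Write gene models as GTF
#'
#' Emits `gene`, `transcript` and `CDS` rows with 1-based inclusive
#' coordinates and correct frame column. The stop codon is included in the
#' terminal CDS (noted in the header). Output ordering is deterministic:
#' sequences, then gene start, then gene id. Overlapping same-strand genes
#' trigger a warning but are still written.
#'
#' @param genes An [annotation_set()] (one transcript per gene for predicted
#'   gene models, but multi-isoform sets are written faithfully).
#' @param path Output file path.
#' @param source Value of the GTF source column.
#' @return Invisibly, the path.
#' @export
write_annotation <- function(genes, path, source = "exonstate") {
  genes <- annotation_set(genes)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("##gtf-version 2.2", "##stop-codon-included true")
  if (nrow(genes) == 0L) {
    writeLines(hdr, con, sep = "\n")
    return(invisible(path))
  }
  gspan <- dplyr::summarise(
    dplyr::group_by(genes, .data$seqid, .data$gene_id, .data$strand),
    gstart = min(.data$start), gend = max(.data$end), .groups = "drop")
  gspan <- dplyr::arrange(gspan, .data$seqid, .data$gstart, .data$gene_id)
  # warn on overlapping same-strand genes
  ov <- dplyr::group_by(gspan, .data$seqid, .data$strand)
  ov <- dplyr::summarise(ov,
    any_ov = any(head(.data$gend, -1) > tail(.data$gstart, -1)),
    .groups = "drop")
  if (any(ov$any_ov)) warning("overlapping same-strand genes in GTF output")

  lines <- character(0)
  for (i in seq_len(nrow(gspan))) {
    g <- gspan[i, ]
    tx <- dplyr::filter(genes, .data$seqid == g$seqid,
                        .data$gene_id == g$gene_id)
    ga <- sprintf('gene_id "%s";', g$gene_id)
    lines <- c(lines, paste(g$seqid, source, "gene", g$gstart + 1L, g$gend,
                            ".", g$strand, ".", ga, sep = "\t"))
    for (tid in unique(tx$transcript_id)) {
      ex <- dplyr::filter(tx, .data$transcript_id == tid)
      ta <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, tid)
      lines <- c(lines, paste(g$seqid, source, "transcript", min(ex$start) + 1L,
                              max(ex$end), ".", g$strand, ".", ta, sep = "\t"))
      fr <- .gtf_frames(ex$start, ex$end, g$strand)
      lines <- c(lines, paste(ex$seqid, source, "CDS", ex$start + 1L, ex$end,
                              ".", ex$strand, fr, ta, sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), con, sep = "\n")
  invisible(path)
}
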