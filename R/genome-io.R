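#' Construct a genome record
#'
#' Normalizes a DNA sequence to the `{A, C, G, T, N}` alphabet. Lowercase
#' letters are read as softmasked repeat positions (repeat track = 1) and
#' uppercased; any letter outside the alphabet is mapped to `N` (a message
#' reports how many).
#'
#' @param sequence A single DNA string.
#' @param sequence_id Identifier of the sequence.
#' @param repeat_track Optional explicit 0/1 repeat flags (overrides the
#'   softmask convention).
#' @return A list of class `genome_record` with fields `sequence_id`,
#'   `sequence` (uppercase ACGTN string), `repeat_track` (integer 0/1 vector)
#'   and `length`.
#' @export
#' @examples
#' rec <- genome_record("acgTNR")
#' rec$sequence
#' rec$repeat_track
genome_record <- function(sequence, sequence_id = "seq", repeat_track = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) {
    stop(sprintf("record '%s' is empty", sequence_id))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (is.null(repeat_track)) {
    repeat_track <- as.integer(chars %in% c("a", "c", "g", "t", "n"))
  } else {
    repeat_track <- as.integer(repeat_track != 0)
    if (length(repeat_track) != length(chars)) {
      stop("repeat_track length must equal sequence length")
    }
  }
  up <- toupper(chars)
  bad <- !(up %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    message(sprintf("record '%s': %d non-ACGTN letters mapped to N",
                    sequence_id, sum(bad)))
    up[bad] <- "N"
  }
  structure(
    list(sequence_id = sequence_id,
         sequence = paste(up, collapse = ""),
         repeat_track = repeat_track,
         length = length(chars)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bases, %.1f%% softmasked\n",
              x$sequence_id, x$length, 100 * mean(x$repeat_track)))
  invisible(x)
}

#' Read a (softmasked) FASTA file
#'
#' Lowercase letters mark repeat regions and populate the per-base repeat
#' track; the stored sequence is uppercased and normalized to ACGTN.
#'
#' @param path Path to a FASTA file (possibly multi-record, possibly gzipped).
#' @return A list of [genome_record()] objects.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read FASTA file '%s'", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf(
                    "cannot parse FASTA file '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("FASTA file '%s' contains no records", path))
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- as.character(set[[i]])
    if (nchar(s) == 0L) {
      stop(sprintf("FASTA record '%s' in '%s' is empty", ids[i], path))
    }
    out[[i]] <- genome_record(s, sequence_id = ids[i])
  }
  out
}

#' Reverse complement of a DNA string
#'
#' `N` (and anything outside ACGT) complements to `N`.
#'
#' @param sequence A DNA string over ACGTN.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(sequence) {
  cpp_reverse_complement(sequence)
}

#' Encode a genome record as network input
#'
#' Produces the T x 6 numeric input of the network: five one-hot columns for
#' A, C, G, T, N plus the repeat track as a sixth column. For the reverse
#' strand, the rows encode the reverse complement of the sequence and the
#' repeat track is reversed, so that the same forward-strand model can predict
#' genes on the opposite strand.
#'
#' @param record A [genome_record()].
#' @param strand `"forward"` or `"reverse"`.
#' @return A list of class `input_encoding` with fields `matrix` (T x 6) and
#'   `strand`.
#' @export
#' @examples
#' enc <- encode_input(genome_record("ACGT"), "forward")
#' enc$matrix
encode_input <- function(record, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  stopifnot(inherits(record, "genome_record"))
  if (strand == "forward") {
    m <- cpp_encode_sequence(record$sequence, record$repeat_track)
  } else {
    m <- cpp_encode_sequence(cpp_reverse_complement(record$sequence),
                             rev(record$repeat_track))
  }
  colnames(m) <- c("A", "C", "G", "T", "N", "repeat")
  structure(list(matrix = m, strand = strand), class = "input_encoding")
}
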