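#' The 15-state gene-structure alphabet
#'
#' Every base of a genome is labeled with one of 15 gene-structure states:
#' intergenic (`IR`), three intron states `I0`/`I1`/`I2` indexed by the codon
#' position of the next coding base, and 11 coding-exon states subdivided by
#' reading frame: interior exon states `E0`/`E1`/`E2` (index = codon position
#' of the base), acceptor and donor splice-site border states
#' `ASS0..2`/`DSS0..2` marking the first and last base of non-initial and
#' non-terminal coding exons, and single-position `START` (first base of the
#' start codon) and `STOP` (last base of the stop codon) border states.
#'
#' The state order is fixed and shared by every component of the package:
#' label encoding, the network output layer, the losses and the HMM.
#'
#' @return A list with elements `states` (ordered state names),
#'   `n_states` (15), `exon_classes` (indices of the 11 coding states),
#'   `noncoding` (indices of the 4 non-coding states), and `edges`
#'   (a 23-row tibble of the allowed transitions).
#' @export
#' @examples
#' ab <- state_alphabet()
#' ab$states
#' nrow(ab$edges)
state_alphabet <- function() {
  states <- c("IR", "I0", "I1", "I2", "E0", "E1", "E2",
              "ASS0", "ASS1", "ASS2", "DSS0", "DSS1", "DSS2", "START", "STOP")
  el <- cpp_edge_list()
  list(
    states = states,
    n_states = 15L,
    exon_classes = 5:15,
    noncoding = 1:4,
    edges = tibble(
      from = states[el$from], to = states[el$to],
      from_index = el$from, to_index = el$to
    )
  )
}

# internal fast accessors
.STATES <- c("IR", "I0", "I1", "I2", "E0", "E1", "E2",
             "ASS0", "ASS1", "ASS2", "DSS0", "DSS1", "DSS2", "START", "STOP")
.S <- as.list(setNames(seq_along(.STATES), .STATES))
.EXON_CLASSES <- 5:15
.NONCODING <- 1:4

#' Construct a label sequence
#'
#' A label sequence is an integer vector of state indices (1..15, in the order
#' of [state_alphabet()]) with the strand and sequence id attached. Reverse
#' strand label sequences are expressed in reverse-complement coordinates
#' (position 1 is the last forward-genome base).
#'
#' @param labels Integer vector of state indices in `[1, 15]`.
#' @param strand `"forward"` or `"reverse"`.
#' @param sequence_id Sequence identifier the labels refer to.
#' @return An integer vector of class `label_seq`.
#' @export
label_seq <- function(labels, strand = c("forward", "reverse"),
                      sequence_id = "seq") {
  strand <- match.arg(strand)
  labels <- as.integer(labels)
  if (length(labels) && (min(labels) < 1L || max(labels) > 15L)) {
    stop("label values must lie in [1, 15]")
  }
  structure(labels, strand = strand, sequence_id = sequence_id,
            class = "label_seq")
}

#' @export
print.label_seq <- function(x, ...) {
  cat(sprintf("<label_seq> %s (%s strand), %d positions\n",
              attr(x, "sequence_id"), attr(x, "strand"), length(x)))
  n <- min(length(x), 60L)
  cat(paste(.STATES[unclass(x)[seq_len(n)]], collapse = " "),
      if (length(x) > n) "...\n" else "\n")
  invisible(x)
}

#' Validate a label path against the gene-structure grammar
#'
#' Checks that every adjacent pair of labels is one of the 23 transitions of
#' the gene-structure HMM and (optionally) that the path starts and ends in
#' intergenic state.
#'
#' @param path A [label_seq()] or plain integer vector of state indices.
#' @param check_boundaries Require the path to start and end in `IR`.
#' @return A list with `valid` (logical) and `violation_at` (1-based position
#'   of the first offending label, `NA` if valid).
#' @export
#' @examples
#' validate_grammar(label_seq(c(1, 1, 14, 6, 15, 1)))
validate_grammar <- function(path, check_boundaries = TRUE) {
  v <- cpp_grammar_violation(as.integer(path), check_boundaries)
  list(valid = v == 0L, violation_at = if (v == 0L) NA_integer_ else v)
}
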