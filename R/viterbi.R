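.log_params <- function(params) {
  list(logA = suppressWarnings(log(params$A)),
       loginit = suppressWarnings(log(params$init)),
       logfinal = suppressWarnings(log(params$final)))
}

#' Most probable state path (sequential Viterbi)
#'
#' Dynamic program over the 23-edge transition graph in log space. Ties are
#' broken deterministically toward the lowest state index at every maximization
#' step, the same rule the segment-parallel decoder uses.
#'
#' @param likelihoods T x 15 emission likelihood matrix.
#' @param params An [build_transitions()] object.
#' @param strand,sequence_id Metadata attached to the returned path.
#' @return A [label_seq()] with attribute `score` (path log-probability).
#' @export
viterbi_sequential <- function(likelihoods, params, strand = "forward",
                               sequence_id = "seq") {
  lp <- .log_params(params)
  res <- cpp_viterbi(suppressWarnings(log(likelihoods)), lp$logA,
                     lp$loginit, lp$logfinal)
  out <- label_seq(res$path, strand, sequence_id)
  attr(out, "score") <- res$score
  out
}

#' Most probable state path (segment-parallel Viterbi)
#'
#' Partitions the sequence into segments of `segment_length`, summarizes each
#' segment independently by a 15 x 15 max-plus score matrix (best in-segment
#' path score for every entry/exit state pair), folds the summaries left to
#' right with one max-plus product per segment, and reconstructs the path by
#' re-running only the chosen segments seeded with the exact border score
#' vectors. The returned path is identical to [viterbi_sequential()] under the
#' shared lowest-index tie-break; the per-segment summaries depend only on
#' their own segment, which is what makes the summary phase parallelizable.
#' The per-segment cost is 15 times the sequential cost (one conditioned run
#' per entry state).
#'
#' @inheritParams viterbi_sequential
#' @param segment_length Segment size in bases (>= 2). A value >= T reduces to
#'   a single segment, i.e. the sequential algorithm.
#' @return A [label_seq()] with attribute `score`.
#' @export
viterbi_parallel <- function(likelihoods, params, segment_length = 4096,
                             strand = "forward", sequence_id = "seq") {
  lp <- .log_params(params)
  res <- cpp_viterbi_parallel(suppressWarnings(log(likelihoods)), lp$logA,
                              lp$loginit, lp$logfinal, as.integer(segment_length))
  out <- label_seq(res$path, strand, sequence_id)
  attr(out, "score") <- res$score
  out
}

#' Max-plus product of segment summaries
#'
#' Combines two adjacent segment summaries: `(a %x% b)[p, q] =
#' max_r a[p, r] + b[r, q]`. Summaries carry any crossing transition scores on
#' their left edge, so the product is associative with the identity summary
#' [maxplus_identity()] (a zero-length segment) as neutral element; `-Inf`
#' marks entry/exit pairs with no grammatical in-segment path.
#'
#' @param a,b 15 x 15 max-plus score matrices.
#' @return The combined 15 x 15 max-plus score matrix.
#' @export
maxplus_combine <- function(a, b) {
  stopifnot(all(dim(a) == c(15, 15)), all(dim(b) == c(15, 15)))
  out <- matrix(-Inf, 15, 15)
  for (r in 1:15) {
    ar <- a[, r]
    br <- b[r, ]
    fin <- ar > -Inf
    if (!any(fin) || all(br == -Inf)) next
    cand <- outer(ar, br, "+")
    cand[!fin, ] <- -Inf
    out <- pmax(out, cand)
  }
  out
}

#' @rdname maxplus_combine
#' @export
maxplus_identity <- function() {
  m <- matrix(-Inf, 15, 15)
  diag(m) <- 0
  m
}

#' Log-score of a given state path
#'
#' Sums boundary weights, transition log-probabilities and emission
#' log-likelihoods along a path; used as a self-consistency check on decoded
#' paths.
#'
#' @inheritParams viterbi_sequential
#' @param path A [label_seq()] or integer vector.
#' @return The path log-score.
#' @export
path_score <- function(likelihoods, params, path) {
  lp <- .log_params(params)
  cpp_path_score(suppressWarnings(log(likelihoods)), lp$logA, lp$loginit,
                 lp$logfinal, as.integer(path))
}
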