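#' Build the fixed 24-parameter gene-structure HMM
#'
#' Transition probabilities are derived from mean region lengths so that state
#' runs follow geometric length distributions with the configured means:
#' `IR -> IR = 1 - 1/L_intergenic`, `I_j -> I_j = 1 - 1/L_intron`, and each
#' interior exon state exits with total probability `1/L_exon`. The `E1` row
#' has two exits (`DSS2` into an intron, `STOP` ending the gene); its split is
#' derived from the mean coding length per gene, keeping the free parameter
#' count at 23 transition values plus one emission-smoothing value = 24. All
#' other rows have a single exit with probability 1. The HMM itself is never
#' trained; it carries the gene-structure grammar.
#'
#' @param mean_lengths Named numeric vector or list with `intergenic`,
#'   `intron`, `coding_exon` mean lengths in bases (all > 1).
#' @param epsilon Emission smoothing in `[0, 1)`; emissions are
#'   `(1 - epsilon) * X + epsilon / 15` before masking.
#' @param mean_coding_length Mean total CDS length of a gene in bases; the
#'   `E1 -> STOP` exit fraction defaults to the reciprocal of this length in
#'   codons. Default: 4 coding exons of mean length.
#' @param stop_exit_fraction Directly override the `E1` stop-exit fraction.
#' @param boundary `"IR"` (paths must start and end intergenic; whole-record
#'   decoding) or `"free"` (uniform boundary weights; used for interior tiles
#'   of the two-pass stitcher).
#' @return An object of class `hmm_params`: list with `A` (15 x 15
#'   row-stochastic matrix supported on the 23 edges), `init`, `final`,
#'   `epsilon`, `mean_lengths`, `stop_exit_fraction`.
#' @export
#' @examples
#' h <- build_transitions(c(intergenic = 1000, intron = 100, coding_exon = 50))
#' sum(h$A > 0)  # 23 edges
build_transitions <- function(mean_lengths = c(intergenic = 49800,
                                               intron = 3200,
                                               coding_exon = 150),
                              epsilon = 0.01,
                              mean_coding_length = NULL,
                              stop_exit_fraction = NULL,
                              boundary = c("IR", "free")) {
  boundary <- match.arg(boundary)
  ml <- as.list(mean_lengths)
  need <- c("intergenic", "intron", "coding_exon")
  if (!all(need %in% names(ml))) {
    stop("mean_lengths must name intergenic, intron and coding_exon")
  }
  if (any(unlist(ml[need]) <= 1)) stop("mean lengths must be > 1")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  L_ir <- ml$intergenic; L_in <- ml$intron; L_ex <- ml$coding_exon
  if (is.null(mean_coding_length)) mean_coding_length <- 4 * L_ex
  if (is.null(stop_exit_fraction)) {
    stop_exit_fraction <- 1 / (mean_coding_length / 3)
  }
  if (stop_exit_fraction <= 0 || stop_exit_fraction >= 1) {
    stop("stop_exit_fraction must be in (0, 1)")
  }

  s <- .S
  A <- matrix(0, 15, 15, dimnames = list(.STATES, .STATES))
  A[s$IR, s$IR] <- 1 - 1 / L_ir
  A[s$IR, s$START] <- 1 / L_ir
  A[s$START, s$E1] <- 1
  ex_exit <- 1 / L_ex
  A[s$E0, s$E1] <- 1 - ex_exit; A[s$E0, s$DSS1] <- ex_exit
  A[s$E2, s$E0] <- 1 - ex_exit; A[s$E2, s$DSS0] <- ex_exit
  A[s$E1, s$E2] <- 1 - ex_exit
  A[s$E1, s$STOP] <- ex_exit * stop_exit_fraction
  A[s$E1, s$DSS2] <- ex_exit * (1 - stop_exit_fraction)
  A[s$DSS0, s$I1] <- 1; A[s$DSS1, s$I2] <- 1; A[s$DSS2, s$I0] <- 1
  for (j in 0:2) {
    Ij <- s[[paste0("I", j)]]
    A[Ij, Ij] <- 1 - 1 / L_in
    A[Ij, s[[paste0("ASS", j)]]] <- 1 / L_in
  }
  A[s$ASS0, s$E1] <- 1; A[s$ASS1, s$E2] <- 1; A[s$ASS2, s$E0] <- 1
  A[s$STOP, s$IR] <- 1

  if (boundary == "IR") {
    init <- c(1, rep(0, 14))
    final <- c(1, rep(0, 14))
  } else {
    init <- rep(1 / 15, 15)
    final <- rep(1, 15)
  }
  structure(list(A = A, init = init, final = final, epsilon = epsilon,
                 mean_lengths = unlist(ml[need]),
                 stop_exit_fraction = stop_exit_fraction,
                 boundary = boundary),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf(
    "<hmm_params> 15 states, %d edges, epsilon = %g, boundary = %s\n",
    sum(x$A > 0), x$epsilon, x$boundary))
  cat(sprintf("  mean lengths: intergenic %g, intron %g, coding exon %g\n",
              x$mean_lengths["intergenic"], x$mean_lengths["intron"],
              x$mean_lengths["coding_exon"]))
  invisible(x)
}

# copy of an hmm_params with different boundary handling
.with_boundary <- function(params, init_ir, final_ir) {
  params$init <- if (init_ir) c(1, rep(0, 14)) else rep(1 / 15, 15)
  params$final <- if (final_ir) c(1, rep(0, 14)) else rep(1, 15)
  params
}

#' Per-position state constraint masks from the DNA sequence
#'
#' Signal states are only allowed where the sequence shows the corresponding
#' pattern: `START` on the A of an `ATG`, `STOP` on the last base of
#' `TAA`/`TAG`/`TGA`, donor states where `GT` follows, acceptor states where
#' `AG` precedes. Codon-position-2 exon states (`E2`, `DSS2`) are forbidden
#' where a stop triplet ends, which prevents in-frame stop codons within an
#' exon (stops spliced across an intron are not prevented and are handled by
#' [filter_spliced_stops()]). Non-coding states are never masked; windows
#' containing `N` or touching the sequence boundary do not license signal
#' states.
#'
#' @param record A [genome_record()] or a plain DNA string.
#' @param strand `"forward"` or `"reverse"` (the mask is computed on the
#'   reverse complement for the reverse strand).
#' @return A T x 15 binary integer matrix; 1 = state allowed.
#' @export
sequence_constraint_masks <- function(record, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  seq <- if (inherits(record, "genome_record")) record$sequence else record
  if (strand == "reverse") seq <- cpp_reverse_complement(seq)
  m <- cpp_constraint_mask(seq)
  colnames(m) <- .STATES
  m
}

#' Masked, smoothed emission likelihoods
#'
#' `likelihood[i, q] = mask[i, q] * ((1 - epsilon) * X[i, q] + epsilon / 15)`.
#' Rows are not normalized; masked entries are exactly 0.
#'
#' @param X T x 15 class-probability matrix (rows on the simplex).
#' @param mask T x 15 binary constraint mask (see
#'   [sequence_constraint_masks()]); `NULL` for all-allowed.
#' @param epsilon Smoothing parameter in `[0, 1)`.
#' @return T x 15 likelihood matrix.
#' @export
emission_likelihoods <- function(X, mask = NULL, epsilon = 0.01) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  lik <- (1 - epsilon) * X + epsilon / 15
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(X))) stop("mask and X dimensions disagree")
    lik <- lik * mask
  }
  lik
}

#' Differentiable forward-backward posteriors
#'
#' Computes the posterior state probabilities `P(Y_i = q | X)` under the
#' gene-structure HMM with per-step scaling. The computation is smooth in the
#' emission likelihoods; [posterior_vjp()] backpropagates a loss gradient on
#' the posteriors to the likelihoods (and onward to the network during
#' fine-tuning). HMM parameters stay fixed.
#'
#' @param likelihoods T x 15 emission likelihood matrix (see
#'   [emission_likelihoods()]).
#' @param params An [build_transitions()] object.
#' @param keep_cache Keep the scaled intermediates needed by
#'   [posterior_vjp()].
#' @return A T x 15 posterior matrix (rows sum to 1) with attribute `loglik`;
#'   with `keep_cache = TRUE`, a list `(posteriors, loglik, cache)`.
#' @export
forward_backward <- function(likelihoods, params, keep_cache = FALSE) {
  res <- cpp_forward_backward(likelihoods, params$A, params$init, params$final)
  gamma <- res$gamma
  colnames(gamma) <- .STATES
  if (keep_cache) {
    return(list(posteriors = gamma, loglik = res$loglik, cache = res))
  }
  attr(gamma, "loglik") <- res$loglik
  gamma
}

#' Backpropagate a posterior gradient to the emission likelihoods
#'
#' @param fb Result of `forward_backward(..., keep_cache = TRUE)`.
#' @param likelihoods The likelihood matrix passed to [forward_backward()].
#' @param params The same [build_transitions()] object.
#' @param dposteriors T x 15 gradient of a scalar loss with respect to the
#'   posteriors.
#' @return T x 15 gradient with respect to the likelihoods.
#' @export
posterior_vjp <- function(fb, likelihoods, params, dposteriors) {
  cpp_forward_backward_vjp(likelihoods, params$A, params$init, params$final,
                           fb$cache, dposteriors)
}
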