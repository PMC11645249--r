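#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted network: one row per parameter block
#'
#' @param x An `exonstate_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `rows`, `cols`, `n`.
#' @export
tidy.exonstate_model <- function(x, ...) {
  dplyr::mutate(x$shapes, n = .data$rows * .data$cols,
                term = .data$name)[, c("term", "rows", "cols", "n")]
}

#' One-row summary of a fitted network
#'
#' @param x An `exonstate_model`.
#' @param ... Unused.
#' @return A tibble with parameter count, training extent and final losses.
#' @export
glance.exonstate_model <- function(x, ...) {
  h <- x$history
  tibble(
    preset = x$config$preset,
    n_params = x$n_params,
    steps = if (is.null(h)) 0L else max(h$step),
    loss = if (is.null(h)) NA_real_ else tail(h$loss, 1),
    val_loss = if (is.null(h)) NA_real_ else tail(h$val_loss, 1),
    val_exon_f1 = if (is.null(h)) NA_real_ else tail(h$val_exon_f1, 1),
    val_gene_f1 = if (is.null(h)) NA_real_ else tail(h$val_gene_f1, 1))
}

#' Tidy the HMM: one row per transition edge
#'
#' @param x An `hmm_params` object.
#' @param ... Unused.
#' @return A 23-row tibble with `from`, `to`, `probability`.
#' @export
tidy.hmm_params <- function(x, ...) {
  idx <- which(x$A > 0, arr.ind = TRUE)
  out <- tibble(from = .STATES[idx[, 1]], to = .STATES[idx[, 2]],
                probability = x$A[idx])
  dplyr::arrange(out, match(.data$from, .STATES), match(.data$to, .STATES))
}

#' One-row summary of the HMM structure
#'
#' @param x An `hmm_params` object.
#' @param ... Unused.
#' @return A tibble with state/edge/parameter counts and epsilon.
#' @export
glance.hmm_params <- function(x, ...) {
  tibble(n_states = ncol(x$A),
         n_coding_states = length(.EXON_CLASSES),
         n_noncoding_states = length(.NONCODING),
         n_edges = sum(x$A > 0),
         n_free_parameters = sum(x$A > 0) + 1L,
         epsilon = x$epsilon)
}

#' Plot training history
#'
#' Loss (training and validation) and, when available, validation exon/gene
#' F1 over training steps.
#'
#' @param object A `training_history` tibble (the `history` element of a
#'   trained model).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_history <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"step",
                              names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "training step", y = NULL)
}

#' Heatmap of per-base class probabilities
#'
#' @param X A T x 15 class-probability (or posterior) matrix.
#' @param from,to Base range to show (1-based, inclusive).
#' @return A ggplot object.
#' @export
plot_class_probabilities <- function(X, from = 1L, to = min(nrow(X), 2000L)) {
  sub <- X[from:to, , drop = FALSE]
  df <- tibble(position = rep(from:to, times = 15),
               state = factor(rep(.STATES, each = nrow(sub)),
                              levels = rev(.STATES)),
               probability = as.vector(sub))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$state,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "genome position", y = NULL)
}

#' Exon-structure plot of gene models
#'
#' Draws CDS exons as boxes per gene, strands separated.
#'
#' @param annotation An [annotation_set()].
#' @return A ggplot object.
#' @export
plot_gene_models <- function(annotation) {
  ann <- as_tibble(annotation_set(annotation))
  ggplot2::ggplot(ann) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = as.integer(factor(.data$gene_id)) - 0.4,
      ymax = as.integer(factor(.data$gene_id)) + 0.4,
      fill = .data$strand)) +
    ggplot2::facet_wrap(~ .data$seqid, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position", y = "gene") +
    ggplot2::theme_minimal()
}
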