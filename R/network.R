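.lcm <- function(a, b) a * b / .gcd(a, b)
.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Network architecture configuration
#'
#' A CNN -> biLSTM -> dense sequence-to-sequence network mapping the T x 6
#' input encoding to T x 15 class probabilities. A reshape by
#' `reshape_factor` pools consecutive bases into one LSTM step (both published
#' sequence lengths, 9999 for training and 500,004 for inference, are
#' divisible by the default factor 9); the dense head emits 15 logits per
#' base. `use_residual` concatenates the reshaped convolutional features to
#' the biLSTM output before the dense head, a skip connection that preserves
#' base-resolution signal detail.
#'
#' Presets: `tiny` (~0.1M parameters, for desk-scale experiments and tests),
#' `small` (~2M, the halved-width variant), `full` (~8M). The layer-by-layer
#' sizes are engineering reconstructions at the stated parameter budgets. The
#' `tiny` preset uses an exponentially dilated convolution ladder (dilations
#' 1, 3, ..., 729 at width 9), giving every base a receptive field of about
#' +/- 4.4 kb: whether a base lies in an intron is then a locally computable
#' property (the nearest splice signal is visible), which a small model can
#' learn quickly, instead of state that the biLSTM must carry across hundreds
#' of steps.
#'
#' @param preset One of `"tiny"`, `"small"`, `"full"`.
#' @param conv_filters,conv_width,conv_dilations,reshape_factor,lstm_units,lstm_layers,use_residual,dropout
#'   Override individual fields of the preset.
#' @return A list of class `network_config`.
#' @export
network_config <- function(preset = c("tiny", "small", "full"),
                           conv_filters = NULL, conv_width = NULL,
                           conv_dilations = NULL, reshape_factor = NULL,
                           lstm_units = NULL, lstm_layers = NULL,
                           use_residual = NULL, dropout = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = list(conv_filters = c(24L, rep(16L, 6L)), conv_width = 9L,
                conv_dilations = c(1L, 3L, 9L, 27L, 81L, 243L, 729L),
                reshape_factor = 9L, lstm_units = 16L, lstm_layers = 1L,
                use_residual = TRUE, dropout = 0),
    small = list(conv_filters = c(32L, 48L), conv_width = 9L,
                 conv_dilations = c(1L, 1L),
                 reshape_factor = 9L, lstm_units = 192L, lstm_layers = 2L,
                 use_residual = TRUE, dropout = 0),
    full = list(conv_filters = c(64L, 96L), conv_width = 9L,
                conv_dilations = c(1L, 1L),
                reshape_factor = 9L, lstm_units = 384L, lstm_layers = 2L,
                use_residual = TRUE, dropout = 0))
  ov <- list(conv_filters = conv_filters, conv_width = conv_width,
             conv_dilations = conv_dilations, reshape_factor = reshape_factor,
             lstm_units = lstm_units, lstm_layers = lstm_layers,
             use_residual = use_residual, dropout = dropout)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) cfg[[nm]] <- ov[[nm]]
  cfg$conv_filters <- as.integer(cfg$conv_filters)
  if (is.null(ov$conv_dilations) &&
      length(cfg$conv_dilations) != length(cfg$conv_filters)) {
    cfg$conv_dilations <- rep(1L, length(cfg$conv_filters))
  }
  cfg$conv_dilations <- as.integer(cfg$conv_dilations)
  if (length(cfg$conv_dilations) != length(cfg$conv_filters)) {
    stop("conv_dilations must match conv_filters in length")
  }
  for (nm in c("conv_width", "reshape_factor", "lstm_units", "lstm_layers")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  cfg$use_residual <- isTRUE(cfg$use_residual)
  cfg$preset <- preset
  if (cfg$conv_width %% 2L == 0L) stop("conv_width must be odd")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  structure(cfg, class = "network_config")
}

#' Window length granularity of a network
#'
#' Input lengths must be divisible by `lcm(3, reshape_factor)` (a whole number
#' of LSTM steps and of codons); [predict_class_probabilities()] pads and
#' trims transparently at inference, but training windows must comply.
#'
#' @param config A [network_config()].
#' @return The integer granularity.
#' @export
window_granularity <- function(config) {
  as.integer(.lcm(3, config$reshape_factor))
}

#' Build (initialize) a network
#'
#' Weights use uniform Glorot initialization, biases start at zero except the
#' LSTM forget-gate bias (1, the standard choice that keeps early memory
#' open). Deterministic given the seed.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `exonstate_model`: list with `par` (flat
#'   parameter vector), `config`, `shapes`, `n_params`, `history`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  shapes <- as_tibble(cpp_nn_param_shapes(config))
  set.seed(seed)
  par <- numeric(sum(shapes$rows * shapes$cols))
  off <- 0L
  for (i in seq_len(nrow(shapes))) {
    n <- shapes$rows[i] * shapes$cols[i]
    if (grepl("_b$", shapes$name[i])) {
      v <- numeric(n)
      if (grepl("^lstm", shapes$name[i])) {
        u <- shapes$cols[i] / 4L
        v[(u + 1L):(2L * u)] <- 1  # forget gate bias
      }
    } else {
      lim <- sqrt(6 / (shapes$rows[i] + shapes$cols[i]))
      v <- runif(n, -lim, lim)
    }
    par[(off + 1L):(off + n)] <- v
    off <- off + n
  }
  structure(list(par = par, config = config, shapes = shapes,
                 n_params = length(par), history = NULL),
            class = "exonstate_model")
}

#' @export
print.exonstate_model <- function(x, ...) {
  cat(sprintf("<exonstate_model> preset '%s': %s parameters\n",
              x$config$preset, format(x$n_params, big.mark = ",")))
  cat(sprintf("  conv %s (width %d) -> reshape %d -> %d x biLSTM(%d) -> dense 15/base%s\n",
              paste(x$config$conv_filters, collapse = "/"), x$config$conv_width,
              x$config$reshape_factor, x$config$lstm_layers,
              x$config$lstm_units,
              if (x$config$use_residual) " (+conv skip)" else ""))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d steps, last loss %.4f\n",
                max(x$history$step), tail(x$history$loss, 1)))
  }
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param x An `exonstate_model` or [network_config()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "exonstate_model")) return(x$n_params)
  s <- cpp_nn_param_shapes(x)
  sum(s$rows * s$cols)
}

.pad_rows <- function(X, gran) {
  T <- nrow(X)
  pad <- (gran - T %% gran) %% gran
  if (pad == 0L) return(list(X = X, pad = 0L))
  extra <- matrix(0, pad, ncol(X))
  extra[, 5] <- 1  # N
  list(X = rbind(X, extra), pad = pad)
}

#' Predict per-base class probabilities
#'
#' Deterministic given the weights; inputs whose length is not a multiple of
#' the window granularity are padded with `N` rows and the output trimmed back,
#' so any length is accepted.
#'
#' @param model An `exonstate_model`.
#' @param encoding An [encode_input()] result or a plain T x 6 matrix.
#' @return A T x 15 class-probability matrix (rows sum to 1).
#' @export
predict_class_probabilities <- function(model, encoding) {
  X <- if (inherits(encoding, "input_encoding")) encoding$matrix else encoding
  p <- .pad_rows(X, window_granularity(model$config))
  probs <- cpp_nn_forward(model$par, model$config, p$X, FALSE, FALSE)
  if (p$pad > 0L) probs <- probs[seq_len(nrow(X)), , drop = FALSE]
  colnames(probs) <- .STATES
  probs
}
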