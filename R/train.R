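#' Training configuration
#'
#' Defaults follow the published regime where it applies at desk scale:
#' seamless windows of length 9999, Adam with learning rate 1e-4, validation
#' every `validation_interval` steps with checkpoint selection by the combined
#' validation exon- and gene-level F1.
#'
#' @param window_length Training window length in bases (must be divisible by
#'   the network's [window_granularity()]).
#' @param batch_size Windows per gradient step.
#' @param learning_rate Adam step size.
#' @param max_steps Total number of gradient steps.
#' @param validation_interval Steps between validation evaluations.
#' @param val_fraction Fraction of windows held out for validation.
#' @param balance_batches Draw half of every batch from windows containing
#'   coding labels (see Details in the methods vignette); without it, desk
#'   scale batches are dominated by exon-free windows.
#' @param seed Seed controlling shuffling (and dropout, if enabled).
#' @return A list of class `training_config`.
#' @export
training_config <- function(window_length = 9999L, batch_size = 4L,
                            learning_rate = 1e-4, max_steps = 1000L,
                            validation_interval = 100L, val_fraction = 0.1,
                            balance_batches = TRUE, seed = 1L) {
  structure(list(window_length = as.integer(window_length),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_steps = as.integer(max_steps),
                 validation_interval = as.integer(validation_interval),
                 val_fraction = val_fraction,
                 balance_batches = isTRUE(balance_batches),
                 seed = as.integer(seed)),
            class = "training_config")
}

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(state, par, grad, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# window-level exon/gene F1 of Viterbi-decoded predictions vs labels
.window_f1 <- function(par, cfg, windows, hmm) {
  preds <- list()
  refs <- list()
  hmm_w <- .with_boundary(hmm, FALSE, FALSE)  # genes may straddle window edges
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    probs <- cpp_nn_forward(par, cfg, w$X[[1]], FALSE, FALSE)
    mask <- cpp_constraint_mask(w$seq[[1]])
    lik <- emission_likelihoods(probs, mask, hmm$epsilon)
    path <- viterbi_sequential(lik, hmm_w, sequence_id = sprintf("w%d", i))
    preds[[i]] <- decode_state_path(path, strict = FALSE)
    refs[[i]] <- suppressWarnings(decode_state_path(
      label_seq(w$y[[1]], sequence_id = sprintf("w%d", i)), strict = FALSE))
  }
  pred <- dplyr::bind_rows(Map(function(a, i) {
    if (nrow(a)) a$seqid <- sprintf("w%d", i); a
  }, preds, seq_along(preds)))
  ref <- dplyr::bind_rows(Map(function(a, i) {
    if (nrow(a)) a$seqid <- sprintf("w%d", i); a
  }, refs, seq_along(refs)))
  m <- evaluate_annotations(annotation_set(pred), annotation_set(ref))
  c(exon = m$f1[m$level == "exon"], gene = m$f1[m$level == "gene"])
}

.check_windows <- function(dataset, cfg, window_length) {
  gran <- .lcm(3, cfg$reshape_factor)
  if (window_length %% gran != 0L) {
    stop(sprintf("window length %d is not divisible by the granularity %d",
                 window_length, gran))
  }
  lens <- vapply(dataset$X, nrow, integer(1))
  if (any(lens %% gran != 0L)) {
    stop("dataset contains windows not divisible by the window granularity")
  }
}

.train_loop <- function(model, dataset, loss_config, training_config, hmm,
                        grad_fn, verbose) {
  tc <- training_config
  .check_windows(dataset, model$config, tc$window_length)
  set.seed(tc$seed)
  n <- nrow(dataset)
  n_val <- if (tc$val_fraction > 0 && n >= 5L) {
    max(1L, round(tc$val_fraction * n))
  } else 0L
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  val <- dataset[val_idx, ]

  par <- model$par
  adam <- .adam_init(length(par))
  history <- list()
  best <- list(par = par, score = -Inf)

  # gene-balanced sampling: with ~1% coding sequence, uniformly sampled
  # batches are dominated by exon-free windows and the minority classes
  # starve at desk scale; half of each batch is drawn from windows that
  # contain coding labels
  has_gene <- vapply(dataset$y[train_idx],
                     function(y) any(y %in% .EXON_CLASSES), logical(1))
  gene_idx <- train_idx[has_gene]
  bg_idx <- train_idx[!has_gene]
  balanced <- tc$balance_batches && length(gene_idx) > 0L &&
    length(bg_idx) > 0L && tc$batch_size >= 2L
  pool_g <- integer(0)
  pool_b <- integer(0)
  order_pool <- integer(0)

  next_from <- function(pool, src, k) {
    while (length(pool) < k) pool <- c(pool, src[sample.int(length(src))])
    pool
  }

  for (step in seq_len(tc$max_steps)) {
    if (balanced) {
      k <- tc$batch_size %/% 2L
      pool_g <- next_from(pool_g, gene_idx, k)
      pool_b <- next_from(pool_b, bg_idx, tc$batch_size - k)
      batch <- c(pool_g[seq_len(k)], pool_b[seq_len(tc$batch_size - k)])
      pool_g <- pool_g[-seq_len(k)]
      pool_b <- pool_b[-seq_len(tc$batch_size - k)]
    } else {
      order_pool <- next_from(order_pool, train_idx, tc$batch_size)
      batch <- order_pool[seq_len(tc$batch_size)]
      order_pool <- order_pool[-seq_len(tc$batch_size)]
    }

    grad <- numeric(length(par))
    loss <- 0
    for (i in batch) {
      gl <- grad_fn(par, dataset[i, ])
      grad <- grad + gl$grad / length(batch)
      loss <- loss + gl$loss / length(batch)
    }
    if (!is.finite(loss)) {
      stop(sprintf("training diverged at step %d (loss = %g)", step, loss))
    }
    upd <- .adam_step(adam, par, grad, tc$learning_rate)
    par <- upd$par
    adam <- upd$state

    if (step %% tc$validation_interval == 0L || step == tc$max_steps) {
      val_loss <- NA_real_
      vf1 <- c(exon = NA_real_, gene = NA_real_)
      if (n_val > 0L) {
        vl <- vapply(seq_len(nrow(val)), function(i) {
          gl <- grad_fn(par, val[i, ], loss_only = TRUE)
          gl$loss
        }, numeric(1))
        val_loss <- mean(vl)
        if (!is.null(hmm)) vf1 <- .window_f1(par, model$config, val, hmm)
        # combined validation F1 decides; validation loss breaks F1 ties
        # (window-level gene F1 can be degenerate when genes span windows)
        score <- if (!is.null(hmm)) sum(vf1) * 1e6 - val_loss else -val_loss
        if (is.finite(score) && score > best$score) {
          best <- list(par = par, score = score)
        }
      } else {
        best <- list(par = par, score = 0)
      }
      history[[length(history) + 1L]] <- tibble(
        step = step, loss = loss, val_loss = val_loss,
        val_exon_f1 = unname(vf1["exon"]), val_gene_f1 = unname(vf1["gene"]))
      if (verbose) {
        message(sprintf("step %d: loss %.4f val %.4f exonF1 %.3f geneF1 %.3f",
                        step, loss, val_loss, vf1["exon"], vf1["gene"]))
      }
    }
  }
  model$par <- if (is.finite(best$score) && best$score > -Inf) best$par else par
  hist <- dplyr::bind_rows(history)
  class(hist) <- c("training_history", class(hist))
  model$history <- dplyr::bind_rows(model$history, hist)
  model
}

#' Pre-HMM training
#'
#' Phase-one training: minimizes the CCE-F1 loss on the raw network output
#' probabilities (no HMM layer), with Adam. The checkpoint returned is the one
#' with the highest combined validation exon- and gene-level F1 (decoded with
#' `hmm`); without an `hmm` the lowest validation loss wins. Deterministic
#' given the seed.
#'
#' @param model An `exonstate_model` from [build_network()].
#' @param dataset A window tibble from [make_training_set()].
#' @param loss_config A [loss_config()].
#' @param training_config A [training_config()].
#' @param hmm Optional [build_transitions()] object used for validation
#'   decoding and checkpoint selection.
#' @param verbose Print progress.
#' @return The trained `exonstate_model` with a `history` tibble.
#' @export
train_pre_hmm <- function(model, dataset, loss_config = NULL,
                          training_config = NULL, hmm = NULL,
                          verbose = FALSE) {
  if (is.null(loss_config)) loss_config <- exonstate::loss_config()
  if (is.null(training_config)) training_config <- exonstate::training_config()
  grad_fn <- function(par, w, loss_only = FALSE) {
    if (loss_only) {
      probs <- cpp_nn_forward(par, model$config, w$X[[1]], FALSE, FALSE)
      return(list(loss = cce_f1_loss(w$y[[1]], probs, loss_config)))
    }
    fw <- cpp_nn_forward(par, model$config, w$X[[1]], TRUE, TRUE)
    loss <- cce_f1_loss(w$y[[1]], fw$probs, loss_config)
    dprobs <- cce_f1_grad(w$y[[1]], fw$probs, loss_config)
    list(loss = loss,
         grad = cpp_nn_backward(par, model$config, fw$cache, dprobs))
  }
  .train_loop(model, dataset, loss_config, training_config, hmm, grad_fn,
              verbose)
}

#' End-to-end fine-tuning through the HMM layer
#'
#' Phase-two training: the CCE-F1 loss is applied to the forward-backward
#' posteriors of the HMM on the (masked, smoothed) network output, and
#' gradients flow through the HMM layer into the network. The HMM parameters
#' themselves stay fixed.
#'
#' @inheritParams train_pre_hmm
#' @param hmm The [build_transitions()] object defining the HMM layer
#'   (required).
#' @return The fine-tuned `exonstate_model`.
#' @export
fine_tune_with_hmm <- function(model, hmm, dataset,
                               loss_config = NULL,
                               training_config = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(hmm, "hmm_params"))
  if (is.null(loss_config)) loss_config <- exonstate::loss_config()
  if (is.null(training_config)) training_config <- exonstate::training_config()
  # training windows are seamless cuts through the genome, so a gene may
  # straddle a window edge: posteriors use free boundary weights (whole-record
  # decoding keeps the IR boundary)
  hmm_w <- .with_boundary(hmm, FALSE, FALSE)
  grad_fn <- function(par, w, loss_only = FALSE) {
    mask <- cpp_constraint_mask(w$seq[[1]])
    if (loss_only) {
      probs <- cpp_nn_forward(par, model$config, w$X[[1]], FALSE, FALSE)
      lik <- emission_likelihoods(probs, mask, hmm$epsilon)
      post <- forward_backward(lik, hmm_w)
      return(list(loss = cce_f1_loss(w$y[[1]], post, loss_config)))
    }
    fw <- cpp_nn_forward(par, model$config, w$X[[1]], TRUE, TRUE)
    lik <- emission_likelihoods(fw$probs, mask, hmm$epsilon)
    fb <- forward_backward(lik, hmm_w, keep_cache = TRUE)
    loss <- cce_f1_loss(w$y[[1]], fb$posteriors, loss_config)
    dpost <- cce_f1_grad(w$y[[1]], fb$posteriors, loss_config)
    dlik <- posterior_vjp(fb, lik, hmm_w, dpost)
    dprobs <- dlik * mask * (1 - hmm$epsilon)
    list(loss = loss,
         grad = cpp_nn_backward(par, model$config, fw$cache, dprobs))
  }
  .train_loop(model, dataset, loss_config, training_config, hmm, grad_fn,
              verbose)
}
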