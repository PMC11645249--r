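#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the flat weight vector and training
#' history, with a JSON sidecar (`<path>.json`) describing the architecture so
#' checkpoints are self-documenting.
#'
#' @param model An `exonstate_model`.
#' @param path Checkpoint path.
#' @return `save_model` invisibly returns the path; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg, n_params = model$n_params,
         package_version = as.character(utils::packageVersion("exonstate"))),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "exonstate_model")) stop("not an exonstate checkpoint")
  model
}

#' Write a genome record as softmasked FASTA
#'
#' Repeat-track positions are written lowercase (the softmask convention read
#' back by [read_genome()]). Mainly used by the `simulate` CLI subcommand.
#'
#' @param records A [genome_record()] or list of them.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (rec in records) {
    chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
    low <- rec$repeat_track == 1L
    chars[low] <- tolower(chars[low])
    seq <- paste(chars, collapse = "")
    writeLines(paste0(">", rec$sequence_id), con, sep = "\n")
    starts <- seq.int(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
               con, sep = "\n")
  }
  invisible(path)
}
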