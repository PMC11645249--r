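#' Synthetic genome simulation settings
#'
#' The generator plants canonical protein-coding genes (ATG start, TAA/TAG/TGA
#' stop, GT-AG introns, frame-consistent exons, no in-frame stops, spliced or
#' not) in random background sequence. Region lengths are geometric with the
#' configured means, matching the length model of the decoding HMM. Defaults
#' target the human-like genome composition of ~1% coding, ~16% intron, ~83%
#' intergenic: the mean intergenic length is derived from `coding_fraction`
#' unless given explicitly.
#'
#' Coding sequence is sampled with biased codon usage and splice sites carry
#' extended context (GTAAG donor, polypyrimidine tract + AG acceptor) by
#' default — the sequence features real genes exhibit and that make the
#' planted genes learnable for a small network.
#'
#' @param genome_length Total genome length in bases.
#' @param coding_fraction Target fraction of coding bases (drives the derived
#'   mean intergenic length).
#' @param mean_intergenic Mean intergenic length; `NULL` derives it from
#'   `coding_fraction`.
#' @param mean_intron,mean_exon Mean intron / coding-exon lengths in bases.
#' @param mean_exons_per_gene Mean number of coding exons per gene.
#' @param gc_content Background GC fraction.
#' @param repeat_fraction Fraction of the genome covered by the simulated
#'   softmask track (random intervals, independent of genes).
#' @param splice_context Plant extended splice-site consensus beyond GT/AG.
#' @param codon_bias_weight Sampling weight of each amino acid's preferred
#'   codon relative to its alternatives (1 = uniform usage).
#' @param noise Class-probability noise for
#'   [simulate_class_probabilities()]: list with `flip_prob` and
#'   `temperature`.
#' @param min_exon,min_intron Minimum region lengths.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 1000008L, coding_fraction = 0.01,
                              mean_intergenic = NULL, mean_intron = 3200,
                              mean_exon = 150, mean_exons_per_gene = 4,
                              gc_content = 0.42, repeat_fraction = 0.2,
                              splice_context = TRUE, codon_bias_weight = 8,
                              noise = list(flip_prob = 0, temperature = 0),
                              min_exon = 12, min_intron = 25, seed = 1L) {
  if (is.null(mean_intergenic)) {
    coding_per_gene <- mean_exons_per_gene * mean_exon
    intron_per_gene <- (mean_exons_per_gene - 1) * mean_intron
    mean_intergenic <- coding_per_gene * (1 - coding_fraction) /
      coding_fraction - intron_per_gene
  }
  cfg <- list(genome_length = as.integer(genome_length),
              coding_fraction = coding_fraction,
              mean_intergenic = mean_intergenic, mean_intron = mean_intron,
              mean_exon = mean_exon,
              mean_exons_per_gene = mean_exons_per_gene,
              gc_content = gc_content, repeat_fraction = repeat_fraction,
              splice_context = splice_context,
              codon_bias_weight = codon_bias_weight, noise = noise,
              min_exon = as.integer(min_exon),
              min_intron = as.integer(min_intron), seed = as.integer(seed))
  if (cfg$mean_intergenic <= 1) {
    stop("infeasible composition: derived mean intergenic length <= 1")
  }
  if (any(c(cfg$mean_intron, cfg$mean_exon) <= 1) ||
      cfg$gc_content < 0 || cfg$gc_content > 1 ||
      cfg$repeat_fraction < 0 || cfg$repeat_fraction > 1) {
    stop("invalid simulation settings")
  }
  if (cfg$min_intron < 20L) stop("min_intron must be >= 20")
  structure(cfg, class = "simulation_config")
}

# sense codons with a preferred codon per amino acid (the GC-richest,
# alphabetically first on ties), weighted by codon_bias_weight
.codon_table <- function(bias) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  gcc <- vapply(strsplit(sense, ""), function(x) sum(x %in% c("G", "C")),
                numeric(1))
  w <- rep(1, length(sense))
  for (aa in unique(gc[sense])) {
    idx <- which(gc[sense] == aa)
    pref <- idx[order(-gcc[idx], sense[idx])][1]
    w[pref] <- bias
  }
  list(codons = sense, prob = w / sum(w))
}

.rand_bases <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# geometric length with a minimum and the requested mean
.rlen <- function(n, mean, min) {
  if (mean <= min) return(rep(as.integer(min), n))
  min + rgeom(n, 1 / (mean - min + 1))
}

.make_gene <- function(cfg, ct) {
  n_ex <- 1L + rpois(1, cfg$mean_exons_per_gene - 1)
  ex <- .rlen(n_ex, cfg$mean_exon, cfg$min_exon)
  total <- sum(ex)
  ex[n_ex] <- ex[n_ex] + (3L - total %% 3L) %% 3L
  total <- sum(ex)
  n_cod <- total %/% 3L
  cds <- paste0("ATG",
                paste(sample(ct$codons, n_cod - 2L, replace = TRUE,
                             prob = ct$prob), collapse = ""),
                sample(.STOP_CODONS, 1L))
  if (n_ex > 1L) {
    inlen <- .rlen(n_ex - 1L, cfg$mean_intron, cfg$min_intron)
    introns <- vapply(inlen, function(l) {
      if (cfg$splice_context) {
        tract <- paste(sample(c("C", "T"), 12, replace = TRUE,
                              prob = c(0.35, 0.65)), collapse = "")
        paste0("GTAAG",
               paste(.rand_bases(l - 19L, cfg$gc_content), collapse = ""),
               tract, "AG")
      } else {
        paste0("GT", paste(.rand_bases(l - 4L, cfg$gc_content), collapse = ""),
               "AG")
      }
    }, character(1))
  } else {
    inlen <- integer(0)
    introns <- character(0)
  }
  cum <- c(0L, cumsum(ex))
  pieces <- character(2L * n_ex - 1L)
  local_start <- integer(n_ex)
  off <- 0L
  for (k in seq_len(n_ex)) {
    pieces[2L * k - 1L] <- substring(cds, cum[k] + 1L, cum[k + 1L])
    local_start[k] <- off
    off <- off + ex[k]
    if (k < n_ex) {
      pieces[2L * k] <- introns[k]
      off <- off + inlen[k]
    }
  }
  list(seq = paste(pieces, collapse = ""), exon_start = local_start,
       exon_len = ex, length = off)
}

#' Simulate a genome with planted gene structures
#'
#' Generates a genome record, its single-isoform annotation, and the per-base
#' label sequences for both strands (labels are produced by
#' [encode_reference_labels()] and are guaranteed grammatical). Every planted
#' gene is canonical by construction and survives [filter_spliced_stops()].
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param sequence_id Name of the simulated sequence.
#' @return A list of class `synthetic_genome` with elements `record`,
#'   `annotation`, `labels_forward`, `labels_reverse`, `config`.
#' @export
simulate_genome <- function(config = simulation_config(),
                            sequence_id = "chrSim") {
  cfg <- config
  set.seed(cfg$seed)
  ct <- .codon_table(cfg$codon_bias_weight)
  G <- cfg$genome_length
  chunks <- list()
  rows <- list()
  pos <- 0L
  gi <- 0L
  repeat {
    ig <- 1L + rgeom(1, 1 / cfg$mean_intergenic)
    gene <- .make_gene(cfg, ct)
    if (pos + ig + gene$length + 1L > G) {
      if (G - pos > 0L) {
        chunks[[length(chunks) + 1L]] <-
          paste(.rand_bases(G - pos, cfg$gc_content), collapse = "")
      }
      break
    }
    chunks[[length(chunks) + 1L]] <-
      paste(.rand_bases(ig, cfg$gc_content), collapse = "")
    gstart <- pos + ig
    strand <- sample(c("+", "-"), 1L)
    gi <- gi + 1L
    gid <- sprintf("sg%04d", gi)
    if (strand == "+") {
      chunks[[length(chunks) + 1L]] <- gene$seq
      st <- gstart + gene$exon_start
      en <- st + gene$exon_len
    } else {
      chunks[[length(chunks) + 1L]] <- cpp_reverse_complement(gene$seq)
      en <- gstart + gene$length - gene$exon_start
      st <- en - gene$exon_len
      o <- order(st)
      st <- st[o]
      en <- en[o]
    }
    rows[[gi]] <- tibble(seqid = sequence_id, gene_id = gid,
                         transcript_id = paste0(gid, ".t1"), strand = strand,
                         start = st, end = en)
    pos <- gstart + gene$length
  }
  sequence <- paste(unlist(chunks), collapse = "")
  stopifnot(nchar(sequence) == G)

  rpt <- integer(G)
  if (cfg$repeat_fraction > 0) {
    target <- cfg$repeat_fraction * G
    covered <- 0
    while (covered < target) {
      l <- min(.rlen(1, 500, 50), G)
      s <- sample.int(G - l + 1L, 1L)
      rpt[s:(s + l - 1L)] <- 1L
      covered <- covered + l
    }
  }
  record <- genome_record(sequence, sequence_id, repeat_track = rpt)
  annotation <- annotation_set(dplyr::bind_rows(rows))
  structure(list(
    record = record,
    annotation = annotation,
    labels_forward = encode_reference_labels(annotation, record, "forward"),
    labels_reverse = encode_reference_labels(annotation, record, "reverse"),
    config = cfg
  ), class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  comp <- genome_composition(x)
  cat(sprintf(
    "<synthetic_genome> %s: %d bases, %d genes (%.2f%% coding, %.1f%% intron)\n",
    x$record$sequence_id, x$record$length,
    length(unique(x$annotation$gene_id)), 100 * comp["coding"],
    100 * comp["intron"]))
  invisible(x)
}

#' Genome composition of a simulation
#'
#' Fractions of coding, intron and intergenic bases, counting a base as coding
#' or intronic if it is so on either strand.
#'
#' @param sim A [simulate_genome()] result.
#' @return Named numeric vector `coding`, `intron`, `intergenic`.
#' @export
genome_composition <- function(sim) {
  f <- as.integer(sim$labels_forward)
  r <- rev(as.integer(sim$labels_reverse))  # map to forward coordinates
  coding_f <- f >= 5L
  coding_r <- r >= 5L
  intron_f <- f >= 2L & f <= 4L
  intron_r <- r >= 2L & r <= 4L
  coding <- mean(coding_f | coding_r)
  intron <- mean((intron_f | intron_r) & !(coding_f | coding_r))
  c(coding = coding, intron = intron, intergenic = 1 - coding - intron)
}

#' Simulate class probabilities for a label sequence
#'
#' Stands in for network output: with zero noise the rows are exact one-hot
#' indicators of the labels; `flip_prob` moves a fraction of rows to a random
#' wrong class, and `temperature` blends rows toward uniform
#' (`u = temperature / (1 + temperature)`), so the rows stay on the simplex.
#'
#' @param labels A [label_seq()].
#' @param noise List with `flip_prob` and `temperature`.
#' @param seed Optional seed.
#' @return A T x 15 class-probability matrix.
#' @export
simulate_class_probabilities <- function(labels,
                                         noise = list(flip_prob = 0,
                                                      temperature = 0),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.integer(labels)
  T <- length(y)
  flip <- noise$flip_prob %||% 0
  temp <- noise$temperature %||% 0
  if (flip > 0) {
    hit <- which(runif(T) < flip)
    if (length(hit)) {
      wrong <- (y[hit] - 1L + sample.int(14L, length(hit), replace = TRUE)) %% 15L + 1L
      y[hit] <- wrong
    }
  }
  u <- temp / (1 + temp)
  X <- matrix(u / 15, T, 15)
  X[cbind(seq_len(T), y)] <- X[cbind(seq_len(T), y)] + (1 - u)
  colnames(X) <- .STATES
  X
}

#' Cut a simulated genome into seamless training windows
#'
#' Non-overlapping windows of `window_length` covering both strands (the
#' reverse strand in reverse-complement coordinates); a final partial window
#' is dropped. Deterministic.
#'
#' @param sim A [simulate_genome()] result.
#' @param window_length Window length in bases.
#' @param strands Which strands to include.
#' @return A tibble with one row per window: `seqid`, `strand`, `start`
#'   (strand-local, 0-based), and list-columns `X` (T x 6 encoding), `y`
#'   (label vector), `seq` (window sequence).
#' @export
make_training_set <- function(sim, window_length = 9999L,
                              strands = c("forward", "reverse")) {
  W <- as.integer(window_length)
  T <- sim$record$length
  n_win <- T %/% W
  out <- list()
  for (strand in strands) {
    if (strand == "forward") {
      seq <- sim$record$sequence
      rpt <- sim$record$repeat_track
      y <- as.integer(sim$labels_forward)
    } else {
      seq <- cpp_reverse_complement(sim$record$sequence)
      rpt <- rev(sim$record$repeat_track)
      y <- as.integer(sim$labels_reverse)
    }
    for (w in seq_len(n_win)) {
      a <- (w - 1L) * W
      sub <- substring(seq, a + 1L, a + W)
      out[[length(out) + 1L]] <- tibble(
        seqid = sim$record$sequence_id, strand = strand, start = a,
        X = list(cpp_encode_sequence(sub, rpt[(a + 1L):(a + W)])),
        y = list(y[(a + 1L):(a + W)]),
        seq = list(sub))
    }
  }
  dplyr::bind_rows(out)
}
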