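# Independent oracles and fixture builders shared across tests.

# plain data-frame view of an annotation's coordinates, for set comparisons
coord_frame <- function(ann) {
  d <- as.data.frame(ann)[, c("seqid", "strand", "start", "end")]
  d <- d[order(d$seqid, d$start, d$end, d$strand), ]
  rownames(d) <- NULL
  attributes(d) <- attributes(d)[c("names", "class", "row.names")]
  d
}

# adjacency matrix of the 23-edge grammar, built independently from an
# explicit edge list (not from the package's own edge table)
oracle_edges <- function() {
  s <- c(IR = 1, I0 = 2, I1 = 3, I2 = 4, E0 = 5, E1 = 6, E2 = 7,
         ASS0 = 8, ASS1 = 9, ASS2 = 10, DSS0 = 11, DSS1 = 12, DSS2 = 13,
         START = 14, STOP = 15)
  from <- c("IR", "IR", "START", "E0", "E1", "E2", "E2", "E0", "E1",
            "DSS0", "DSS1", "DSS2", "I0", "I1", "I2", "I0", "I1", "I2",
            "ASS0", "ASS1", "ASS2", "E1", "STOP")
  to <- c("IR", "START", "E1", "E1", "E2", "E0", "DSS0", "DSS1", "DSS2",
          "I1", "I2", "I0", "I0", "I1", "I2", "ASS0", "ASS1", "ASS2",
          "E1", "E2", "E0", "STOP", "IR")
  E <- matrix(FALSE, 15, 15)
  E[cbind(s[from], s[to])] <- TRUE
  E
}

# brute-force sum/max over all paths on the transition graph (T small);
# returns posteriors, log-likelihood, best path score and best path
oracle_enumerate <- function(lik, params) {
  A <- params$A
  init <- params$init
  fin <- params$final
  T <- nrow(lik)
  probs <- c()
  paths <- list()
  rec <- function(path, p) {
    t <- length(path)
    if (t == T) {
      if (p * fin[path[T]] > 0) {
        paths[[length(paths) + 1]] <<- path
        probs <<- c(probs, p * fin[path[T]])
      }
      return()
    }
    for (q in 1:15) {
      step <- if (t == 0) init[q] else A[path[t], q]
      pr <- p * step * lik[t + 1, q]
      if (pr > 0) rec(c(path, q), pr)
    }
  }
  rec(integer(0), 1)
  if (length(probs) == 0) return(NULL)
  gamma <- matrix(0, T, 15)
  for (k in seq_along(paths)) {
    for (t in 1:T) gamma[t, paths[[k]][t]] <- gamma[t, paths[[k]][t]] + probs[k]
  }
  list(posteriors = gamma / sum(probs), loglik = log(sum(probs)),
       best_score = max(log(probs)),
       best_path = paths[[which.max(probs)]])
}

# independent re-validation of a predicted GTF against the genome sequence:
# every gene must start with ATG, end with a stop codon, use GT..AG introns,
# have total CDS length divisible by 3 and no internal in-frame stop in its
# spliced CDS (the spliced-stop filter guarantee)
oracle_validate_gtf <- function(gtf_path, fasta_path) {
  ann <- read_annotation(gtf_path)
  recs <- read_genome(fasta_path)
  names(recs) <- vapply(recs, `[[`, character(1), "sequence_id")
  stops <- c("TAA", "TAG", "TGA")
  rc <- function(s) vapply(s, exonstate::reverse_complement, character(1),
                           USE.NAMES = FALSE)
  ok <- TRUE
  for (tid in unique(ann$transcript_id)) {
    tx <- ann[ann$transcript_id == tid, ]
    seq <- recs[[tx$seqid[1]]]$sequence
    ord <- order(tx$start)
    parts <- substring(seq, tx$start[ord] + 1, tx$end[ord])
    cds <- paste(parts, collapse = "")
    if (tx$strand[1] == "-") cds <- rc(cds)
    n <- nchar(cds)
    ok <- ok && n %% 3 == 0 && startsWith(cds, "ATG") &&
      substring(cds, n - 2, n) %in% stops
    if (n >= 6) {
      cod <- substring(cds, seq(1, n - 3, 3), seq(3, n - 3, 3))
      ok <- ok && !any(cod[-length(cod)] %in% stops) &&
        !any(cod %in% stops)  # no internal stop at all before the terminal one
    }
    if (nrow(tx) > 1) {
      st <- sort(tx$start)
      en <- sort(tx$end)
      if (tx$strand[1] == "+") {
        don <- substring(seq, en[-length(en)] + 1, en[-length(en)] + 2)
        acc <- substring(seq, st[-1] - 1, st[-1])
      } else {
        # minus strand: donor is the revcomp of the last two forward bases
        # before each downstream exon, acceptor of the first two after each
        # upstream exon
        don <- rc(substring(seq, st[-1] - 1, st[-1]))
        acc <- rc(substring(seq, en[-length(en)] + 1, en[-length(en)] + 2))
      }
      ok <- ok && all(don == "GT") && all(acc == "AG")
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# small fully-specified annotation builder (seqid matches genome_record's
# default so the two compose)
toy_annotation <- function(starts, ends, strand = "+", seqid = "seq",
                           gene = "g1", tx = "g1.t1") {
  annotation_set(tibble::tibble(
    seqid = seqid, gene_id = gene, transcript_id = tx, strand = strand,
    start = as.integer(starts), end = as.integer(ends)))
}

# a tiny deterministic genome with one forward two-exon gene used in several
# tests: CDS "ATGA" + intron + "AATAA" (the worked splice example)
toy_two_exon <- function() {
  # positions:        0123456789...
  seq <- paste0("CCC", "ATGA", "GTAAGTTTTTCCCCAG", "AATAA", "GCGCC")
  rec <- genome_record(seq)
  ann <- toy_annotation(c(3L, 23L), c(7L, 28L))
  list(record = rec, annotation = ann)
}

# free-boundary copy of an hmm_params object
.free_boundary <- function(params) {
  params$init <- rep(1 / 15, 15)
  params$final <- rep(1, 15)
  params
}

rand_simplex_matrix <- function(T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rexp(T * 15), T, 15)
  m / rowSums(m)
}
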