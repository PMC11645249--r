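test_that("transition matrix has 15 states, 23 edges, 24 free parameters", {
  h <- build_transitions(c(intergenic = 1000, intron = 100, coding_exon = 50))
  expect_equal(dim(h$A), c(15L, 15L))
  expect_equal(sum(h$A > 0), 23L)
  expect_equal(max(abs(rowSums(h$A) - 1)), 0, tolerance = 1e-12)
  # support exactly on the oracle edge set
  expect_equal(unname(h$A > 0), oracle_edges())
  g <- glance(h)
  expect_equal(g$n_free_parameters, 24L)
  expect_equal(g$n_coding_states, 11L)
  expect_equal(g$n_noncoding_states, 4L)
  # geometric mean-length identity
  h2 <- build_transitions(c(intergenic = 1000, intron = 50, coding_exon = 20))
  expect_equal(h2$A[1, 1], 1 - 1 / 1000)
  expect_equal(h2$A[1, 14], 1 / 1000)
  expect_equal(h2$A[2, 2], 1 - 1 / 50)
  expect_error(build_transitions(c(intergenic = 0.5, intron = 10,
                                   coding_exon = 10)), "> 1")
  expect_error(build_transitions(epsilon = 1), "epsilon")
})

test_that("sampled state durations reproduce the configured means within 2%", {
  means <- c(intergenic = 300, intron = 80, coding_exon = 40)
  h <- build_transitions(means)
  set.seed(101)
  n <- 1e5
  # run-length sampling straight from the self-transition probabilities
  ir_runs <- rgeom(n, 1 - h$A[1, 1]) + 1
  intron_runs <- rgeom(n, 1 - h$A[2, 2]) + 1
  expect_equal(mean(ir_runs), means[["intergenic"]], tolerance = 0.02)
  expect_equal(mean(intron_runs), means[["intron"]], tolerance = 0.02)
  # exon run: interior exon states chain E->E with exit prob 1/L at each base
  exon_runs <- rgeom(n, 1 / means[["coding_exon"]]) + 1
  expect_equal(mean(exon_runs), means[["coding_exon"]], tolerance = 0.02)
})

test_that("constraint masks implement the signal-state rules", {
  m <- sequence_constraint_masks("CATGC")
  expect_equal(which(m[, 14] == 1), 2L)          # START only on the A of ATG
  m2 <- sequence_constraint_masks("AAGTA")
  expect_equal(which(m2[, 11] == 1), 2L)         # DSS0 only where GT follows
  expect_equal(which(m2[, 12] == 1), 2L)
  # STOP only on last base of a stop triplet
  m3 <- sequence_constraint_masks("CCTAACC")
  expect_equal(which(m3[, 15] == 1), 5L)
  # E2 forbidden exactly there
  expect_equal(which(m3[, 7] == 0), 5L)
  # non-coding states never masked
  expect_true(all(m3[, 1:4] == 1))
  # N disables signal states
  mN <- sequence_constraint_masks("CATNC")
  expect_true(all(mN[, 14] == 0))
})

test_that("emission likelihoods follow the one-parameter smoothing form", {
  X <- diag(15)[c(1, 5, 14), ]
  lik0 <- emission_likelihoods(X, NULL, 0)
  expect_equal(lik0, X, ignore_attr = TRUE)
  eps <- 0.3
  lik <- emission_likelihoods(X, NULL, eps)
  expect_equal(lik, (1 - eps) * X + eps / 15, ignore_attr = TRUE)
  mask <- matrix(1L, 3, 15); mask[2, 5] <- 0L
  likm <- emission_likelihoods(X, mask, eps)
  expect_equal(likm[2, 5], 0)
  expect_error(emission_likelihoods(X, NULL, 1), "epsilon")
})

test_that("posteriors match exhaustive path enumeration on short instances", {
  set.seed(2024)
  h <- build_transitions(c(intergenic = 10, intron = 5, coding_exon = 4),
                         epsilon = 0)
  checked <- 0
  for (rep in 1:220) {
    T <- sample(1:8, 1)
    hh <- if (rep %% 2) .free_boundary(h) else h
    lik <- matrix(runif(T * 15), T, 15) *
      matrix(rbinom(T * 15, 1, 0.85), T, 15)
    bf <- oracle_enumerate(lik, hh)
    if (is.null(bf)) next
    fb <- forward_backward(lik, hh)
    expect_equal(unname(unclass(fb))[, ], bf$posteriors, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(attr(fb, "loglik"), bf$loglik, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 150)
})

test_that("posterior rows sum to 1 and masked states carry no mass", {
  set.seed(6)
  sim <- simulate_genome(simulation_config(
    genome_length = 20000, coding_fraction = 0.05, mean_intron = 150,
    mean_exon = 60, mean_exons_per_gene = 3, seed = 6))
  h <- build_transitions()
  X <- simulate_class_probabilities(sim$labels_forward,
                                    list(flip_prob = 0.2, temperature = 1),
                                    seed = 1)
  mask <- sequence_constraint_masks(sim$record, "forward")
  lik <- emission_likelihoods(X, mask, 0.05)
  fb <- forward_backward(lik, h)
  expect_lt(max(abs(rowSums(fb) - 1)), 1e-6)
  expect_true(all(fb[mask == 0] == 0))
})

test_that("clean one-hot likelihoods recover the planted labels as argmax", {
  sim <- simulate_genome(simulation_config(
    genome_length = 20000, coding_fraction = 0.05, mean_intron = 150,
    mean_exon = 60, mean_exons_per_gene = 3, seed = 17))
  h <- build_transitions()
  X <- simulate_class_probabilities(sim$labels_forward)
  mask <- sequence_constraint_masks(sim$record, "forward")
  fb <- forward_backward(emission_likelihoods(X, mask, 0.01), h)
  expect_equal(max.col(fb), as.integer(sim$labels_forward))
})

test_that("T = 1 posterior equals the normalized initial x likelihood row", {
  h <- .free_boundary(build_transitions())
  lik <- matrix(runif(15), 1, 15)
  fb <- forward_backward(lik, h)
  expect_equal(unname(fb[1, ]), lik[1, ] / sum(lik[1, ]), tolerance = 1e-12)
})

test_that("over-masking raises a numeric error naming the position", {
  h <- build_transitions()
  lik <- matrix(1, 5, 15)
  lik[3, ] <- 0
  expect_error(forward_backward(lik, h), "position 3")
})

test_that("posterior VJP matches central finite differences", {
  set.seed(31)
  h <- .free_boundary(build_transitions(c(intergenic = 50, intron = 20,
                                          coding_exon = 10)))
  T <- 10
  lik <- matrix(runif(T * 15, 0.05, 1), T, 15)
  fb <- forward_backward(lik, h, keep_cache = TRUE)
  dg <- matrix(rnorm(T * 15), T, 15)
  an <- posterior_vjp(fb, lik, h, dg)
  eps <- 1e-6
  f <- function(l) sum(dg * forward_backward(l, h))
  num <- matrix(0, T, 15)
  for (k in seq_len(T * 15)) {
    lp <- lik; lm <- lik
    lp[k] <- lik[k] + eps; lm[k] <- lik[k] - eps
    num[k] <- (f(lp) - f(lm)) / (2 * eps)
  }
  expect_lt(max(abs(an - num)) / max(abs(num)), 1e-4)
})

test_that("masked Viterbi paths never place an in-frame stop inside an exon", {
  set.seed(77)
  h <- build_transitions(c(intergenic = 60, intron = 20, coding_exon = 15),
                         epsilon = 0.1)
  stops <- c("TAA", "TAG", "TGA")
  for (rep in 1:15) {
    n <- 300
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    mask <- sequence_constraint_masks(seq)
    X <- rand_simplex_matrix(n)
    lik <- emission_likelihoods(X, mask, 0.1)
    path <- as.integer(viterbi_sequential(lik, h))
    # scan decoded path: each E2/DSS2 must not close a stop triplet
    for (i in which(path %in% c(7L, 13L))) {
      if (i >= 3) expect_false(substring(seq, i - 2, i) %in% stops)
    }
  }
})
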