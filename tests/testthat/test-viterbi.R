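test_that("sequential Viterbi matches brute-force max over all paths", {
  set.seed(90)
  h <- build_transitions(c(intergenic = 10, intron = 5, coding_exon = 4),
                         epsilon = 0)
  checked <- 0
  for (rep in 1:120) {
    T <- sample(1:8, 1)
    hh <- if (rep %% 2) .free_boundary(h) else h
    lik <- matrix(runif(T * 15), T, 15) *
      matrix(rbinom(T * 15, 1, 0.85), T, 15)
    bf <- oracle_enumerate(lik, hh)
    if (is.null(bf)) next
    v <- viterbi_sequential(lik, hh)
    expect_equal(attr(v, "score"), bf$best_score, tolerance = 1e-9)
    expect_equal(as.integer(v), bf$best_path)
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("T = 1 Viterbi is the argmax of initial x likelihood", {
  h <- .free_boundary(build_transitions())
  lik <- matrix(runif(15), 1, 15)
  v <- viterbi_sequential(lik, h)
  expect_equal(as.integer(v), which.max(lik[1, ]))
})

test_that("parallel Viterbi returns the identical path for every segment length", {
  set.seed(404)
  h <- build_transitions(c(intergenic = 60, intron = 20, coding_exon = 15),
                         epsilon = 0.05)
  for (rep in 1:40) {
    T <- sample(50:300, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), T, TRUE), collapse = "")
    mask <- sequence_constraint_masks(seq)
    X <- rand_simplex_matrix(T)
    lik <- emission_likelihoods(X, mask, 0.05)
    hh <- if (rep %% 3 == 0) .free_boundary(h) else h
    vs <- viterbi_sequential(lik, hh)
    for (L in c(7L, 50L, 128L, T + 10L)) {
      vp <- viterbi_parallel(lik, hh, L)
      expect_identical(as.integer(vp), as.integer(vs))
      expect_equal(attr(vp, "score"), attr(vs, "score"), tolerance = 1e-9)
    }
  }
})

test_that("single segment reduces to the sequential decoder", {
  set.seed(5)
  h <- build_transitions()
  sim <- simulate_genome(simulation_config(
    genome_length = 9000, coding_fraction = 0.06, mean_intron = 100,
    mean_exon = 50, mean_exons_per_gene = 2, seed = 5))
  X <- simulate_class_probabilities(sim$labels_forward,
                                    list(flip_prob = 0.1, temperature = 0.3),
                                    seed = 2)
  mask <- sequence_constraint_masks(sim$record, "forward")
  lik <- emission_likelihoods(X, mask, 0.05)
  expect_identical(as.integer(viterbi_parallel(lik, h, nrow(lik) + 1)),
                   as.integer(viterbi_sequential(lik, h)))
})

test_that("decoded paths are grammatical and score-consistent", {
  set.seed(6)
  h <- build_transitions(c(intergenic = 60, intron = 20, coding_exon = 15),
                         epsilon = 0.05)
  for (rep in 1:10) {
    T <- 200
    seq <- paste(sample(c("A", "C", "G", "T"), T, TRUE), collapse = "")
    lik <- emission_likelihoods(rand_simplex_matrix(T),
                                sequence_constraint_masks(seq), 0.05)
    v <- viterbi_parallel(lik, h, 64)
    expect_true(validate_grammar(v)$valid)
    expect_equal(path_score(lik, h, v), attr(v, "score"), tolerance = 1e-9)
  }
})

test_that("clean one-hot likelihoods recover the planted label path exactly", {
  sim <- simulate_genome(simulation_config(
    genome_length = 30000, coding_fraction = 0.05, mean_intron = 150,
    mean_exon = 60, mean_exons_per_gene = 3, seed = 31))
  h <- build_transitions()
  for (strand in c("forward", "reverse")) {
    lab <- if (strand == "forward") sim$labels_forward else sim$labels_reverse
    X <- simulate_class_probabilities(lab)
    mask <- sequence_constraint_masks(sim$record, strand)
    lik <- emission_likelihoods(X, mask, 0.01)
    expect_identical(as.integer(viterbi_parallel(lik, h, 4992)),
                     as.integer(lab))
  }
})

test_that("max-plus combination is associative with the identity as neutral", {
  set.seed(8)
  rand_summary <- function() {
    m <- matrix(-Inf, 15, 15)
    k <- sample(30:120, 1)
    idx <- sample(225, k)
    m[idx] <- rnorm(k)
    m
  }
  for (rep in 1:20) {
    a <- rand_summary(); b <- rand_summary(); c <- rand_summary()
    expect_equal(maxplus_combine(maxplus_combine(a, b), c),
                 maxplus_combine(a, maxplus_combine(b, c)))
    expect_equal(maxplus_combine(a, maxplus_identity()), a)
    expect_equal(maxplus_combine(maxplus_identity(), a), a)
    # direct naive evaluation oracle
    naive <- matrix(-Inf, 15, 15)
    for (p in 1:15) for (q in 1:15) naive[p, q] <- max(a[p, ] + b[, q])
    expect_equal(maxplus_combine(a, b), naive)
  }
  allneg <- matrix(-Inf, 15, 15)
  expect_equal(maxplus_combine(allneg, maxplus_identity()), allneg)
})

test_that("an all-masked instance raises an error", {
  h <- build_transitions()
  lik <- matrix(0, 10, 15)
  expect_error(viterbi_sequential(lik, h), "path")
})
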