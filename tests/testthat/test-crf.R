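# Linear-chain CRF: scoring, partition function, Viterbi, constraints.

test_that("sequence score matches hand arithmetic", {
  # 1 token, zero transitions: emission alone
  em <- matrix(c(1.5, -0.5), 1, 2)
  tr <- matrix(0, 4, 4)
  expect_equal(crf_sequence_score(em, tr, 1L), 1.5)
  expect_equal(crf_sequence_score(em, tr, 2L), -0.5)

  # 2 tokens, 2 labels, hand-filled tables:
  # score(y=1,2) = T[start,1] + E[1,1] + T[1,2] + E[2,2] + T[2,stop]
  em2 <- matrix(c(1, 2, 3, 4), 2, 2)     # E[1,1]=1 E[2,1]=2 E[1,2]=3 E[2,2]=4
  tr2 <- matrix(0, 4, 4)
  tr2[3, 1] <- 0.5   # start -> 1
  tr2[1, 2] <- 0.25  # 1 -> 2
  tr2[2, 4] <- 0.125 # 2 -> stop
  expect_equal(crf_sequence_score(em2, tr2, c(1L, 2L)),
               0.5 + 1 + 0.25 + 4 + 0.125)
})

test_that("log-partition matches closed form and exhaustive enumeration", {
  set.seed(5)
  # 1 token closed form
  em <- matrix(rnorm(3), 1, 3)
  tr <- matrix(rnorm(25), 5, 5)
  manual <- log(sum(exp(tr[4, 1:3] + em[1, ] + tr[1:3, 5])))
  expect_equal(crf_log_partition(em, tr), manual, tolerance = 1e-12)

  # exhaustive oracle on random instances
  for (i in 1:30) {
    n <- sample(1:8, 1); ny <- sample(2:6, 1)
    inst <- random_crf_instance(n, ny)
    expect_equal(crf_log_partition(inst$em, inst$tr),
                 oracle_logz(inst$em, inst$tr), tolerance = 1e-6)
  }
})

test_that("adding a constant to one token's emissions shifts logZ by it", {
  set.seed(6)
  inst <- random_crf_instance(5, 4)
  z0 <- crf_log_partition(inst$em, inst$tr)
  em2 <- inst$em
  em2[3, ] <- em2[3, ] + 2.5
  expect_equal(crf_log_partition(em2, inst$tr), z0 + 2.5, tolerance = 1e-9)
})

test_that("path probabilities normalize and nll is non-negative", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:6, 1); ny <- sample(2:5, 1)
    inst <- random_crf_instance(n, ny)
    z <- crf_log_partition(inst$em, inst$tr)
    sc <- oracle_all_paths(inst$em, inst$tr)
    expect_equal(sum(exp(sc - z)), 1, tolerance = 1e-6)
    gold <- sample(ny, n, TRUE)
    expect_gte(crf_nll(inst$em, inst$tr, gold), 0)
    expect_lte(crf_sequence_score(inst$em, inst$tr, gold), z)
  }
})

test_that("viterbi equals the brute-force argmax", {
  set.seed(8)
  for (i in 1:40) {
    n <- sample(1:8, 1); ny <- sample(2:6, 1)
    inst <- random_crf_instance(n, ny)
    got <- viterbi_decode(inst$em, inst$tr)
    expect_equal(as.integer(got), oracle_argmax(inst$em, inst$tr))
  }
})

test_that("compiled viterbi agrees with the R implementation", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(1:10, 1); ny <- sample(2:8, 1)
    inst <- random_crf_instance(n, ny)
    expect_equal(as.integer(negscope:::cpp_viterbi(inst$em, inst$tr)),
                 as.integer(viterbi_decode(inst$em, inst$tr)))
  }
})

test_that("gold path length and unknown labels are validated", {
  em <- matrix(0, 2, 2)
  tr <- matrix(0, 4, 4)
  expect_error(crf_sequence_score(em, tr, c(1L)), "length")
  expect_error(crf_sequence_score(em, tr, c(1L, 3L)), "range")
  colnames(em) <- c("O", "W-X")
  expect_error(crf_sequence_score(em, tr, c("O", "nope")), "unknown label")
})

test_that("transition constraints exclude shape-invalid paths", {
  labels <- joint_vocabulary(c("X", "Y"))
  mask <- transition_mask(labels)
  ny <- length(labels)
  # M cannot follow O; E-Y cannot follow B-X; start cannot enter E or M
  expect_false(mask["O", "M-X"])
  expect_false(mask["B-X", "E-Y"])
  expect_false(mask["<start>", "E-X"])
  expect_false(mask["B-X", "<stop>"])
  expect_true(mask["B-X", "M-X"])
  expect_true(mask["V-X", "V-Y"])
  expect_true(mask["O", "<stop>"])

  # property: constrained decodes are always codec-valid without repair
  set.seed(10)
  for (i in 1:50) {
    n <- sample(2:9, 1)
    em <- matrix(rnorm(n * ny, sd = 3), n, ny)
    tr <- matrix(rnorm((ny + 2L)^2), ny + 2L, ny + 2L)
    tr[!mask] <- -Inf
    y <- viterbi_decode(em, tr)
    joint <- labels[y]
    expect_true(joint_is_valid(joint))
    expect_equal(bmewov_repair(joint), joint)
  }
})
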