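test_that("sequence score sums emissions and boundary-inclusive transitions", {
  crf <- crf_init(c("t0", "t1"))
  em <- matrix(c(0.5, 0.2, 0.1, 0.9), 2, 2)  # p[1,]=(0.5,0.1), p[2,]=(0.2,0.9)
  expect_equal(sequence_score(em, crf, c("t0", "t1")), 1.4)
  crf$transition["t0", "t1"] <- 0.3
  expect_equal(sequence_score(em, crf, c("t0", "t1")), 1.7)
  crf$transition["t0", "t1"] <- 0
  expect_equal(sequence_score(matrix(0, 2, 2), crf, c(2, 1)), 0)
  expect_error(sequence_score(em, crf, c("t0", "bogus")), "unknown tag")
})

test_that("log partition matches exhaustive enumeration", {
  crf0 <- crf_init(c("t0", "t1"))
  expect_equal(log_partition(matrix(0, 1, 2), crf0), log(2))
  set.seed(51)
  for (rep in 1:5) {
    inst <- random_crf_instance(n = 3, n_tags = 3)
    sc <- enum_scores(inst$em, inst$crf)
    expect_equal(log_partition(inst$em, inst$crf), enum_logsumexp(sc),
                 tolerance = 1e-10)
  }
  ## shift identity: +c on every emission adds n*c
  inst <- random_crf_instance(4, 3)
  expect_equal(log_partition(inst$em + 0.37, inst$crf),
               log_partition(inst$em, inst$crf) + 4 * 0.37)
})

test_that("viterbi decoding matches exhaustive argmax with index tie-break", {
  crf <- crf_init(c("t0", "t1"))
  v <- viterbi_decode(diag(2), crf)
  expect_equal(v$tags, c("t0", "t1"))
  expect_equal(v$score, 2)
  ## all-zero parameters: every path ties; smallest tag index wins
  v0 <- viterbi_decode(matrix(0, 3, 2), crf)
  expect_equal(v0$tags, rep("t0", 3))
  expect_equal(v0$score, 0)
  set.seed(52)
  for (rep in 1:5) {
    inst <- random_crf_instance(n = 4, n_tags = 3)
    sc <- enum_scores(inst$em, inst$crf)
    paths <- enum_paths(4, 3)
    v <- viterbi_decode(inst$em, inst$crf)
    expect_equal(v$score, max(sc), tolerance = 1e-10)
    expect_equal(v$indices, unname(paths[which.max(sc), ]))
    expect_equal(sequence_score(inst$em, inst$crf, v$indices), v$score)
  }
})

test_that("NLL equals logZ minus gold score and is a proper likelihood", {
  crf <- crf_init(c("t0", "t1"))
  expect_equal(nll_loss(matrix(0, 1, 2), crf, "t0"), log(2))
  ## emissions strongly favoring gold drive the loss toward zero
  em <- matrix(0, 3, 2); gold <- c(1L, 2L, 1L)
  em[cbind(1:3, gold)] <- 10
  expect_lt(nll_loss(em, crf, gold), 1e-3)
  expect_gte(nll_loss(em, crf, gold), 0)
  ## agrees with enumerated softmax
  set.seed(53)
  inst <- random_crf_instance(3, 3)
  sc <- enum_scores(inst$em, inst$crf)
  paths <- enum_paths(3, 3)
  k <- 14L
  expect_equal(nll_loss(inst$em, inst$crf, unname(paths[k, ])),
               -(sc[k] - enum_logsumexp(sc)), tolerance = 1e-8)
})

test_that("enumerated path probabilities are normalized", {
  set.seed(54)
  for (rep in 1:4) {
    n <- sample(2:6, 1); Tn <- sample(2:4, 1)
    inst <- random_crf_instance(n, Tn)
    sc <- enum_scores(inst$em, inst$crf)
    expect_equal(sum(exp(sc - log_partition(inst$em, inst$crf))), 1,
                 tolerance = 1e-6)
  }
})

test_that("boosting the decoded path's emissions cannot change the decode", {
  set.seed(55)
  for (rep in 1:10) {
    inst <- random_crf_instance(5, 3)
    v <- viterbi_decode(inst$em, inst$crf)
    em2 <- inst$em
    em2[cbind(seq_len(5), v$indices)] <- em2[cbind(seq_len(5), v$indices)] + 0.8
    expect_equal(viterbi_decode(em2, inst$crf)$indices, v$indices)
  }
})

test_that("BIO transition masking excludes illegal paths", {
  crf <- crf_init(bio_tags(c("disease", "drug")), bio_mask = TRUE)
  expect_equal(crf$transition["O", "I-disease"], -Inf)
  expect_equal(crf$transition["B-disease", "I-drug"], -Inf)
  expect_false(is.infinite(crf$transition["B-disease", "I-disease"]))
  ## decoding never produces an illegal transition
  set.seed(56)
  em <- matrix(rnorm(5 * 5, sd = 3), 5, 5)
  v <- viterbi_decode(em, crf)
  for (i in 2:5)
    expect_true(is.finite(crf$transition[v$indices[i - 1], v$indices[i]]))
})

test_that("CRF gradients match finite differences", {
  set.seed(57)
  inst <- random_crf_instance(4, 3)
  gold <- c(2L, 1L, 3L, 3L)
  g <- softlattice:::crf_gradients(inst$em, inst$crf, gold)
  h <- 1e-6
  for (probe in list(c(1, 2), c(4, 1), c(3, 3))) {
    e2 <- inst$em; e2[probe[1], probe[2]] <- e2[probe[1], probe[2]] + h
    e3 <- inst$em; e3[probe[1], probe[2]] <- e3[probe[1], probe[2]] - h
    fd <- (nll_loss(e2, inst$crf, gold) - nll_loss(e3, inst$crf, gold)) / (2 * h)
    expect_equal(g$d_em[probe[1], probe[2]], fd, tolerance = 1e-5)
  }
  for (probe in list(c(1, 2), c(2, 2), c(4, 5), c(5, 1))) {  # incl. START row
    c2 <- inst$crf; c2$transition[probe[1], probe[2]] <-
      c2$transition[probe[1], probe[2]] + h
    c3 <- inst$crf; c3$transition[probe[1], probe[2]] <-
      c3$transition[probe[1], probe[2]] - h
    fd <- (nll_loss(inst$em, c2, gold) - nll_loss(inst$em, c3, gold)) / (2 * h)
    expect_equal(g$d_trans[probe[1], probe[2]], fd, tolerance = 1e-5)
  }
})
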