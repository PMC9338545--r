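two_word_lattice <- function() {
  lay <- list(spans = data.frame(surface = c("ab", "cd"), head = c(0L, 2L),
                                 tail = c(1L, 3L)))
  build_flat_lattice("abcd", lay)
}

tiny_params <- function(d_model = 8L, n_heads = 2L, n_layers = 1L,
                        tags = c("O", "B-disease", "I-disease"),
                        tokens = c("a", "b", "c", "d", "ab", "cd"), ...) {
  cfg <- list(d_model = d_model, n_heads = n_heads, n_layers = n_layers,
              d_embed = NULL, dropout = 0, position_mode = "four_distance",
              tags = tags)
  cfg[names(list(...))] <- list(...)
  sl_params_init(tokens, cfg)
}

test_that("sinusoid encoding matches its closed form", {
  e0 <- sinusoid_encode(0, 8)
  expect_equal(e0[c(1, 3, 5, 7)], rep(0, 4))
  expect_equal(e0[c(2, 4, 6, 8)], rep(1, 4))
  e1 <- sinusoid_encode(1, 8)
  expect_equal(e1[1], sin(1), tolerance = 1e-12)
  expect_equal(e1[2], cos(1), tolerance = 1e-12)
  expect_equal(e1[3], sin(1 / 10000^(2 / 8)), tolerance = 1e-12)
  ## parity: sin components flip with -d, cos components do not
  em1 <- sinusoid_encode(-1, 8)
  expect_equal(em1[c(1, 3, 5, 7)], -e1[c(1, 3, 5, 7)])
  expect_equal(em1[c(2, 4, 6, 8)], e1[c(2, 4, 6, 8)])
})

test_that("span distances follow the four head/tail differences", {
  lat <- two_word_lattice()
  D <- span_distances(lat)
  ## token 5 is word (0,1); token 3 is character (2,2)
  expect_equal(unname(D[5, 3, ]), c(-2L, -2L, -1L, -1L))
  expect_equal(unname(D[3, 3, ]), c(0L, 0L, 0L, 0L))
})

test_that("relative position codes are ReLU outputs, hence non-negative", {
  set.seed(61)
  params <- tiny_params()
  rp <- relative_position_bias(two_word_lattice(), params)
  expect_true(all(rp$R >= 0))
  expect_equal(nrow(rp$R), 6L * 6L)
})

test_that("attention scores reduce to their hand-evaluated four-term form", {
  ## zero weights: identically zero scores
  n <- 3; d <- 2
  E <- matrix(rnorm(n * d), n, d)
  R <- matrix(abs(rnorm(n * n * d)), n * n, d)
  zero_w <- list(W_q = matrix(0, d, d), W_kE = matrix(0, d, d),
                 W_kR = matrix(0, d, d), u = numeric(d), v = numeric(d))
  expect_equal(attention_scores(E, R, zero_w)[[1]], matrix(0, n, n))

  ## u = v = 0, W_kR = 0: vanilla content-content attention
  set.seed(62)
  W_q <- matrix(rnorm(4), 2, 2); W_kE <- matrix(rnorm(4), 2, 2)
  cc_w <- list(W_q = W_q, W_kE = W_kE, W_kR = matrix(0, 2, 2),
               u = numeric(2), v = numeric(2))
  got <- attention_scores(E, R, cc_w)[[1]]
  want <- (E %*% t(W_q)) %*% t(E %*% t(W_kE)) / sqrt(2)
  expect_equal(got, want, tolerance = 1e-12)

  ## two tokens, hand-set 2x2 weights: symbolic evaluation of all four terms
  E2 <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2, byrow = TRUE)
  R2 <- matrix(c(0.2, 0.0, 0.4, 0.3, 0.1, 0.6, 0.0, 0.5), 4, 2, byrow = TRUE)
  w <- list(W_q = matrix(c(1, 2, -1, 0.5), 2, 2, byrow = TRUE),
            W_kE = matrix(c(0.5, -1, 1, 1), 2, 2, byrow = TRUE),
            W_kR = matrix(c(2, 0, -1, 1), 2, 2, byrow = TRUE),
            u = c(0.1, -0.3), v = c(0.2, 0.4))
  got2 <- attention_scores(E2, R2, w, n_heads = 1L)[[1]]
  want2 <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    q <- w$W_q %*% E2[i, ]; ke <- w$W_kE %*% E2[j, ]
    kr <- w$W_kR %*% R2[(i - 1) * 2 + j, ]
    want2[i, j] <- (sum(q * ke) + sum(q * kr) + sum(w$u * ke) +
                      sum(w$v * kr)) / sqrt(2)
  }
  expect_equal(got2, want2, tolerance = 1e-10)
})

test_that("a zero-layer encoder is the linear map of raw embeddings", {
  set.seed(63)
  params <- tiny_params(n_layers = 0L)
  lat <- two_word_lattice()
  fw <- encoder_forward(lat, params)
  X <- params$embed[match(c("a", "b", "c", "d"), rownames(params$embed)), ]
  expect_equal(fw$emissions,
               X %*% t(params$W_emit) + rep(params$b_emit, each = 4))
})

test_that("inference is deterministic and ignores word-token order", {
  set.seed(64)
  params <- tiny_params(n_layers = 2L, tokens = c("a", "b", "c", "d", "e",
                                                  "ab", "de"))
  lay <- list(spans = data.frame(surface = c("ab", "c", "de"),
                                 head = c(0L, 2L, 3L), tail = c(1L, 2L, 4L)))
  lat <- build_flat_lattice("abcde", lay)
  f1 <- encoder_forward(lat, params)
  f2 <- encoder_forward(lat, params)
  expect_identical(f1$emissions, f2$emissions)

  ## permute the two word tokens (rows 6 and 7): character emissions identical
  lat_p <- lat
  lat_p$tokens <- lat$tokens[c(1:5, 7, 6), ]
  f3 <- encoder_forward(lat_p, params)
  expect_equal(f3$emissions, f1$emissions, tolerance = 1e-12)
})

test_that("attention weights of each row are a probability distribution", {
  set.seed(65)
  params <- tiny_params()
  lat <- two_word_lattice()
  fw <- encoder_forward(lat, params, cache = TRUE)
  for (hc in fw$cache$layers[[1]]$heads) {
    expect_equal(unname(rowSums(hc$alpha)), rep(1, 6))
    expect_true(all(hc$alpha >= 0))
  }
})

test_that("encoder gradients match central finite differences", {
  set.seed(66)
  params <- tiny_params(n_layers = 1L)
  crf <- crf_init(params$config$tags)
  lat <- two_word_lattice()
  gold <- c(2L, 3L, 1L, 1L)
  loss_fn <- function(p) {
    fw <- encoder_forward(lat, p, train_mode = FALSE)
    nll_loss(fw$emissions, crf, gold)
  }
  fw <- encoder_forward(lat, params, cache = TRUE)
  cg <- softlattice:::crf_gradients(fw$emissions, crf, gold)
  g <- softlattice:::encoder_backward(cg$d_em, params, fw)
  h <- 1e-5
  check <- function(getter, setter, gmat, k = 3) {
    x <- getter(params)
    for (i in sample(length(x), min(k, length(x)))) {
      x2 <- x; x2[i] <- x2[i] + h
      x3 <- x; x3[i] <- x3[i] - h
      fd <- (loss_fn(setter(params, x2)) - loss_fn(setter(params, x3))) / (2 * h)
      expect_equal(unname(gmat[i]), fd, tolerance = 1e-4)
    }
  }
  check(function(p) p$embed, function(p, x) { p$embed[] <- x; p }, g$embed)
  check(function(p) p$W_emit, function(p, x) { p$W_emit[] <- x; p }, g$W_emit)
  for (nm in c("W_q", "W_kE", "W_kR", "W_v", "W_r", "u", "v",
               "W1", "b1", "W2", "ln1_g", "ln2_b")) {
    check(function(p) p$layers[[1]][[nm]],
          function(p, x) { p$layers[[1]][[nm]][] <- x; p },
          g$layers[[1]][[nm]], k = 2)
  }
})

test_that("one SGD step decreases the training loss on a small fixture", {
  set.seed(67)
  params <- tiny_params(n_layers = 1L, tokens = c("a", "b", "c", "d",
                                                  "ab", "cd"))
  crf <- crf_init(params$config$tags)
  lats <- list(two_word_lattice(),
               build_flat_lattice("ba", list(spans = data.frame(
                 surface = c("b", "a"), head = 0:1, tail = 0:1))))
  golds <- list(c(2L, 3L, 1L, 1L), c(1L, 2L))
  total_loss <- function(params, crf) {
    sum(vapply(seq_along(lats), function(i) {
      fw <- encoder_forward(lats[[i]], params)
      nll_loss(fw$emissions, crf, golds[[i]])
    }, 0))
  }
  l0 <- total_loss(params, crf)
  gsum <- NULL
  dtrans <- matrix(0, 5, 5)
  for (i in seq_along(lats)) {
    fw <- encoder_forward(lats[[i]], params, cache = TRUE)
    cg <- softlattice:::crf_gradients(fw$emissions, crf, golds[[i]])
    ge <- softlattice:::encoder_backward(cg$d_em, params, fw)
    gsum <- if (is.null(gsum)) ge else softlattice:::acc_grads(gsum, ge)
    dtrans <- dtrans + cg$d_trans
  }
  params2 <- softlattice:::sgd_step(params, gsum, 0.05)
  crf2 <- crf
  fin <- is.finite(crf$transition)
  crf2$transition[fin] <- crf$transition[fin] - 0.05 * dtrans[fin]
  expect_lt(total_loss(params2, crf2), l0)
})

test_that("span-length position mode runs and differs from four-distance", {
  set.seed(69)
  lat <- two_word_lattice()
  p4 <- tiny_params()
  ps <- tiny_params(position_mode = "span_length")
  f4a <- encoder_forward(lat, p4)
  fsa <- encoder_forward(lat, ps)
  fsb <- encoder_forward(lat, ps)
  expect_identical(fsa$emissions, fsb$emissions)   # deterministic
  ## span-length codes depend only on the key token's length: W_r is square
  expect_equal(dim(ps$layers[[1]]$W_r), c(8L, 8L))
  expect_equal(dim(p4$layers[[1]]$W_r), c(8L, 32L))
  ## the two position modes genuinely produce different encodings
  expect_false(isTRUE(all.equal(f4a$emissions, fsa$emissions)))
})

test_that("external embedding tables seed the embedding matrix", {
  emb <- matrix(seq(0.01, 0.12, length.out = 12), 3, 4,
                dimnames = list(c("a", "b", "zz"), NULL))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "emb.txt")
  writeLines(paste(rownames(emb), apply(emb, 1, paste, collapse = " ")), path)
  back <- read_embeddings(path)
  expect_equal(back, emb, tolerance = 1e-12)
  set.seed(68)
  params <- tiny_params(d_model = 4L, n_heads = 2L)
  cfg <- params$config
  p2 <- sl_params_init(c("a", "b", "c"), cfg, embeddings = back)
  expect_equal(p2$embed["a", ], emb["a", ])
  expect_equal(p2$embed["b", ], emb["b", ])
})
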