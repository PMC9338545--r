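test_that("layers are greedy longest-match tilings under shrinking caps", {
  lex <- lexicon_with_counts(
    c("a", "b", "c", "d", "ab", "cd", "abcd"),
    matrix(0L, 7, 2, dimnames = list(c("a", "b", "c", "d", "ab", "cd", "abcd"),
                                     c("disease", "drug"))))
  layers <- build_layers("abcd", lex, max_layers = 3)
  expect_equal(layers[[1]]$spans$surface, "abcd")       # whole sentence
  expect_equal(layers[[1]]$spans$head, 0L)
  expect_equal(layers[[1]]$spans$tail, 3L)
  surfaces <- lapply(layers, function(l) l$spans$surface)
  expect_true(any(vapply(surfaces, function(s)
    identical(s, c("ab", "cd")), TRUE)))
  grans <- vapply(layers, `[[`, 0L, "granularity")
  expect_true(all(diff(grans) < 0))

  ## empty lexicon: every layer is the single-character tiling, deduplicated
  lex0 <- lexicon_with_counts(c("a", "b", "c"),
                              matrix(0L, 3, 1, dimnames = list(c("a", "b", "c"),
                                                               "disease")))
  l0 <- build_layers("abc", lex0, max_layers = 4)
  expect_length(l0, 1L)
  expect_equal(l0[[1]]$spans$surface, c("a", "b", "c"))
})

test_that("every produced layer tiles the sentence exactly", {
  set.seed(41)
  gz <- make_gazetteer(gazetteer_spec(seed = 42, terms_per_category = 4))
  bundle <- make_corpus(gz, corpus_spec(n_sentences = 10, seed = 43))
  lex <- train_bpe(bundle$raw, target_size = NULL)
  for (s in bundle$corpus[1:6]) {
    txt <- paste(s$chars, collapse = "")
    for (layer in build_layers(txt, lex)) {
      sp <- layer$spans
      expect_equal(sp$head[1], 0L)
      expect_equal(sp$tail[nrow(sp)], nchar(txt) - 1L)
      if (nrow(sp) > 1)
        expect_equal(sp$head[-1], sp$tail[-nrow(sp)] + 1L)
      expect_equal(paste(sp$surface, collapse = ""), txt)
    }
  }
})

test_that("TF-CR score reproduces hand-computed values and is additive", {
  counts <- matrix(c(4L, 1L), 1, 2,
                   dimnames = list("ab", c("disease", "drug")))
  lex <- lexicon_with_counts(c("a", "b", "ab"),
                             rbind(counts,
                                   matrix(0L, 2, 2,
                                          dimnames = list(c("a", "b"),
                                                          c("disease", "drug")))))
  ## dominant category disease: count 4, total 5; force the TF denominator
  lex$cat_token_total <- c(disease = 20, drug = 10)
  one_span <- data.frame(surface = "ab", head = 0L, tail = 1L)
  expect_equal(tf_cr_score(one_span, lex), (4 / 20) * (4 / 5))   # 0.16
  two_spans <- data.frame(surface = c("ab", "ab"), head = c(0L, 2L),
                          tail = c(1L, 3L))
  expect_equal(tf_cr_score(two_spans, lex), 0.32)
  ## spans with no occurrences contribute zero
  zero_spans <- data.frame(surface = c("a", "b"), head = 0:1, tail = 0:1)
  expect_equal(tf_cr_score(zero_spans, lex), 0)
  ## additivity across concatenated sentences
  expect_equal(tf_cr_score(rbind(one_span, zero_spans), lex),
               tf_cr_score(one_span, lex) + tf_cr_score(zero_spans, lex))
})

test_that("layer selection is the argmax with a fine-granularity tie-break", {
  mk <- function(score, gran) list(spans = data.frame(), score = score,
                                   granularity = gran)
  picked <- select_layer(list(mk(0.1, 4), mk(0.5, 2), mk(0.2, 1)))
  expect_equal(picked$score, 0.5)
  expect_equal(select_layer(list(mk(0.7, 3)))$score, 0.7)
  tie <- select_layer(list(mk(0.3, 4), mk(0.3, 2)))
  expect_equal(tie$granularity, 2L)
  ## softmax shift invariance: adding a constant does not change the pick
  shifted <- select_layer(list(mk(0.1 + 5, 4), mk(0.5 + 5, 2), mk(0.2 + 5, 1)))
  expect_equal(shifted$score - 5, 0.5)
  expect_error(select_layer(list()), "no layers")
})

test_that("flat lattice lists characters first then multi-character spans", {
  lay <- list(spans = data.frame(surface = c("xy", "z"), head = c(0L, 2L),
                                 tail = c(1L, 2L)))
  lat <- build_flat_lattice("xyz", lay)
  expect_equal(nrow(lat$tokens), 4L)
  expect_equal(lat$tokens$surface, c("x", "y", "z", "xy"))
  expect_equal(lat$tokens$head, c(0L, 1L, 2L, 0L))
  expect_equal(lat$tokens$tail, c(0L, 1L, 2L, 1L))
  expect_equal(lat$tokens$is_word, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(lat$n_chars, 3L)

  chars_only <- list(spans = data.frame(surface = c("x", "y", "z"),
                                        head = 0:2, tail = 0:2))
  expect_equal(nrow(build_flat_lattice("xyz", chars_only)$tokens), 3L)

  ## span length d = e - b
  lay6 <- list(spans = data.frame(surface = c("a", "b", "cdef"),
                                  head = c(0L, 1L, 2L), tail = c(0L, 1L, 5L)))
  lat6 <- build_flat_lattice("abcdef", lay6)
  wt <- lat6$tokens[lat6$tokens$is_word, ]
  expect_equal(wt$tail - wt$head, 3L)

  bad <- list(spans = data.frame(surface = "xyzz", head = 0L, tail = 3L))
  expect_error(build_flat_lattice("xyz", bad), "out of range")
})

test_that("lattice serializes to JSON lines", {
  lay <- list(spans = data.frame(surface = c("xy", "z"), head = c(0L, 2L),
                                 tail = c(1L, 2L)))
  lat <- build_flat_lattice("xyz", lay)
  lines <- lattice_to_jsonl(lat)
  expect_length(lines, 4L)
  rec <- jsonlite::fromJSON(lines[4])
  expect_equal(rec$surface, "xy")
  expect_true(rec$is_word)
})
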