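## shared fixtures and independent oracles

## enumerate every tag sequence and its score by direct summation --
## the brute-force oracle for the CRF dynamic programs
enum_paths <- function(n, n_tags) {
  as.matrix(expand.grid(rep(list(seq_len(n_tags)), n)))
}

enum_scores <- function(em, crf) {
  paths <- enum_paths(nrow(em), ncol(em))
  apply(paths, 1L, function(y) sequence_score(em, crf, y))
}

enum_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

random_crf_instance <- function(n, n_tags) {
  em <- matrix(stats::rnorm(n * n_tags), n, n_tags)
  crf <- crf_init(paste0("t", seq_len(n_tags)))
  fin <- is.finite(crf$transition)
  crf$transition[fin] <- stats::rnorm(sum(fin))
  list(em = em, crf = crf)
}

## a lexicon with hand-set category statistics (no corpus needed)
lexicon_with_counts <- function(vocab, counts, cat_token_total = NULL) {
  cats <- colnames(counts)
  lex <- structure(list(vocab = vocab,
                        merges = data.frame(left = character(0),
                                            right = character(0),
                                            rank = integer(0)),
                        alphabet = vocab[nchar(vocab) == 1L],
                        target_size = length(vocab), categories = cats,
                        counts = counts, cat_token_total = colSums(counts)),
                   class = "sl_lexicon")
  if (!is.null(cat_token_total)) lex$cat_token_total <- cat_token_total
  lex
}

## tiny two-category tagged corpus over latin characters
tiny_annotated <- function() {
  list(
    list(chars = c("x", "a", "b", "y"),
         tags = c("O", "B-disease", "I-disease", "O")),
    list(chars = c("a", "b", "z"),
         tags = c("B-disease", "I-disease", "O")),
    list(chars = c("q", "a", "b"),
         tags = c("O", "B-drug", "I-drug")))
}

## small synthetic bundle + fitted model, cached across tests in one run
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gz <- make_gazetteer(gazetteer_spec(seed = 21, terms_per_category = 6,
                                          term_length_range = c(2L, 8L)))
      cache <<- make_corpus(gz, corpus_spec(n_sentences = 40, seed = 22))
    }
    cache
  }
})

desk_config <- function(...) {
  args <- utils::modifyList(
    list(learning_rate = 0.2, d_model = 32L, n_heads = 4L, n_layers = 1L,
         dropout = 0.1, seed = 7L),
    list(...))
  do.call(sl_config, args)
}
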