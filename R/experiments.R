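#' Boundary-information experiment
#'
#' Trains the same small tagger under lexicon-building corpora that retain
#' a proportion (0, 0.5, 1) of the gazetteer terms, and returns strict test
#' F1 per proportion and training run. Only the raw text that byte-pair
#' encoding learns from is ablated; the annotated corpus never changes, so
#' the proportions differ exactly in how much entity-boundary information
#' the induced lexicon can carry into the lattice.
#'
#' The corpus deliberately draws its filler from fragments of the gazetteer
#' terms (`filler_mode = "term_fragments"`): non-entity text is then locally
#' indistinguishable from entity text, as in real clinical records where
#' entity-like character sequences occur outside entities, and boundary
#' information must come from somewhere beyond character identity.
#'
#' @param seed master seed; all corpus, ablation and training seeds derive
#'   from it.
#' @param proportions boundary-information proportions to compare.
#' @param n_runs training runs (seeds) per proportion.
#' @param n_train,n_test training/test sentences.
#' @param epochs training epochs per run.
#' @param quiet suppress progress messages?
#' @return Matrix of strict test F1, proportions x runs, with the
#'   proportion values as rownames.
#' @export
boundary_experiment <- function(seed = 1L, proportions = c(0, 0.5, 1),
                                n_runs = 3L, n_train = 130L, n_test = 150L,
                                epochs = 30L, quiet = TRUE) {
  seed <- as.integer(seed)
  gz <- make_gazetteer(gazetteer_spec(seed = seed, terms_per_category = 15L,
                                      long_term_fraction = 0.4))
  bundle <- make_corpus(gz, corpus_spec(n_sentences = n_train + n_test,
                                        seed = seed + 1L,
                                        filler_mode = "term_fragments"))
  train <- bundle$corpus[seq_len(n_train)]
  test <- bundle$corpus[n_train + seq_len(n_test)]
  n_chars <- length(unique(unlist(strsplit(bundle$raw, ""))))
  res <- matrix(NA_real_, length(proportions), n_runs,
                dimnames = list(format(proportions), paste0("run", seq_len(n_runs))))
  for (pi in seq_along(proportions)) {
    ab <- make_boundary_ablation(bundle, proportions[pi], seed = seed + 2L)
    lex <- train_bpe(ab$raw, target_size = n_chars + 400L)
    lex <- attach_category_stats(lex, train)
    for (r in seq_len(n_runs)) {
      cfg <- sl_config(learning_rate = 0.2, epochs = epochs, d_model = 64L,
                       n_heads = 4L, n_layers = 1L, dropout = 0.1,
                       early_stop_patience = epochs, seed = seed + 10L + r)
      m <- softlattice(train, dev = NULL, lexicon = lex, config = cfg,
                       quiet = TRUE)
      res[pi, r] <- evaluate_strict(test, predict(m, test))$f1
      if (!quiet)
        message(sprintf("proportion %.1f run %d: test F1 %.4f",
                        proportions[pi], r, res[pi, r]))
    }
  }
  res
}
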