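## Seeded synthetic clinical-style corpora. Sentences interleave filler
## character runs with gazetteer terms drawn from six entity categories;
## the construction emulates the statistical structure the tagger assumes
## (multi-character in-vocabulary entity terms, long terms, abbreviations
## and numerals, Zipf-skewed term frequencies) without any real clinical
## vocabulary: character identity is immaterial to the method.

## sample one integer from [a, b] (safe for a == b, unlike sample())
runifi <- function(a, b) if (a >= b) a else sample(a:b, 1L)

default_term_alphabet <- function() intToUtf8(0x4E00 + 0:119, multiple = TRUE)
default_filler_alphabet <- function() intToUtf8(0x5500 + 0:79, multiple = TRUE)

#' Specification of a synthetic gazetteer
#'
#' @param categories entity category names (default [sl_categories()]).
#' @param terms_per_category terms per category.
#' @param term_length_range `(min, max)` characters per term.
#' @param long_term_fraction fraction of terms longer than 6 characters
#'   (long clinical proper nouns).
#' @param abbrev_numeric_fraction fraction of terms carrying injected ASCII
#'   letters/digits (abbreviations and numbers).
#' @param alphabet character pool terms are built from.
#' @param affixes_per_category number of category-specific two-character
#'   suffixes; when positive, every term ends in one of its category's
#'   suffixes, emulating the morphology of clinical terminology (disease
#'   terms ending in "-itis"/"-oma" analogues, and so on). 0 disables.
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @return List of class `sl_gazetteer_spec`.
#' @export
gazetteer_spec <- function(categories = sl_categories(),
                           terms_per_category = 10L,
                           term_length_range = c(2L, 10L),
                           long_term_fraction = 0.3,
                           abbrev_numeric_fraction = 0.2,
                           alphabet = default_term_alphabet(),
                           affixes_per_category = 0L,
                           seed = 1L) {
  stopifnot(length(term_length_range) == 2L,
            term_length_range[1] >= 1L,
            term_length_range[2] >= term_length_range[1],
            long_term_fraction >= 0, long_term_fraction <= 1,
            abbrev_numeric_fraction >= 0, abbrev_numeric_fraction <= 1)
  structure(list(categories = sort(categories),
                 terms_per_category = as.integer(terms_per_category),
                 term_length_range = as.integer(term_length_range),
                 long_term_fraction = long_term_fraction,
                 abbrev_numeric_fraction = abbrev_numeric_fraction,
                 alphabet = alphabet,
                 affixes_per_category = as.integer(affixes_per_category),
                 seed = as.integer(seed)),
            class = "sl_gazetteer_spec")
}

#' Generate a category-tagged gazetteer
#'
#' Terms are unique across categories; the requested fractions of long
#' (> 6 characters) and abbreviation/numeric terms are met within one term
#' per category (rounding); output is deterministic for a fixed spec.
#'
#' @param spec a [gazetteer_spec()].
#' @return Named list mapping category to a character vector of terms.
#' @export
make_gazetteer <- function(spec) {
  stopifnot(inherits(spec, "sl_gazetteer_spec"))
  set.seed(spec$seed)
  lo <- spec$term_length_range[1]; hi <- spec$term_length_range[2]
  npc <- spec$terms_per_category
  n_long <- round(spec$long_term_fraction * npc)
  if (n_long > 0L && hi <= 6L)
    stop("make_gazetteer: long_term_fraction > 0 needs term_length_range ",
         "max > 6", call. = FALSE)
  ascii_pool <- c(LETTERS, as.character(0:9))
  ## optional category-specific suffixes (term morphology)
  affixes <- NULL
  if (spec$affixes_per_category > 0L) {
    n_aff <- spec$affixes_per_category * length(spec$categories)
    repeat {
      pool <- replicate(n_aff, paste(sample(spec$alphabet, 2L, TRUE),
                                     collapse = ""))
      if (anyDuplicated(pool) == 0L) break
    }
    affixes <- split(pool, rep(spec$categories,
                               each = spec$affixes_per_category))
  }
  seen <- character(0)
  out <- list()
  for (cat in spec$categories) {
    terms <- character(0)
    n_abbr <- round(spec$abbrev_numeric_fraction * npc)
    for (k in seq_len(npc)) {
      short_hi <- min(hi, 6L)
      len <- if (k <= n_long || lo > short_hi) runifi(max(7L, lo), hi)
             else runifi(lo, short_hi)
      tries <- 0L
      repeat {
        chars <- sample(spec$alphabet, len, replace = TRUE)
        if (!is.null(affixes) && len >= 3L) {
          suf <- split_chars(affixes[[cat]][runifi(1L, length(affixes[[cat]]))])
          chars[(len - 1L):len] <- suf
        }
        if (k <= n_abbr) {
          ## keep the category suffix intact when morphology is on
          sub_max <- if (is.null(affixes)) len else max(1L, len - 2L)
          n_sub <- min(sub_max, runifi(1L, 2L))
          pos <- sample.int(sub_max, n_sub)
          chars[pos] <- sample(ascii_pool, n_sub, replace = TRUE)
        }
        term <- paste(chars, collapse = "")
        if (!(term %in% seen)) break
        tries <- tries + 1L
        if (tries > 1000L)
          stop("make_gazetteer: alphabet too small for unique terms",
               call. = FALSE)
      }
      seen <- c(seen, term)
      terms <- c(terms, term)
    }
    out[[cat]] <- terms
  }
  out
}

#' Specification of a synthetic corpus
#'
#' @param n_sentences sentences to generate.
#' @param entities_per_sentence `(min, max)` gazetteer terms per sentence.
#' @param filler_length_range `(min, max)` filler characters between terms.
#' @param filler_alphabet character pool for filler runs; disjoint from the
#'   term alphabet by default so filler never spuriously matches a term.
#' @param filler_mode `"alphabet"` (default): filler characters are drawn
#'   independently from `filler_alphabet`; `"term_fragments"`: filler runs
#'   are stitched from short (2-4 character) substrings of gazetteer terms,
#'   so non-entity text is locally indistinguishable from entity text and
#'   boundaries are genuinely ambiguous to a character model.
#' @param zipf_s Zipf exponent for term sampling (skewed term frequencies
#'   keep TF-CR scores non-degenerate).
#' @param sentences_per_record sentences joined per raw record.
#' @param seed RNG seed.
#' @return List of class `sl_corpus_spec`.
#' @export
corpus_spec <- function(n_sentences = 100L,
                        entities_per_sentence = c(1L, 3L),
                        filler_length_range = c(2L, 6L),
                        filler_alphabet = default_filler_alphabet(),
                        filler_mode = c("alphabet", "term_fragments"),
                        zipf_s = 1.2, sentences_per_record = 3L,
                        seed = 1L) {
  filler_mode <- match.arg(filler_mode)
  stopifnot(n_sentences >= 1L, length(entities_per_sentence) == 2L,
            entities_per_sentence[1] >= 0L,
            entities_per_sentence[2] >= entities_per_sentence[1],
            length(filler_length_range) == 2L,
            filler_length_range[1] >= 0L)
  structure(list(n_sentences = as.integer(n_sentences),
                 entities_per_sentence = as.integer(entities_per_sentence),
                 filler_length_range = as.integer(filler_length_range),
                 filler_alphabet = filler_alphabet,
                 filler_mode = filler_mode, zipf_s = zipf_s,
                 sentences_per_record = as.integer(sentences_per_record),
                 seed = as.integer(seed)),
            class = "sl_corpus_spec")
}

#' Generate a synthetic annotated corpus
#'
#' Each sentence interleaves filler runs with gazetteer terms sampled
#' Zipf-like over the term inventory; BIO tags mark exactly the injected
#' terms and the sentence ends with a Chinese full stop (tagged `O`), so
#' raw records — the per-record concatenations — invert exactly under
#' [split_sentences()].
#'
#' @param gazetteer named list from [make_gazetteer()].
#' @param spec a [corpus_spec()].
#' @return List of class `sl_synth`: `raw` (character vector of records),
#'   `corpus` (list of tagged sentences), `manifest` (per-category entity
#'   counts), `gazetteer`, `spec`.
#' @export
make_corpus <- function(gazetteer, spec) {
  stopifnot(inherits(spec, "sl_corpus_spec"), length(gazetteer) > 0L)
  set.seed(spec$seed)
  cats <- rep(names(gazetteer), lengths(gazetteer))
  terms <- unlist(gazetteer, use.names = FALSE)
  ## Zipf-like weights over a seeded random rank assignment
  ranks <- sample(length(terms))
  w <- 1 / ranks^spec$zipf_s
  w <- w / sum(w)
  epsr <- spec$entities_per_sentence
  flr <- spec$filler_length_range
  corpus <- vector("list", spec$n_sentences)
  counts <- stats::setNames(integer(length(gazetteer)), names(gazetteer))
  for (s in seq_len(spec$n_sentences)) {
    k <- runifi(epsr[1], epsr[2])
    pick <- sample.int(length(terms), k, replace = TRUE, prob = w)
    chars <- character(0); tags <- character(0)
    filler <- function() {
      m <- runifi(flr[1], flr[2])
      if (m == 0L) return(character(0))
      if (spec$filler_mode == "alphabet")
        return(sample(spec$filler_alphabet, m, replace = TRUE))
      ## term_fragments: stitch short substrings of gazetteer terms, but
      ## never let a filler run contain a complete term
      out <- character(0)
      while (length(out) < m) {
        tm <- split_chars(terms[sample.int(length(terms), 1L)])
        fl <- runifi(2L, min(4L, length(tm)))
        if (fl >= length(tm)) fl <- length(tm) - 1L
        if (fl < 1L) next
        st <- runifi(1L, length(tm) - fl + 1L)
        out <- c(out, tm[st:(st + fl - 1L)])
      }
      out <- out[seq_len(m)]
      run <- paste(out, collapse = "")
      if (any(vapply(terms, function(t) grepl(t, run, fixed = TRUE), TRUE)))
        return(filler())   # resample the rare full-term collision
      out
    }
    f0 <- filler()
    chars <- f0; tags <- rep("O", length(f0))
    for (p in pick) {
      tc <- split_chars(terms[p])
      chars <- c(chars, tc)
      tags <- c(tags, paste0("B-", cats[p]),
                rep(paste0("I-", cats[p]), length(tc) - 1L))
      counts[cats[p]] <- counts[cats[p]] + 1L
      fx <- filler()
      chars <- c(chars, fx); tags <- c(tags, rep("O", length(fx)))
    }
    chars <- c(chars, "。")   # sentence-final full stop
    tags <- c(tags, "O")
    corpus[[s]] <- list(chars = chars, tags = tags)
  }
  spr <- spec$sentences_per_record
  rec_id <- ceiling(seq_len(spec$n_sentences) / spr)
  raw <- vapply(split(corpus, rec_id), function(sents)
    paste(vapply(sents, function(s) paste(s$chars, collapse = ""), ""),
          collapse = ""), "")
  names(raw) <- NULL
  structure(list(raw = raw, corpus = corpus,
                 manifest = list(per_category = as.list(counts),
                                 total = sum(counts)),
                 gazetteer = gazetteer, spec = spec),
            class = "sl_synth")
}

#' @export
print.sl_synth <- function(x, ...) {
  cat("synthetic corpus: ", length(x$corpus), " sentences, ",
      x$manifest$total, " entities over ", length(x$gazetteer),
      " categories\n", sep = "")
  print(unlist(x$manifest$per_category))
  invisible(x)
}

#' Boundary-information ablation of a synthetic corpus bundle
#'
#' Retains a seeded random `proportion` of the distinct gazetteer terms and
#' deletes every occurrence of the remaining terms from the raw
#' (lexicon-building) records, so the induced lexicon's word coverage of
#' gold entity boundaries scales with `proportion`. The annotated corpus is
#' left untouched — only the boundary information available to lexicon
#' induction changes.
#'
#' @param bundle an `sl_synth` from [make_corpus()].
#' @param proportion fraction of entity terms retained, in `[0, 1]`.
#' @param seed RNG seed for the retained-term selection.
#' @return The bundle with `raw` filtered and a `retained_terms` field.
#' @export
make_boundary_ablation <- function(bundle, proportion, seed = 1L) {
  stopifnot(inherits(bundle, "sl_synth"), proportion >= 0, proportion <= 1)
  terms <- unlist(bundle$gazetteer, use.names = FALSE)
  if (proportion >= 1) {
    bundle$retained_terms <- terms
    return(bundle)
  }
  set.seed(as.integer(seed))
  n_keep <- round(proportion * length(terms))
  keep <- if (n_keep > 0L) sample(terms, n_keep) else character(0)
  drop <- setdiff(terms, keep)
  raw <- bundle$raw
  for (tm in drop) raw <- gsub(tm, "", raw, fixed = TRUE)
  bundle$raw <- raw
  bundle$retained_terms <- keep
  bundle
}

#' Write a synthetic bundle to disk
#'
#' Emits `raw.txt`, `train.conll`, `dev.conll`, `test.conll`,
#' `gazetteer.tsv` and `manifest.json` — the file layout consumed by the
#' CLI. The corpus is split 80/10/10 in generation order.
#'
#' @param bundle an `sl_synth`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synth <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sl_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "raw.txt"), open = "w", encoding = "UTF-8")
  writeLines(bundle$raw, con); close(con)
  n <- length(bundle$corpus)
  n_tr <- max(1L, floor(0.8 * n)); n_dev <- max(1L, floor(0.1 * n))
  idx_tr <- seq_len(n_tr)
  idx_dev <- seq(n_tr + 1L, min(n, n_tr + n_dev))
  idx_te <- if (n_tr + n_dev < n) seq(n_tr + n_dev + 1L, n) else idx_dev
  write_conll(bundle$corpus[idx_tr], file.path(dir, "train.conll"))
  write_conll(bundle$corpus[idx_dev], file.path(dir, "dev.conll"))
  write_conll(bundle$corpus[idx_te], file.path(dir, "test.conll"))
  gz <- data.frame(category = rep(names(bundle$gazetteer),
                                  lengths(bundle$gazetteer)),
                   term = unlist(bundle$gazetteer, use.names = FALSE))
  con <- file(file.path(dir, "gazetteer.tsv"), open = "w", encoding = "UTF-8")
  writeLines(paste(gz$category, gz$term, sep = "\t"), con); close(con)
  writeLines(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
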