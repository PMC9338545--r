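#' Default clinical entity categories
#'
#' The six clinical entity categories used throughout the package: disease,
#' image_review, test, treatment, drug and anatomy. BIO tagging over these
#' yields 13 tags (`B-`/`I-` per category plus `O`).
#'
#' @return Character vector of category names, sorted.
#' @export
sl_categories <- function() {
  sort(c("disease", "image_review", "test", "treatment", "drug", "anatomy"))
}

#' BIO tag set for a category inventory
#'
#' @param categories character vector of entity category names.
#' @return Character vector of tags: `O` first, then `B-`/`I-` pairs in
#'   category order.
#' @export
bio_tags <- function(categories = sl_categories()) {
  c("O", as.vector(rbind(paste0("B-", categories), paste0("I-", categories))))
}

split_chars <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "", fixed = FALSE)[[1]]
}

## Merge one (left,right) symbol pair, left to right, non-overlapping.
merge_pair_once <- function(toks, left, right) {
  n <- length(toks)
  if (n < 2L) return(toks)
  hit <- which(toks[-n] == left & toks[-1L] == right)
  if (length(hit) == 0L) return(toks)
  ## drop overlapping hits (e.g. "aaa" with pair (a,a)): keep greedy leftmost
  keep <- logical(length(hit))
  last <- -1L
  for (k in seq_along(hit)) {
    if (hit[k] > last + 1L) { keep[k] <- TRUE; last <- hit[k] }
  }
  hit <- hit[keep]
  toks[hit] <- paste0(left, right)
  toks[-(hit + 1L)]
}

#' Induce a subword lexicon by byte-pair encoding
#'
#' Starting from single characters, iteratively merges the most frequent
#' adjacent symbol pair in the corpus into a new subword until the vocabulary
#' reaches `target_size` or no pair occurs at least `min_pair_freq` times.
#' Pair-frequency ties are broken by lexicographic (C-locale) order of
#' (left, right), so induction is deterministic for a fixed corpus.
#'
#' @param corpus character vector of sentences/records (UTF-8).
#' @param target_size desired vocabulary size (single characters plus merged
#'   subwords). Default: alphabet size + 3000.
#' @param min_pair_freq minimum pair frequency for a merge (default 2).
#' @param categories entity category inventory the lexicon will be used with.
#' @return An object of class `sl_lexicon` with fields `vocab`, `merges`
#'   (data.frame left/right/rank), `alphabet`, `target_size`, `categories`,
#'   and (after [attach_category_stats()]) `counts` and `cat_token_total`.
#' @examples
#' lex <- train_bpe(c("aaab", "aaab"), target_size = 4)
#' lex$merges
#' bpe_tokenize("aaab", lex)
#' @export
train_bpe <- function(corpus, target_size = NULL, min_pair_freq = 2L,
                      categories = sl_categories()) {
  corpus <- corpus[!is.na(corpus)]
  if (length(corpus) == 0L || all(!nzchar(corpus)))
    stop("train_bpe: corpus is empty", call. = FALSE)
  seqs <- lapply(corpus, split_chars)
  seqs <- seqs[lengths(seqs) > 0L]
  alphabet <- sort(unique(unlist(seqs)), method = "radix")
  if (is.null(target_size)) target_size <- length(alphabet) + 3000L
  target_size <- as.integer(target_size)
  if (target_size < length(alphabet))
    stop("train_bpe: target_size (", target_size, ") is smaller than the ",
         "alphabet (", length(alphabet), " characters)", call. = FALSE)

  vocab <- alphabet
  merges <- list()
  sep <- "\u0001"
  while (length(vocab) < target_size) {
    lefts <- unlist(lapply(seqs, function(s) if (length(s) > 1L) s[-length(s)] else character(0)))
    if (length(lefts) == 0L) break
    rights <- unlist(lapply(seqs, function(s) if (length(s) > 1L) s[-1L] else character(0)))
    key <- paste0(lefts, sep, rights)
    tab <- table(key)
    best_freq <- max(tab)
    if (best_freq < min_pair_freq) break
    cand <- names(tab)[tab == best_freq]
    parts <- strsplit(cand, sep, fixed = TRUE)
    cl <- vapply(parts, `[`, "", 1L)
    cr <- vapply(parts, `[`, "", 2L)
    o <- order(cl, cr, method = "radix")[1L]
    left <- cl[o]; right <- cr[o]
    merges[[length(merges) + 1L]] <- c(left, right)
    seqs <- lapply(seqs, merge_pair_once, left = left, right = right)
    sym <- paste0(left, right)
    if (!(sym %in% vocab)) vocab <- c(vocab, sym)
  }

  merges_df <- if (length(merges)) {
    m <- do.call(rbind, merges)
    data.frame(left = m[, 1L], right = m[, 2L],
               rank = seq_len(nrow(m)) - 1L, stringsAsFactors = FALSE)
  } else {
    data.frame(left = character(0), right = character(0), rank = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(list(vocab = vocab, merges = merges_df, alphabet = alphabet,
                 target_size = target_size, categories = sort(categories),
                 counts = NULL, cat_token_total = NULL),
            class = "sl_lexicon")
}

#' Segment a sentence into subwords with a trained lexicon
#'
#' Applies the lexicon's merge rules in rank order to the character split of
#' `sentence`. Concatenating the result always reproduces the input exactly;
#' characters never seen in training pass through as single-character
#' subwords.
#'
#' @param sentence a single string.
#' @param lexicon an [train_bpe()] lexicon.
#' @return Character vector of subwords (empty for the empty string).
#' @export
bpe_tokenize <- function(sentence, lexicon) {
  stopifnot(inherits(lexicon, "sl_lexicon"))
  toks <- split_chars(sentence)
  if (length(toks) < 2L || nrow(lexicon$merges) == 0L) return(toks)
  m <- lexicon$merges
  joined <- paste0(m$left, m$right)
  for (r in seq_len(nrow(m))) {
    ## cheap necessary-condition filter before the symbol-level merge
    if (!grepl(joined[r], sentence, fixed = TRUE)) next
    toks <- merge_pair_once(toks, m$left[r], m$right[r])
    if (length(toks) < 2L) break
  }
  toks
}

parse_tag <- function(tag) {
  ## returns list(kind, category) or NULL for malformed
  if (identical(tag, "O")) return(list(kind = "O", category = NA_character_))
  if (grepl("^[BI]-.+$", tag))
    return(list(kind = substr(tag, 1L, 1L), category = substring(tag, 3L)))
  NULL
}

validate_tags <- function(tags, categories, where = "sentence") {
  ok <- tags == "O" | tags %in% paste0("B-", categories) |
    tags %in% paste0("I-", categories)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("unknown tag '", tags[bad], "' at position ", bad, " of ", where,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Attach per-category subword occurrence statistics to a lexicon
#'
#' Tokenizes each annotated sentence with the lexicon and counts, for every
#' subword occurrence whose character span lies entirely inside a single gold
#' entity of category c, one occurrence of that subword in category c. Also
#' records, per category, the total number of subword tokens inside that
#' category's entities (the TF denominator of the TF-CR score).
#'
#' @param lexicon an `sl_lexicon`.
#' @param annotated list of tagged sentences; each element is a list with
#'   `chars` (character vector) and `tags` (BIO tag vector of equal length).
#' @return The lexicon with `counts` (subword x category matrix) and
#'   `cat_token_total` (named vector) filled in.
#' @export
attach_category_stats <- function(lexicon, annotated) {
  stopifnot(inherits(lexicon, "sl_lexicon"))
  cats <- lexicon$categories
  rows <- lexicon$vocab
  counts <- matrix(0L, nrow = length(rows), ncol = length(cats),
                   dimnames = list(rows, cats))
  extra <- list()  # subwords outside vocab (unseen characters)
  for (si in seq_along(annotated)) {
    ts <- annotated[[si]]
    chars <- ts$chars; tags <- ts$tags
    if (length(chars) != length(tags))
      stop("attach_category_stats: chars/tags length mismatch in sentence ", si,
           call. = FALSE)
    if (length(chars) == 0L) next
    validate_tags(tags, cats, where = paste0("sentence ", si))
    ents <- tags_to_entities(tags, warn = FALSE)
    if (nrow(ents) == 0L) next
    toks <- bpe_tokenize(paste(chars, collapse = ""), lexicon)
    len <- nchar(toks)
    tail0 <- cumsum(len) - 1L          # 0-based inclusive
    head0 <- tail0 - len + 1L
    for (k in seq_along(toks)) {
      hit <- which(ents$head <= head0[k] & ents$tail >= tail0[k])
      if (length(hit) != 1L) next
      cat <- ents$category[hit]
      sw <- toks[k]
      if (sw %in% rows) {
        counts[sw, cat] <- counts[sw, cat] + 1L
      } else {
        key <- paste0(sw, "\u0001", cat)
        extra[[key]] <- (if (is.null(extra[[key]])) 0L else extra[[key]]) + 1L
      }
    }
  }
  if (length(extra)) {
    parts <- strsplit(names(extra), "\u0001", fixed = TRUE)
    esw <- vapply(parts, `[`, "", 1L)
    ecat <- vapply(parts, `[`, "", 2L)
    for (sw in unique(esw)) {
      row <- matrix(0L, 1L, length(cats), dimnames = list(sw, cats))
      sel <- esw == sw
      row[1L, ecat[sel]] <- as.integer(unlist(extra[sel]))
      counts <- rbind(counts, row)
    }
  }
  lexicon$counts <- counts
  lexicon$cat_token_total <- colSums(counts)
  lexicon
}

#' @export
print.sl_lexicon <- function(x, ...) {
  cat("BPE lexicon: ", length(x$vocab), " subwords (",
      length(x$alphabet), " characters + ", nrow(x$merges), " merges; target ",
      x$target_size, ")\n", sep = "")
  if (!is.null(x$counts)) {
    cat("category stats attached; in-entity subword tokens per category:\n")
    print(x$cat_token_total)
  } else {
    cat("no category stats attached (see attach_category_stats)\n")
  }
  invisible(x)
}

#' Write / read a lexicon as plain text
#'
#' `write_lexicon()` stores the vocabulary with its category statistics as a
#' UTF-8 TSV (`lexicon.tsv`: subword, total count, then `category:count`
#' pairs) and the ordered merge rules as a two-column `merges.txt`
#' (the usual BPE convention). `read_lexicon()` restores the object.
#'
#' @param lexicon an `sl_lexicon`.
#' @param dir directory to write into (created if missing).
#' @return `write_lexicon()` returns `dir` invisibly; `read_lexicon()` an
#'   `sl_lexicon`.
#' @export
write_lexicon <- function(lexicon, dir) {
  stopifnot(inherits(lexicon, "sl_lexicon"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- file(file.path(dir, "merges.txt"), open = "w", encoding = "UTF-8")
  writeLines(paste(lexicon$merges$left, lexicon$merges$right), mf)
  close(mf)
  counts <- lexicon$counts
  if (is.null(counts))
    counts <- matrix(0L, length(lexicon$vocab), length(lexicon$categories),
                     dimnames = list(lexicon$vocab, lexicon$categories))
  vocab_all <- rownames(counts)
  tot <- rowSums(counts)
  pairs <- apply(counts, 1L, function(r)
    paste(paste0(colnames(counts), ":", r), collapse = "\t"))
  lf <- file(file.path(dir, "lexicon.tsv"), open = "w", encoding = "UTF-8")
  writeLines(c(paste0("#target_size\t", lexicon$target_size),
               paste0("#alphabet\t", paste(lexicon$alphabet, collapse = "")),
               paste(vocab_all, tot, pairs, sep = "\t")), lf)
  close(lf)
  invisible(dir)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(dir) {
  lex_lines <- readLines(file.path(dir, "lexicon.tsv"), encoding = "UTF-8")
  merge_lines <- readLines(file.path(dir, "merges.txt"), encoding = "UTF-8")
  meta <- lex_lines[startsWith(lex_lines, "#")]
  body <- lex_lines[!startsWith(lex_lines, "#") & nzchar(lex_lines)]
  target_size <- as.integer(sub("^#target_size\t", "", meta[1L]))
  alphabet <- split_chars(sub("^#alphabet\t", "", meta[2L]))
  fields <- strsplit(body, "\t", fixed = TRUE)
  sw <- vapply(fields, `[`, "", 1L)
  catfields <- lapply(fields, function(f) f[-c(1L, 2L)])
  cat_names <- sub(":.*$", "", catfields[[1L]])
  counts <- t(vapply(catfields, function(f) as.integer(sub("^.*:", "", f)),
                     integer(length(cat_names))))
  dimnames(counts) <- list(sw, cat_names)
  merges <- if (length(merge_lines) && any(nzchar(merge_lines))) {
    ml <- strsplit(merge_lines[nzchar(merge_lines)], " ", fixed = TRUE)
    data.frame(left = vapply(ml, `[`, "", 1L),
               right = vapply(ml, `[`, "", 2L),
               rank = seq_along(ml) - 1L, stringsAsFactors = FALSE)
  } else {
    data.frame(left = character(0), right = character(0), rank = integer(0),
               stringsAsFactors = FALSE)
  }
  vocab <- c(alphabet, setdiff(paste0(merges$left, merges$right), alphabet))
  lex <- structure(list(vocab = vocab, merges = merges, alphabet = alphabet,
                        target_size = target_size, categories = cat_names,
                        counts = NULL, cat_token_total = NULL),
                   class = "sl_lexicon")
  if (any(counts != 0L)) {
    lex$counts <- counts
    lex$cat_token_total <- colSums(counts)
  }
  lex
}
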