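#' Build multi-granularity segmentation layers of a sentence
#'
#' Layer g (g = 1..`max_layers`) is the greedy longest-match tiling of the
#' sentence using lexicon subwords of length at most `ceiling(n/g)`, with a
#' single-character fallback wherever no subword matches. Coarse layers thus
#' admit whole-sentence spans while fine layers approach the character
#' tiling. Identical tilings are deduplicated (first occurrence kept).
#'
#' @param sentence a single non-empty string.
#' @param lexicon an `sl_lexicon` (stats optional; layer scores are 0 when
#'   stats are absent).
#' @param max_layers number of granularity levels to construct (default 4).
#' @return List of segmentation layers; each is a list with `spans`
#'   (data.frame surface/head/tail, 0-based inclusive indices),
#'   `granularity` (longest span length in the layer) and `score`
#'   (the layer's TF-CR score).
#' @export
build_layers <- function(sentence, lexicon, max_layers = 4L) {
  stopifnot(inherits(lexicon, "sl_lexicon"))
  chars <- split_chars(sentence)
  n <- length(chars)
  if (n == 0L) stop("build_layers: empty sentence", call. = FALSE)
  multi <- lexicon$vocab[nchar(lexicon$vocab) > 1L]
  max_len <- if (length(multi)) max(nchar(multi)) else 1L
  layers <- list()
  seen <- character(0)
  for (g in seq_len(max_layers)) {
    cap <- ceiling(n / g)
    spans <- greedy_tile(chars, multi, min(cap, max_len))
    key <- paste(spans$head, spans$tail, collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    layers[[length(layers) + 1L]] <- list(
      spans = spans,
      granularity = max(spans$tail - spans$head + 1L),
      score = if (is.null(lexicon$counts)) 0 else tf_cr_score_spans(spans, lexicon))
  }
  layers
}

## greedy longest-match tiling with single-character fallback; cap on length
greedy_tile <- function(chars, multi_vocab, cap) {
  n <- length(chars)
  surface <- character(0); head <- integer(0); tail <- integer(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    if (cap >= 2L && length(multi_vocab)) {
      for (len in seq(from = min(cap, n - i + 1L), to = 2L)) {
        if (len < 2L) break
        cand <- paste(chars[i:(i + len - 1L)], collapse = "")
        if (cand %in% multi_vocab) {
          surface <- c(surface, cand)
          head <- c(head, i - 1L); tail <- c(tail, i + len - 2L)
          i <- i + len
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) {
      surface <- c(surface, chars[i])
      head <- c(head, i - 1L); tail <- c(tail, i - 1L)
      i <- i + 1L
    }
  }
  data.frame(surface = surface, head = head, tail = tail,
             stringsAsFactors = FALSE)
}

tf_cr_score_spans <- function(spans, lexicon) {
  counts <- lexicon$counts
  ctt <- lexicon$cat_token_total
  total <- 0
  idx <- match(spans$surface, rownames(counts))
  for (k in seq_along(idx)) {
    if (is.na(idx[k])) next
    row <- counts[idx[k], ]
    tot <- sum(row)
    if (tot == 0) next
    c_star <- which.max(row)  # ties: first (lexicographically first category)
    cnt <- row[c_star]
    denom <- ctt[c_star]
    if (denom == 0) next
    total <- total + (cnt / denom) * (cnt / tot)
  }
  unname(total)
}

#' TF-CR score of a segmentation layer
#'
#' Sums, over the spans of a layer, term frequency times category ratio for
#' the span's dominant category c* (the category with the largest per-span
#' occurrence count; ties go to the lexicographically first category):
#' TF = count(span, c*) / total subword tokens inside c* entities, and
#' CR = count(span, c*) / total occurrences of the span across categories.
#' Spans never observed inside an entity contribute 0.
#'
#' @param layer a segmentation layer from [build_layers()], or a data.frame
#'   of spans with a `surface` column.
#' @param lexicon an `sl_lexicon` with category statistics attached.
#' @return The layer score (non-negative real).
#' @export
tf_cr_score <- function(layer, lexicon) {
  stopifnot(inherits(lexicon, "sl_lexicon"))
  if (is.null(lexicon$counts))
    stop("tf_cr_score: lexicon has no category statistics; ",
         "run attach_category_stats() first", call. = FALSE)
  spans <- if (is.data.frame(layer)) layer else layer$spans
  tf_cr_score_spans(spans, lexicon)
}

#' Select the segmentation layer with the largest TF-CR score
#'
#' Softmax over layer scores preserves the argmax, so selection reduces to
#' the layer with maximal raw score; ties are broken in favour of the
#' smallest granularity (finest segmentation).
#'
#' @param layers non-empty list of layers from [build_layers()].
#' @return The selected layer, with a `prob` field giving its softmax
#'   probability among the candidates.
#' @export
select_layer <- function(layers) {
  if (length(layers) == 0L)
    stop("select_layer: no layers supplied", call. = FALSE)
  scores <- vapply(layers, function(l) as.numeric(l$score), 0)
  gran <- vapply(layers, function(l) as.integer(l$granularity), 0L)
  p <- exp(scores - max(scores))
  p <- p / sum(p)
  best <- which(scores == max(scores))
  pick <- best[which.min(gran[best])]
  out <- layers[[pick]]
  out$prob <- p[pick]
  out
}

#' Flatten a selected segmentation into a word-character lattice
#'
#' The flat lattice lists every character of the sentence first (token k has
#' head = tail = k - 1) followed by the multi-character spans of the selected
#' layer, each carrying its (head, tail) character indices. Single-character
#' spans of the layer are not duplicated. Span length is tail - head.
#'
#' @param sentence the sentence string the layer tiles.
#' @param selected a segmentation layer whose spans tile the sentence.
#' @return An object of class `sl_lattice`: list with `tokens` (data.frame
#'   surface/head/tail/is_word) and `n_chars`.
#' @export
build_flat_lattice <- function(sentence, selected) {
  chars <- split_chars(sentence)
  n <- length(chars)
  spans <- if (is.data.frame(selected)) selected else selected$spans
  if (nrow(spans)) {
    if (min(spans$head) < 0L || max(spans$tail) > n - 1L)
      stop("build_flat_lattice: span indices out of range for a ", n,
           "-character sentence", call. = FALSE)
    widths <- spans$tail - spans$head + 1L
    if (sum(widths) != n || any(spans$head[-1L] != spans$tail[-nrow(spans)] + 1L) ||
        spans$head[1L] != 0L)
      stop("build_flat_lattice: spans do not tile the sentence", call. = FALSE)
  }
  words <- spans[spans$tail > spans$head, , drop = FALSE]
  tokens <- data.frame(
    surface = c(chars, words$surface),
    head = c(seq_len(n) - 1L, words$head),
    tail = c(seq_len(n) - 1L, words$tail),
    is_word = c(rep(FALSE, n), rep(TRUE, nrow(words))),
    stringsAsFactors = FALSE)
  structure(list(tokens = tokens, n_chars = n), class = "sl_lattice")
}

#' @export
print.sl_lattice <- function(x, ...) {
  cat("flat lattice: ", x$n_chars, " characters + ",
      sum(x$tokens$is_word), " word spans\n", sep = "")
  print(x$tokens)
  invisible(x)
}

#' Serialize a flat lattice to JSON lines
#'
#' One JSON object per token: `{"surface": ..., "head": ..., "tail": ...,
#' "is_word": ...}` — the format dumped by the CLI `lattice` subcommand.
#'
#' @param lattice an `sl_lattice`.
#' @param path optional file to write to; if `NULL` the lines are returned.
#' @return Character vector of JSON lines (invisibly when `path` is given).
#' @export
lattice_to_jsonl <- function(lattice, path = NULL) {
  stopifnot(inherits(lattice, "sl_lattice"))
  lines <- vapply(seq_len(nrow(lattice$tokens)), function(i) {
    row <- lattice$tokens[i, ]
    jsonlite::toJSON(list(surface = row$surface, head = row$head,
                          tail = row$tail, is_word = row$is_word),
                     auto_unbox = TRUE)
  }, "")
  if (!is.null(path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    writeLines(lines, con)
    close(con)
    return(invisible(lines))
  }
  lines
}

#' Build the lattice for one sentence end to end
#'
#' Convenience wrapper: [build_layers()], [select_layer()],
#' [build_flat_lattice()]. With `use_words = FALSE` the lattice contains
#' characters only (the character-baseline ablation).
#'
#' @inheritParams build_layers
#' @param use_words include word spans from the selected layer?
#' @return An `sl_lattice`.
#' @export
sentence_lattice <- function(sentence, lexicon, max_layers = 4L,
                             use_words = TRUE) {
  if (!use_words) {
    chars <- split_chars(sentence)
    sel <- list(spans = data.frame(surface = chars,
                                   head = seq_along(chars) - 1L,
                                   tail = seq_along(chars) - 1L,
                                   stringsAsFactors = FALSE),
                granularity = 1L, score = 0)
    return(build_flat_lattice(sentence, sel))
  }
  layers <- build_layers(sentence, lexicon, max_layers = max_layers)
  build_flat_lattice(sentence, select_layer(layers))
}
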