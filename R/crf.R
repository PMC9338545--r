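## Linear-chain CRF with explicit START/END states, exact inference.
## Emission matrix: n_positions x n_tags. Transition matrix:
## (n_tags + 2) x (n_tags + 2), entry [a, b] scoring the step a -> b;
## START occupies row/column n_tags + 1, END n_tags + 2. Transitions into
## START and out of END are -Inf and never updated.

#' Initialise CRF parameters
#'
#' @param tags character vector of tag names (e.g. [bio_tags()]).
#' @param bio_mask if `TRUE`, transitions that are illegal under the BIO
#'   scheme (`O -> I-X`, `B-X -> I-Y`, `I-X -> I-Y`, `START -> I-X`) are set
#'   to `-Inf` instead of being learned.
#' @return An object of class `sl_crf`: list with `transition` (matrix),
#'   `tags`, and the `start`/`end` state indices.
#' @export
crf_init <- function(tags, bio_mask = FALSE) {
  n <- length(tags)
  states <- c(tags, "<START>", "<END>")
  A <- matrix(0, n + 2L, n + 2L, dimnames = list(states, states))
  A[, n + 1L] <- -Inf   # into START
  A[n + 2L, ] <- -Inf   # out of END
  A[n + 1L, n + 2L] <- -Inf  # empty sequence is impossible
  if (bio_mask) {
    kind <- substr(tags, 1L, 1L)
    cat <- ifelse(kind == "O", NA, substring(tags, 3L))
    for (j in which(kind == "I")) {
      ok_prev <- which((kind %in% c("B", "I")) & cat == cat[j])
      bad_prev <- setdiff(seq_len(n), ok_prev)
      A[bad_prev, j] <- -Inf
      A[n + 1L, j] <- -Inf
    }
  }
  structure(list(transition = A, tags = tags,
                 start = n + 1L, end = n + 2L),
            class = "sl_crf")
}

tag_indices <- function(y, crf) {
  if (is.character(y)) {
    idx <- match(y, crf$tags)
    if (anyNA(idx))
      stop("unknown tag '", y[which(is.na(idx))[1L]], "'", call. = FALSE)
    idx
  } else as.integer(y)
}

#' Score of one tag sequence
#'
#' Sum of per-position emission scores plus the boundary-inclusive chain of
#' transition scores START -> y_1 -> ... -> y_n -> END.
#'
#' @param em emission matrix, positions x tags.
#' @param crf an [crf_init()] object.
#' @param y tag sequence (tag names or integer indices), length `nrow(em)`.
#' @return The unnormalized sequence score.
#' @export
sequence_score <- function(em, crf, y) {
  y <- tag_indices(y, crf)
  n <- nrow(em)
  stopifnot(length(y) == n)
  A <- crf$transition
  s <- sum(em[cbind(seq_len(n), y)]) + A[crf$start, y[1L]] + A[y[n], crf$end]
  if (n > 1L) s <- s + sum(A[cbind(y[-n], y[-1L])])
  s
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## column-wise log-sum-exp of (a + A): result_j = logsumexp_k(a_k + A[k, j])
lse_step <- function(a, A) {
  M <- a + A
  cmax <- apply(M, 2L, max)
  out <- cmax + log(colSums(exp(sweep(M, 2L, cmax, check.margin = FALSE))))
  out[!is.finite(cmax)] <- -Inf
  out
}

crf_forward <- function(em, crf) {
  n <- nrow(em); Tn <- ncol(em)
  A <- crf$transition
  core <- A[seq_len(Tn), seq_len(Tn), drop = FALSE]
  alpha <- matrix(-Inf, n, Tn)
  alpha[1L, ] <- A[crf$start, seq_len(Tn)] + em[1L, ]
  if (n > 1L) for (i in 2L:n)
    alpha[i, ] <- lse_step(alpha[i - 1L, ], core) + em[i, ]
  alpha
}

crf_backward <- function(em, crf) {
  n <- nrow(em); Tn <- ncol(em)
  A <- crf$transition
  core <- A[seq_len(Tn), seq_len(Tn), drop = FALSE]
  beta <- matrix(-Inf, n, Tn)
  beta[n, ] <- A[seq_len(Tn), crf$end]
  if (n > 1L) for (i in (n - 1L):1L)
    beta[i, ] <- lse_step(beta[i + 1L, ] + em[i + 1L, ], t(core))
  beta
}

#' Log partition function of the CRF
#'
#' The log of the sum of `exp(score)` over all possible tag sequences,
#' computed by the forward recursion in log space (log-sum-exp; exact and
#' numerically stable).
#'
#' @inheritParams sequence_score
#' @return `log Z` as a single real.
#' @export
log_partition <- function(em, crf) {
  alpha <- crf_forward(em, crf)
  log_sum_exp(alpha[nrow(em), ] + crf$transition[seq_len(ncol(em)), crf$end])
}

#' Viterbi decoding
#'
#' Returns the tag sequence maximizing the CRF sequence score, by dynamic
#' programming over the (tags + START/END) chain. Score ties are resolved
#' toward the smallest tag index (first maximum at every backtracking step).
#'
#' @inheritParams sequence_score
#' @return List with `tags` (character), `indices` (integer) and `score`.
#' @export
viterbi_decode <- function(em, crf) {
  n <- nrow(em); Tn <- ncol(em)
  A <- crf$transition
  core <- A[seq_len(Tn), seq_len(Tn), drop = FALSE]
  delta <- matrix(-Inf, n, Tn)
  bp <- matrix(0L, n, Tn)
  delta[1L, ] <- A[crf$start, seq_len(Tn)] + em[1L, ]
  if (n > 1L) for (i in 2L:n) {
    M <- delta[i - 1L, ] + core     # M[k, j] = delta_k + A[k, j]
    bp[i, ] <- apply(M, 2L, which.max)
    delta[i, ] <- M[cbind(bp[i, ], seq_len(Tn))] + em[i, ]
  }
  fin <- delta[n, ] + A[seq_len(Tn), crf$end]
  path <- integer(n)
  path[n] <- which.max(fin)
  if (n > 1L) for (i in n:2L) path[i - 1L] <- bp[i, path[i]]
  list(tags = crf$tags[path], indices = path, score = max(fin))
}

#' Negative log-likelihood of a gold tag sequence
#'
#' `log_partition(em, crf) - sequence_score(em, crf, gold)`; non-negative,
#' and zero only when the gold path carries all probability mass.
#'
#' @inheritParams sequence_score
#' @param gold gold tag sequence.
#' @return The NLL as a single real.
#' @export
nll_loss <- function(em, crf, gold) {
  log_partition(em, crf) - sequence_score(em, crf, gold)
}

## Gradients of the NLL w.r.t. emissions and transitions (expected counts
## minus gold counts), via forward-backward. Returns d_em (n x T) and
## d_trans ((T+2) x (T+2); -Inf entries get zero gradient).
crf_gradients <- function(em, crf, gold) {
  gold <- tag_indices(gold, crf)
  n <- nrow(em); Tn <- ncol(em)
  A <- crf$transition
  core <- A[seq_len(Tn), seq_len(Tn), drop = FALSE]
  alpha <- crf_forward(em, crf)
  beta <- crf_backward(em, crf)
  logZ <- log_sum_exp(alpha[n, ] + A[seq_len(Tn), crf$end])

  marg <- exp(alpha + beta - logZ)            # position marginals
  d_em <- marg
  d_em[cbind(seq_len(n), gold)] <- d_em[cbind(seq_len(n), gold)] - 1

  d_trans <- matrix(0, Tn + 2L, Tn + 2L)
  ## interior pairwise marginals
  if (n > 1L) {
    dcore <- matrix(0, Tn, Tn)
    for (i in seq_len(n - 1L)) {
      lp <- outer(alpha[i, ], beta[i + 1L, ] + em[i + 1L, ], "+") + core - logZ
      dcore <- dcore + exp(lp)
    }
    gold_pairs <- table(factor(gold[-n], levels = seq_len(Tn)),
                        factor(gold[-1L], levels = seq_len(Tn)))
    d_trans[seq_len(Tn), seq_len(Tn)] <- dcore - as.numeric(gold_pairs)
  }
  ## boundary transitions
  m1 <- exp(alpha[1L, ] + beta[1L, ] - logZ)
  d_trans[crf$start, seq_len(Tn)] <- m1
  d_trans[crf$start, gold[1L]] <- d_trans[crf$start, gold[1L]] - 1
  mn <- exp(alpha[n, ] + beta[n, ] - logZ)
  d_trans[seq_len(Tn), crf$end] <- mn
  d_trans[gold[n], crf$end] <- d_trans[gold[n], crf$end] - 1
  d_trans[!is.finite(A)] <- 0
  list(d_em = d_em, d_trans = d_trans, logZ = logZ)
}
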