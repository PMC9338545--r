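## Lattice encoder: stacked relative-position multi-head self-attention over
## the flat word-character lattice, with add & layer-norm and a position-wise
## feed-forward block per layer, emitting per-character tag scores.
## Forward and analytic backward passes are implemented in base R matrix
## algebra; gradients are checked against finite differences in the tests.

#' Sinusoidal encoding of a (possibly negative) distance
#'
#' Component 2k (0-based) is `sin(d / 10000^(2k/d_model))` and component
#' 2k+1 is `cos(d / 10000^(2k/d_model))`, k = 0..d_model/2 - 1.
#'
#' @param d integer distance (scalar).
#' @param d_model even embedding dimension.
#' @return Numeric vector of length `d_model`.
#' @export
sinusoid_encode <- function(d, d_model) {
  stopifnot(length(d) == 1L, d_model %% 2L == 0L)
  drop(sinusoid_matrix(d, d_model))
}

## vectorized: one row per distance
sinusoid_matrix <- function(ds, d_model) {
  k <- seq_len(d_model %/% 2L) - 1L
  freq <- 10000^(2 * k / d_model)
  ang <- outer(ds, 1 / freq)          # length(ds) x d_model/2
  out <- matrix(0, length(ds), d_model)
  out[, 2L * k + 1L] <- sin(ang)
  out[, 2L * k + 2L] <- cos(ang)
  out
}

#' Pairwise span distances of a flat lattice
#'
#' For tokens i = (b_i, e_i) and j = (b_j, e_j), the four relative distances
#' b_i - b_j, b_i - e_j, e_i - b_j, e_i - e_j (head-head, head-tail,
#' tail-head, tail-tail).
#'
#' @param lattice an `sl_lattice`.
#' @return An n x n x 4 integer array.
#' @export
span_distances <- function(lattice) {
  h <- lattice$tokens$head; t <- lattice$tokens$tail
  n <- length(h)
  arr <- array(0L, dim = c(n, n, 4L),
               dimnames = list(NULL, NULL, c("hh", "ht", "th", "tt")))
  arr[, , 1L] <- outer(h, h, "-")
  arr[, , 2L] <- outer(h, t, "-")
  arr[, , 3L] <- outer(t, h, "-")
  arr[, , 4L] <- outer(t, t, "-")
  arr
}

## Raw sinusoid feature matrix P: one row per ordered token pair (i-major:
## row (i-1)*n + j), d_pos columns. four_distance concatenates the four
## distance encodings (d_pos = 4 d_model); span_length uses only the key
## token's span length e_j - b_j (d_pos = d_model).
position_features <- function(lattice, d_model, position_mode) {
  n <- nrow(lattice$tokens)
  if (position_mode == "span_length") {
    len <- lattice$tokens$tail - lattice$tokens$head
    ud <- sort(unique(len))
    S <- sinusoid_matrix(ud, d_model)
    jseq <- rep(seq_len(n), times = n)   # i-major pair order
    return(S[match(len, ud)[jseq], , drop = FALSE])
  }
  D <- span_distances(lattice)
  ud <- sort(unique(as.vector(D)))
  S <- sinusoid_matrix(ud, d_model)
  blocks <- lapply(1:4, function(k) {
    dk <- t(D[, , k])            # transpose so as.vector is i-major
    S[match(as.vector(dk), ud), , drop = FALSE]
  })
  do.call(cbind, blocks)
}

#' Relative position encodings R of a lattice
#'
#' Sinusoid-encodes the pairwise span distances, projects with the learned
#' `W_r` and applies ReLU, yielding the non-negative relative position code
#' for every ordered token pair.
#'
#' @param lattice an `sl_lattice`.
#' @param params an `sl_params` object (layer 1's `W_r` is used).
#' @return List: `distances` (n x n x 4 array) and `R`, an (n*n) x d_model
#'   matrix whose row (i-1)*n + j encodes the pair (i, j).
#' @export
relative_position_bias <- function(lattice, params) {
  cfg <- params$config
  P <- position_features(lattice, cfg$d_model, cfg$position_mode)
  W_r <- params$layers[[1L]]$W_r
  R <- pmax(P %*% t(W_r), 0)
  list(distances = span_distances(lattice), R = R)
}

#' Relative-position attention scores
#'
#' The four-term score for every ordered token pair (i, j): content-content
#' `(W_q E_i)' (W_kE E_j)`, content-position `(W_q E_i)' (W_kR R_ij)`, and
#' the two global bias terms `u' (W_kE E_j)` and `v' (W_kR R_ij)`, split
#' across heads and scaled by `1/sqrt(d_head)`.
#'
#' @param E n x d_model matrix of token representations.
#' @param R (n*n) x d_model matrix of pair position codes (i-major rows).
#' @param weights list with `W_q`, `W_kE`, `W_kR` (d x d), `u`, `v` (d).
#' @param n_heads number of attention heads.
#' @return List of n x n score matrices, one per head.
#' @export
attention_scores <- function(E, R, weights, n_heads = 1L) {
  n <- nrow(E); d <- ncol(E)
  stopifnot(d %% n_heads == 0L, nrow(R) == n * n)
  dh <- d %/% n_heads
  Q <- E %*% t(weights$W_q)
  KE <- E %*% t(weights$W_kE)
  KR <- R %*% t(weights$W_kR)
  iidx <- rep(seq_len(n), each = n)
  lapply(seq_len(n_heads), function(h) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qu <- sweep(Q[, cols, drop = FALSE], 2L, weights$u[cols], "+")
    Qv <- sweep(Q[, cols, drop = FALSE], 2L, weights$v[cols], "+")
    A1 <- Qu %*% t(KE[, cols, drop = FALSE])
    bd <- rowSums(KR[, cols, drop = FALSE] * Qv[iidx, , drop = FALSE])
    (A1 + matrix(bd, n, n, byrow = TRUE)) / sqrt(dh)
  })
}

xavier <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Initialise encoder parameters
#'
#' Embeddings are drawn uniform in (-0.1, 0.1) under the caller's RNG state;
#' weight matrices use Xavier-uniform initialisation; layer-norm gains start
#' at 1, biases and the global attention biases u, v at 0. When `d_embed`
#' differs from `d_model` a learned input projection is added.
#'
#' @param tokens character vector of known token surfaces (characters and
#'   words); an `<unk>` row is always added.
#' @param config list with `d_model`, `n_heads`, `n_layers`, `d_embed`,
#'   `dropout`, `position_mode`, and `tags`.
#' @param embeddings optional numeric matrix (rownames = tokens) of external
#'   character embeddings to seed the table with.
#' @return An object of class `sl_params`.
#' @export
sl_params_init <- function(tokens, config, embeddings = NULL) {
  d <- config$d_model
  stopifnot(d %% config$n_heads == 0L, d %% 2L == 0L)
  d_embed <- if (is.null(config$d_embed)) d else config$d_embed
  config$d_embed <- d_embed
  config$d_head <- d %/% config$n_heads
  d_pos <- if (config$position_mode == "span_length") d else 4L * d
  tokens <- unique(c(tokens, "<unk>"))
  embed <- matrix(stats::runif(length(tokens) * d_embed, -0.1, 0.1),
                  length(tokens), d_embed, dimnames = list(tokens, NULL))
  if (!is.null(embeddings)) {
    hit <- intersect(rownames(embeddings), tokens)
    if (ncol(embeddings) != d_embed)
      stop("external embeddings have ", ncol(embeddings),
           " dimensions; config$d_embed is ", d_embed, call. = FALSE)
    embed[hit, ] <- embeddings[hit, , drop = FALSE]
  }
  d_ff <- 2L * d
  layers <- lapply(seq_len(config$n_layers), function(l) list(
    W_q = xavier(d, d), W_kE = xavier(d, d), W_kR = xavier(d, d),
    W_v = xavier(d, d), W_r = xavier(d, d_pos),
    u = numeric(d), v = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    W1 = xavier(d_ff, d), b1 = numeric(d_ff),
    W2 = xavier(d, d_ff), b2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d)))
  n_tags <- length(config$tags)
  structure(list(config = config, embed = embed,
                 W_in = if (d_embed != d) xavier(d, d_embed) else NULL,
                 layers = layers,
                 W_emit = xavier(n_tags, d), b_emit = numeric(n_tags)),
            class = "sl_params")
}

ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd
  list(Y = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, sd = sd)
}

ln_backward <- function(dY, xhat, sd, g) {
  dxhat <- sweep(dY, 2L, g, "*")
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

drop_mask <- function(nr, nc, p) {
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

#' Encode a flat lattice and emit per-character tag scores
#'
#' Runs `n_layers` of relative-position multi-head self-attention (add &
#' layer-norm, position-wise feed-forward, add & layer-norm) over the
#' lattice tokens, then applies a learned linear map to the character rows.
#' Word tokens participate in attention but receive no emissions. Dropout is
#' active only when `train_mode` is `TRUE`. With `n_layers = 0` the
#' emissions are the linear map of the (projected) raw embeddings.
#'
#' @param lattice an `sl_lattice`.
#' @param params an `sl_params`.
#' @param train_mode apply dropout (uses the current RNG state)?
#' @param cache keep intermediates for the backward pass?
#' @return List with `emissions` (n_chars x n_tags), `hidden` (final n x
#'   d_model states) and, when requested, `cache`.
#' @export
encoder_forward <- function(lattice, params, train_mode = FALSE,
                            cache = FALSE) {
  stopifnot(inherits(lattice, "sl_lattice"))
  cfg <- params$config
  n <- nrow(lattice$tokens)
  if (n == 0L) stop("encoder_forward: empty lattice", call. = FALSE)
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  p_drop <- if (train_mode) cfg$dropout else 0

  ids <- match(lattice$tokens$surface, rownames(params$embed))
  ids[is.na(ids)] <- match("<unk>", rownames(params$embed))
  X0 <- params$embed[ids, , drop = FALSE]
  H <- if (is.null(params$W_in)) X0 else X0 %*% t(params$W_in)

  P <- position_features(lattice, d, cfg$position_mode)
  iidx <- rep(seq_len(n), each = n)
  caches <- vector("list", cfg$n_layers)

  for (l in seq_len(cfg$n_layers)) {
    w <- params$layers[[l]]
    H_in <- H
    R_pre <- P %*% t(w$W_r)
    Rm <- pmax(R_pre, 0)
    Q <- H %*% t(w$W_q); KE <- H %*% t(w$W_kE)
    KR <- Rm %*% t(w$W_kR); V <- H %*% t(w$W_v)
    O <- matrix(0, n, d)
    hc <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qu <- sweep(Q[, cols, drop = FALSE], 2L, w$u[cols], "+")
      Qv <- sweep(Q[, cols, drop = FALSE], 2L, w$v[cols], "+")
      A <- Qu %*% t(KE[, cols, drop = FALSE])
      bd <- rowSums(KR[, cols, drop = FALSE] * Qv[iidx, , drop = FALSE])
      A <- (A + matrix(bd, n, n, byrow = TRUE)) / sqrt(dh)
      if (any(!is.finite(A)))
        stop("non-finite attention score in layer ", l, call. = FALSE)
      Am <- exp(A - apply(A, 1L, max))
      alpha <- Am / rowSums(Am)
      mask_a <- if (p_drop > 0) drop_mask(n, n, p_drop) else NULL
      alpha_d <- if (is.null(mask_a)) alpha else alpha * mask_a
      O[, cols] <- alpha_d %*% V[, cols, drop = FALSE]
      hc[[h]] <- list(Qu = Qu, Qv = Qv, alpha = alpha, alpha_d = alpha_d,
                      mask_a = mask_a)
    }
    mask_o <- if (p_drop > 0) drop_mask(n, d, p_drop) else NULL
    Od <- if (is.null(mask_o)) O else O * mask_o
    ln1 <- ln_forward(H + Od, w$ln1_g, w$ln1_b)
    H1 <- ln1$Y
    Z <- H1 %*% t(w$W1) + rep(w$b1, each = n)
    Zr <- pmax(Z, 0)
    Fo <- Zr %*% t(w$W2) + rep(w$b2, each = n)
    mask_f <- if (p_drop > 0) drop_mask(n, d, p_drop) else NULL
    Fd <- if (is.null(mask_f)) Fo else Fo * mask_f
    ln2 <- ln_forward(H1 + Fd, w$ln2_g, w$ln2_b)
    H <- ln2$Y
    caches[[l]] <- list(H_in = H_in, R_pre = R_pre, Rm = Rm, Q = Q, KE = KE,
                        KR = KR, V = V, heads = hc, mask_o = mask_o,
                        ln1 = ln1, H1 = H1, Z = Z, Zr = Zr,
                        mask_f = mask_f, ln2 = ln2)
  }

  nc <- lattice$n_chars
  Hc <- H[seq_len(nc), , drop = FALSE]
  em <- Hc %*% t(params$W_emit) + rep(params$b_emit, each = nc)
  out <- list(emissions = em, hidden = H)
  if (cache)
    out$cache <- list(layers = caches, X0 = X0, ids = ids, P = P,
                      iidx = iidx, H_final = H, n = n, n_chars = nc)
  out
}

## Backward pass: d_em is the gradient of the loss w.r.t. the emissions.
## Returns a gradient structure mirroring the parameters.
encoder_backward <- function(d_em, params, fw) {
  cfg <- params$config
  cc <- fw$cache
  n <- cc$n; d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  g <- zero_grads(params)

  Hc <- cc$H_final[seq_len(cc$n_chars), , drop = FALSE]
  g$W_emit <- t(d_em) %*% Hc
  g$b_emit <- colSums(d_em)
  dH <- matrix(0, n, d)
  dH[seq_len(cc$n_chars), ] <- d_em %*% params$W_emit

  for (l in rev(seq_len(cfg$n_layers))) {
    w <- params$layers[[l]]
    ca <- caches_at(cc, l)
    ## LN2 / feed-forward
    b2g <- ln_backward(dH, ca$ln2$xhat, ca$ln2$sd, w$ln2_g)
    g$layers[[l]]$ln2_g <- b2g$dg; g$layers[[l]]$ln2_b <- b2g$db
    dH1 <- b2g$dX
    dFo <- if (is.null(ca$mask_f)) b2g$dX else b2g$dX * ca$mask_f
    g$layers[[l]]$W2 <- t(dFo) %*% ca$Zr
    g$layers[[l]]$b2 <- colSums(dFo)
    dZ <- (dFo %*% w$W2) * (ca$Z > 0)
    g$layers[[l]]$W1 <- t(dZ) %*% ca$H1
    g$layers[[l]]$b1 <- colSums(dZ)
    dH1 <- dH1 + dZ %*% w$W1
    ## LN1 / attention
    b1g <- ln_backward(dH1, ca$ln1$xhat, ca$ln1$sd, w$ln1_g)
    g$layers[[l]]$ln1_g <- b1g$dg; g$layers[[l]]$ln1_b <- b1g$db
    dH_in <- b1g$dX
    dO <- if (is.null(ca$mask_o)) b1g$dX else b1g$dX * ca$mask_o
    dQ <- matrix(0, n, d); dKE <- matrix(0, n, d)
    dV <- matrix(0, n, d); dKR <- matrix(0, n * n, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      hc <- ca$heads[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- ca$V[, cols, drop = FALSE]
      dalpha_d <- dOh %*% t(Vh)
      dV[, cols] <- t(hc$alpha_d) %*% dOh
      dalpha <- if (is.null(hc$mask_a)) dalpha_d else dalpha_d * hc$mask_a
      dA <- hc$alpha * (dalpha - rowSums(dalpha * hc$alpha))
      dA <- dA / sqrt(dh)
      KEh <- ca$KE[, cols, drop = FALSE]
      KRh <- ca$KR[, cols, drop = FALSE]
      dQu <- dA %*% KEh
      dKE[, cols] <- t(dA) %*% hc$Qu
      vec_dA <- as.vector(t(dA))
      dQv <- rowsum(KRh * vec_dA, cc$iidx, reorder = TRUE)
      dKR[, cols] <- vec_dA * hc$Qv[cc$iidx, , drop = FALSE]
      dQ[, cols] <- dQu + dQv
      g$layers[[l]]$u[cols] <- colSums(dQu)
      g$layers[[l]]$v[cols] <- colSums(dQv)
    }
    H_in <- ca$H_in
    g$layers[[l]]$W_q <- t(dQ) %*% H_in
    g$layers[[l]]$W_kE <- t(dKE) %*% H_in
    g$layers[[l]]$W_v <- t(dV) %*% H_in
    g$layers[[l]]$W_kR <- t(dKR) %*% ca$Rm
    dRm <- dKR %*% w$W_kR
    g$layers[[l]]$W_r <- t(dRm * (ca$R_pre > 0)) %*% cc$P
    dH_in <- dH_in + dQ %*% w$W_q + dKE %*% w$W_kE + dV %*% w$W_v
    dH <- dH_in
  }

  if (!is.null(params$W_in)) {
    g$W_in <- t(dH) %*% cc$X0
    dX0 <- dH %*% params$W_in
  } else dX0 <- dH
  agg <- rowsum(dX0, cc$ids, reorder = FALSE)
  g$embed[as.integer(rownames(agg)), ] <- g$embed[as.integer(rownames(agg)), ] + agg
  g
}

caches_at <- function(cc, l) cc$layers[[l]]

zero_grads <- function(params) {
  zl <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(embed = matrix(0, nrow(params$embed), ncol(params$embed)),
       W_in = if (is.null(params$W_in)) NULL else zl(params$W_in),
       layers = lapply(params$layers, function(w) lapply(w, zl)),
       W_emit = zl(params$W_emit), b_emit = zl(params$b_emit))
}

## elementwise grads accumulation / update helpers --------------------------

acc_grads <- function(a, b) {
  a$embed <- a$embed + b$embed
  if (!is.null(a$W_in)) a$W_in <- a$W_in + b$W_in
  for (l in seq_along(a$layers))
    for (nm in names(a$layers[[l]]))
      a$layers[[l]][[nm]] <- a$layers[[l]][[nm]] + b$layers[[l]][[nm]]
  a$W_emit <- a$W_emit + b$W_emit
  a$b_emit <- a$b_emit + b$b_emit
  a
}

scale_grads <- function(g, s) {
  g$embed <- g$embed * s
  if (!is.null(g$W_in)) g$W_in <- g$W_in * s
  for (l in seq_along(g$layers))
    g$layers[[l]] <- lapply(g$layers[[l]], function(x) x * s)
  g$W_emit <- g$W_emit * s
  g$b_emit <- g$b_emit * s
  g
}

grad_sqnorm <- function(g) {
  s <- sum(g$embed^2) + sum(g$W_emit^2) + sum(g$b_emit^2)
  if (!is.null(g$W_in)) s <- s + sum(g$W_in^2)
  for (l in seq_along(g$layers))
    s <- s + sum(vapply(g$layers[[l]], function(x) sum(x^2), 0))
  s
}

sgd_step <- function(params, g, lr) {
  params$embed <- params$embed - lr * g$embed
  if (!is.null(params$W_in)) params$W_in <- params$W_in - lr * g$W_in
  for (l in seq_along(params$layers))
    for (nm in names(params$layers[[l]]))
      params$layers[[l]][[nm]] <- params$layers[[l]][[nm]] - lr * g$layers[[l]][[nm]]
  params$W_emit <- params$W_emit - lr * g$W_emit
  params$b_emit <- params$b_emit - lr * g$b_emit
  params
}
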