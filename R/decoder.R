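#' Decoder parameters
#'
#' Bundles the Tucker core tensor with the decoder nonlinearity and dropout
#' rates. Dropout is applied only in training mode; scoring at evaluation
#' time is deterministic.
#'
#' @param core 3-way numeric array `d x d x d` (the shared core tensor
#'   mediating all entity-relation-entity interactions).
#' @param f_non Name of the decoder nonlinearity (`"identity"` recovers the
#'   plain linear Tucker scorer).
#' @param input_dropout,hidden_dropout1,hidden_dropout2 Dropout rates in
#'   `[0, 1)`: on the head embedding, after the relation contraction, and
#'   after the nonlinearity.
#' @param prelu_slope Negative slope when `f_non = "prelu"`.
#' @return A list of class `decoder_params`.
#' @export
decoder_params <- function(core, f_non = "leakyrelu", input_dropout = 0,
                           hidden_dropout1 = 0, hidden_dropout2 = 0,
                           prelu_slope = 0.25) {
  stopifnot(is.array(core), length(dim(core)) == 3L,
            length(unique(dim(core))) == 1L, all(is.finite(core)))
  rates <- c(input_dropout, hidden_dropout1, hidden_dropout2)
  stopifnot(all(rates >= 0 & rates < 1))
  structure(list(core = core, f_non = tolower(f_non),
                 input_dropout = input_dropout,
                 hidden_dropout1 = hidden_dropout1,
                 hidden_dropout2 = hidden_dropout2,
                 prelu_slope = prelu_slope),
            class = "decoder_params")
}

# core as d x d^2 matrix: column index j + (k-1)*d  (column-major unfold)
core_unfold <- function(core) {
  d <- dim(core)[1L]
  matrix(core, d, d * d)
}

#' Mode-1/mode-2 tensor contraction
#'
#' Contracts the core tensor with a head-entity vector along mode 1 and a
#' relation vector along mode 2: `v[k] = sum_ij core[i,j,k] e_s[i] r[j]`.
#' This is the query-specific vector that every candidate tail is scored
#' against.
#'
#' @param core 3-way array `d x d x d`.
#' @param e_s,r Numeric vectors of length d.
#' @return Numeric vector of length d.
#' @examples
#' core <- array(2, c(1, 1, 1))
#' mode_product_chain(core, 3, 0.5)
#' @export
mode_product_chain <- function(core, e_s, r) {
  d <- dim(core)[1L]
  stopifnot(length(dim(core)) == 3L, all(dim(core) == d),
            length(e_s) == d, length(r) == d)
  tmat <- as.numeric(e_s %*% core_unfold(core))  # length d^2, j fast, k slow
  as.numeric(r %*% matrix(tmat, d, d))
}

#' Linear Tucker 1-N scoring
#'
#' Scores the query `(e_s, r, ?)` against every candidate tail row of
#' `entity_table` with the trilinear Tucker form
#' `score[o] = e_o . (core x1 e_s x2 r)`.
#'
#' @param e_s,r Numeric vectors of length d.
#' @param entity_table Numeric matrix `n_ent x d` of candidate tails.
#' @param core 3-way array `d x d x d`.
#' @return Numeric vector of scores, one per candidate tail.
#' @export
tucker_score <- function(e_s, r, entity_table, core) {
  v <- mode_product_chain(core, e_s, r)
  as.numeric(entity_table %*% v)
}

#' Nonlinear Tucker 1-N scoring
#'
#' As [tucker_score()] but with the decoder nonlinearity applied to the
#' contracted query vector before the candidate contraction:
#' `score[o] = e_o . f_non(core x1 e_s x2 r)`. With `f_non = "identity"`
#' this equals [tucker_score()] exactly.
#'
#' @inheritParams tucker_score
#' @param params A `decoder_params` object (supplies the core tensor, the
#'   nonlinearity, and its slope).
#' @return Numeric vector of scores.
#' @export
ftucker_score <- function(e_s, r, entity_table, params) {
  f <- activation(params$f_non, params$prelu_slope)
  v <- f$fn(mode_product_chain(params$core, e_s, r))
  as.numeric(entity_table %*% v)
}

# batched scorer: queries given as index vectors into encoded tables.
# Training mode draws inverted-dropout masks and returns a cache for backward.
score_queries <- function(params, enc, qh, qr, training = FALSE) {
  d <- dim(params$core)[1L]
  Wm <- core_unfold(params$core)
  f <- activation(params$f_non, params$prelu_slope)
  es <- enc$entity_out[qh, , drop = FALSE]
  r <- enc$relation_out[qr, , drop = FALSE]
  B <- nrow(es)
  m1 <- m2 <- m3 <- NULL
  if (training && params$input_dropout > 0) {
    m1 <- matrix(stats::rbinom(B * d, 1L, 1 - params$input_dropout),
                 B, d) / (1 - params$input_dropout)
    es <- es * m1
  }
  tm <- es %*% Wm                       # B x d^2, col = j + (k-1)d
  v <- matrix(0, B, d)
  for (k in seq_len(d)) {
    v[, k] <- rowSums(tm[, (k - 1L) * d + seq_len(d), drop = FALSE] * r)
  }
  if (training && params$hidden_dropout1 > 0) {
    m2 <- matrix(stats::rbinom(B * d, 1L, 1 - params$hidden_dropout1),
                 B, d) / (1 - params$hidden_dropout1)
    v <- v * m2
  }
  z <- f$fn(v)
  if (training && params$hidden_dropout2 > 0) {
    m3 <- matrix(stats::rbinom(B * d, 1L, 1 - params$hidden_dropout2),
                 B, d) / (1 - params$hidden_dropout2)
    z <- z * m3
  }
  scores <- z %*% t(enc$entity_out)
  list(scores = scores,
       cache = list(es = es, r = r, tm = tm, v = v, z = z,
                    m1 = m1, m2 = m2, m3 = m3))
}

# backward through score_queries; dscores is B x n_ent.
# Returns gradients wrt the encoded tables and the core tensor.
score_queries_backward <- function(params, enc, qh, qr, sc, dscores) {
  d <- dim(params$core)[1L]
  Wm <- core_unfold(params$core)
  f <- activation(params$f_non, params$prelu_slope)
  ch <- sc$cache
  dz <- dscores %*% enc$entity_out
  dE_cand <- crossprod(dscores, ch$z)
  if (!is.null(ch$m3)) dz <- dz * ch$m3
  dv <- dz * f$grad(ch$v)
  if (!is.null(ch$m2)) dv <- dv * ch$m2
  B <- nrow(dv)
  dtm <- matrix(0, B, d * d)
  dr <- matrix(0, B, d)
  for (k in seq_len(d)) {
    cols <- (k - 1L) * d + seq_len(d)
    dtm[, cols] <- ch$r * dv[, k]
    dr <- dr + ch$tm[, cols, drop = FALSE] * dv[, k]
  }
  des <- dtm %*% t(Wm)
  dWm <- crossprod(ch$es, dtm)
  if (!is.null(ch$m1)) des <- des * ch$m1
  n_ent <- nrow(enc$entity_out)
  n_rel <- nrow(enc$relation_out)
  dE <- dE_cand + scatter_rowsum(des, qh, n_ent)
  dR <- scatter_rowsum(dr, qr, n_rel)
  list(dE = dE, dR = dR, dcore = array(dWm, dim(params$core)))
}

#' Score one query through the full encoder-decoder model
#'
#' Encodes the graph (or reuses a supplied encoding), then scores the tail
#' query `(head, rel, ?)` against all entities with the nonlinear Tucker
#' decoder. Probabilities are the logistic transform of the scores — the
#' quantity thresholded during graph completion.
#'
#' @param head,rel Entity and (augmented) relation indices.
#' @param params Model parameters ([kge_init()] or a fitted model's
#'   `$params`).
#' @param kg A reciprocal-augmented `semlink_kg`.
#' @param encoded Optional precomputed [encode()] output (avoids re-encoding
#'   when scoring many queries).
#' @return A tibble with columns `tail`, `score`, `probability`, one row per
#'   candidate entity.
#' @export
gnn_ftucker_score <- function(head, rel, params, kg, encoded = NULL) {
  enc <- encoded %||% encode(params, kg)
  n_ent <- nrow(enc$entity_out)
  n_rel <- nrow(enc$relation_out)
  if (head < 1L || head > n_ent || rel < 1L || rel > n_rel) {
    stop("query index out of range", call. = FALSE)
  }
  dec <- decoder_slice(params)
  s <- ftucker_score(enc$entity_out[head, ], enc$relation_out[rel, ],
                     enc$entity_out, dec)
  tibble::tibble(tail = seq_len(n_ent), score = s, probability = logistic(s))
}

# view of the full parameter list as decoder_params
decoder_slice <- function(params) {
  decoder_params(params$core, f_non = params$f_non,
                 input_dropout = params$input_dropout,
                 hidden_dropout1 = params$hidden_dropout1,
                 hidden_dropout2 = params$hidden_dropout2,
                 prelu_slope = params$prelu_slope)
}
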