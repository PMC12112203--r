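#' Dot-product attention weights
#'
#' Softmax attention of a centre embedding over a set of neighbour keys:
#' `w_j = exp(k_j . c) / sum_k exp(k_k . c)`, computed with max-subtraction
#' for numerical stability. An empty key set yields an empty weight vector.
#'
#' @param center_vec Numeric vector (length d), the centre entity embedding.
#' @param neighbor_keys Numeric matrix with d columns, one key per row (or an
#'   empty matrix / NULL).
#' @return Numeric vector of weights, one per key row; sums to 1 when
#'   non-empty.
#' @examples
#' attention_weights(c(1, 0), rbind(c(1, 0), c(0, 1)))
#' @export
attention_weights <- function(center_vec, neighbor_keys) {
  if (is.null(neighbor_keys) || NROW(neighbor_keys) == 0L) return(numeric(0))
  keys <- rbind(neighbor_keys)
  if (!all(is.finite(center_vec)) || !all(is.finite(keys))) {
    stop("non-finite values in attention inputs", call. = FALSE)
  }
  logits <- as.numeric(keys %*% center_vec)
  w <- exp(logits - max(logits))
  w / sum(w)
}

#' Combine a neighbour entity and relation embedding
#'
#' The composition `phi(e_j, r_j)` used by triple-level aggregation:
#' elementwise product (default) or sum. Operates on vectors or on
#' conforming matrices (row-wise).
#'
#' @param e,r Numeric vectors or matrices of equal shape.
#' @param mode `"multiply"` or `"add"`.
#' @return The composed vector/matrix.
#' @export
compose <- function(e, r, mode = c("multiply", "add")) {
  mode <- match.arg(mode)
  if (mode == "multiply") e * r else e + r
}

se_neighbor_data <- function(i, params, kg, embeddings) {
  E <- embeddings$E %||% params$E
  R <- embeddings$R %||% params$R
  nb <- neighbors_of(kg, i)
  list(E = E, R = R, nb = nb)
}

se_aggregate <- function(center, keys, values, W, act) {
  if (NROW(keys) == 0L) return(rep(0, length(center)))
  alpha <- attention_weights(center, keys)
  msg <- values %*% t(W)
  act$fn(as.numeric(colSums(alpha * msg)))
}

#' Relation-level semantic evidence for one entity
#'
#' Reference (per-entity) implementation of the relation-level aggregation:
#' `s_i = act( sum_j alpha_ij W_rel r_j )` with attention computed from the
#' dot products of the centre entity against its neighbours' relation
#' embeddings. Entities without neighbours get the zero vector. The
#' vectorised all-entity path used in training is [encode()]; these
#' per-entity forms are its audit trail.
#'
#' @param i Entity index.
#' @param layer Encoder layer number (selects the transform).
#' @param params Model parameters ([kge_init()]).
#' @param kg A reciprocal-augmented `semlink_kg`.
#' @param embeddings Optional list `E`, `R` of current-layer embeddings;
#'   defaults to the raw tables in `params`.
#' @return Numeric vector of length d.
#' @export
relation_se <- function(i, layer, params, kg, embeddings = list()) {
  dat <- se_neighbor_data(i, params, kg, embeddings)
  act <- activation(params$activation, params$prelu_slope)
  keys <- dat$R[dat$nb$rel, , drop = FALSE]
  se_aggregate(dat$E[i, ], keys, keys, params$layers[[layer]]$W_rel, act)
}

#' Entity-level semantic evidence for one entity
#'
#' As [relation_se()], but aggregating neighbour entity embeddings with
#' attention over entity-entity dot products.
#'
#' @inheritParams relation_se
#' @return Numeric vector of length d.
#' @export
entity_se <- function(i, layer, params, kg, embeddings = list()) {
  dat <- se_neighbor_data(i, params, kg, embeddings)
  act <- activation(params$activation, params$prelu_slope)
  keys <- dat$E[dat$nb$nbr, , drop = FALSE]
  se_aggregate(dat$E[i, ], keys, keys, params$layers[[layer]]$W_ent, act)
}

#' Triple-level semantic evidence for one entity
#'
#' As [relation_se()], but aggregating the composed neighbour pair
#' `phi(e_j, r_j)` with attention over the dot products of the composition
#' against the centre entity.
#'
#' @inheritParams relation_se
#' @return Numeric vector of length d.
#' @export
triple_se <- function(i, layer, params, kg, embeddings = list()) {
  dat <- se_neighbor_data(i, params, kg, embeddings)
  act <- activation(params$activation, params$prelu_slope)
  keys <- compose(dat$E[dat$nb$nbr, , drop = FALSE],
                  dat$R[dat$nb$rel, , drop = FALSE], params$composition)
  se_aggregate(dat$E[i, ], keys, keys, params$layers[[layer]]$W_tri, act)
}

# ---- vectorised grouped helpers -------------------------------------------

# max per group via ordered assignment (last write wins on sorted values)
group_max <- function(x, grp, n_groups) {
  gm <- rep(-Inf, n_groups)
  o <- order(grp, x)
  gm[grp[o]] <- x[o]
  gm
}

group_softmax <- function(logits, grp, n_groups) {
  gm <- group_max(logits, grp, n_groups)
  w <- exp(logits - gm[grp])
  denom <- group_sum(w, grp, n_groups)
  w / denom[grp]
}

group_sum <- function(x, grp, n_groups) {
  out <- numeric(n_groups)
  rs <- rowsum(x, grp)
  out[as.integer(rownames(rs))] <- rs
  out
}

# scatter-add rows of `mat` into an n_rows x d matrix by integer group
scatter_rowsum <- function(mat, grp, n_rows) {
  out <- matrix(0, n_rows, ncol(mat))
  rs <- rowsum(mat, grp)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# ---- full-graph encoder ----------------------------------------------------

level_forward <- function(E, R, edges, W, comp, act) {
  c_ <- edges$center; n_ <- edges$nbr; q_ <- edges$rel
  n_ent <- nrow(E)
  Ec <- E[c_, , drop = FALSE]
  keysets <- list(
    rel = R[q_, , drop = FALSE],
    ent = E[n_, , drop = FALSE],
    tri = compose(E[n_, , drop = FALSE], R[q_, , drop = FALSE], comp)
  )
  res <- purrr::imap(keysets, function(keys, lev) {
    logits <- rowSums(Ec * keys)
    alpha <- group_softmax(logits, c_, n_ent)
    m <- scatter_rowsum((alpha * keys) %*% t(W[[lev]]), c_, n_ent)
    list(alpha = alpha, m = m, s = act$fn(m))
  })
  res
}

encode_forward <- function(params, kg, cache = FALSE) {
  E <- params$E
  R <- params$R
  L <- length(params$layers)
  act <- activation(params$activation, params$prelu_slope)
  edges <- kg$edges
  if (L > 0L && is.null(edges)) {
    stop("encoder needs the neighbour index; call kg_add_reciprocals() first",
         call. = FALSE)
  }
  layers_cache <- if (cache) vector("list", L) else NULL
  if (L > 0L) {
    for (l in seq_len(L)) {
      lay <- params$layers[[l]]
      lev <- level_forward(E, R, edges,
                           list(rel = lay$W_rel, ent = lay$W_ent, tri = lay$W_tri),
                           params$composition, act)
      u <- lev$rel$s + lev$ent$s + lev$tri$s
      g <- u %*% t(lay$F)
      E_next <- E + act$fn(g)
      R_next <- R %*% t(lay$U)
      if (!all(is.finite(E_next)) || !all(is.finite(R_next))) {
        stop("non-finite embeddings after encoder layer ", l, call. = FALSE)
      }
      if (cache) {
        layers_cache[[l]] <- list(E_in = E, R_in = R, lev = lev, u = u, g = g)
      }
      E <- E_next
      R <- R_next
    }
  }
  list(entity_out = E, relation_out = R, cache = layers_cache)
}

#' Encode all entities and relations
#'
#' Runs the L-layer semantic-evidence encoder over the whole graph. Each
#' layer computes, for every entity, the three attention-aggregated evidence
#' vectors (relation-, entity- and triple-level), sums them, applies a
#' learned fusion transform and activation, and adds the result to the
#' previous layer's embedding (residual update, synchronous across
#' entities). Relations are updated by a per-layer linear transform.
#' `L = 0` returns the raw tables unchanged (the "no GNN" ablation).
#'
#' @param params Model parameters ([kge_init()]).
#' @param kg A reciprocal-augmented `semlink_kg` (not needed when L = 0).
#' @return A list with matrices `entity_out` (n_ent x d) and `relation_out`
#'   (n_rel_augmented x d).
#' @export
encode <- function(params, kg = NULL) {
  out <- encode_forward(params, kg, cache = FALSE)
  out["cache"] <- NULL
  out
}

# backward pass through the cached encoder; returns gradients for E, R and
# every layer transform
encode_backward <- function(params, kg, fwd, dE_out, dR_out) {
  L <- length(params$layers)
  act <- activation(params$activation, params$prelu_slope)
  edges <- kg$edges
  dE <- dE_out
  dR <- dR_out
  dlayers <- vector("list", L)
  if (L == 0L) return(list(E = dE, R = dR, layers = dlayers))
  c_ <- edges$center; n_ <- edges$nbr; q_ <- edges$rel
  n_ent <- nrow(params$E)
  n_rel <- nrow(params$R)
  for (l in rev(seq_len(L))) {
    ch <- fwd$cache[[l]]
    lay <- params$layers[[l]]
    E_in <- ch$E_in; R_in <- ch$R_in
    # relation transform: R_next = R_in %*% t(U)
    dU <- crossprod(dR, R_in)
    dR <- dR %*% lay$U
    # residual entity update: E_next = E_in + act(g), g = u %*% t(F)
    dg <- dE * act$grad(ch$g)
    dF <- crossprod(dg, ch$u)
    du <- dg %*% lay$F
    dE_in <- dE   # residual path
    dR_in <- dR
    Ec <- E_in[c_, , drop = FALSE]
    Wl <- list(rel = lay$W_rel, ent = lay$W_ent, tri = lay$W_tri)
    dW <- list()
    for (lev in c("rel", "ent", "tri")) {
      keys <- switch(lev,
        rel = R_in[q_, , drop = FALSE],
        ent = E_in[n_, , drop = FALSE],
        tri = compose(E_in[n_, , drop = FALSE], R_in[q_, , drop = FALSE],
                      params$composition)
      )
      alpha <- ch$lev[[lev]]$alpha
      dm <- du * act$grad(ch$lev[[lev]]$m)
      dmc <- dm[c_, , drop = FALSE]
      msg <- keys %*% t(Wl[[lev]])
      dalpha <- rowSums(dmc * msg)
      dmsg <- alpha * dmc
      dW[[lev]] <- crossprod(dmsg, keys)
      dkeys <- dmsg %*% Wl[[lev]]
      # softmax backward
      S <- group_sum(alpha * dalpha, c_, n_ent)
      dlogit <- alpha * (dalpha - S[c_])
      dE_in <- dE_in + scatter_rowsum(dlogit * keys, c_, n_ent)
      dkeys <- dkeys + dlogit * Ec
      if (lev == "rel") {
        dR_in <- dR_in + scatter_rowsum(dkeys, q_, n_rel)
      } else if (lev == "ent") {
        dE_in <- dE_in + scatter_rowsum(dkeys, n_, n_ent)
      } else if (params$composition == "multiply") {
        dE_in <- dE_in + scatter_rowsum(dkeys * R_in[q_, , drop = FALSE], n_, n_ent)
        dR_in <- dR_in + scatter_rowsum(dkeys * E_in[n_, , drop = FALSE], q_, n_rel)
      } else {
        dE_in <- dE_in + scatter_rowsum(dkeys, n_, n_ent)
        dR_in <- dR_in + scatter_rowsum(dkeys, q_, n_rel)
      }
    }
    dlayers[[l]] <- list(W_rel = dW$rel, W_ent = dW$ent, W_tri = dW$tri,
                         F = dF, U = dU)
    dE <- dE_in
    dR <- dR_in
  }
  list(E = dE, R = dR, layers = dlayers)
}
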