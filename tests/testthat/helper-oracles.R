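# Independent reference implementations used as oracles. These deliberately
# use plain loops and their own softmax, and never call the package's
# vectorised paths.

# softmax of dot products, straight from the definition
ref_softmax <- function(x) {
  w <- exp(x - max(x))
  w / sum(w)
}

# trilinear Tucker score by triple-nested loop: e_o . (core x1 e_s x2 r)
ref_tucker_one <- function(core, e_s, r, e_o, f = identity) {
  d <- length(e_s)
  v <- numeric(d)
  for (k in seq_len(d)) {
    acc <- 0
    for (i in seq_len(d)) {
      for (j in seq_len(d)) {
        acc <- acc + core[i, j, k] * e_s[i] * r[j]
      }
    }
    v[k] <- acc
  }
  sum(e_o * f(v))
}

ref_tucker_all <- function(core, e_s, r, entity_table, f = identity) {
  vapply(seq_len(nrow(entity_table)),
         function(o) ref_tucker_one(core, e_s, r, entity_table[o, ], f),
         numeric(1))
}

# one full encoder pass by per-entity loops over the three aggregation
# levels, residual update, and per-layer relation transform
ref_encode <- function(params, kg) {
  act <- semlink::activation(params$activation, params$prelu_slope)$fn
  E <- params$E
  R <- params$R
  for (lay in params$layers) {
    E_new <- E
    for (i in seq_len(nrow(E))) {
      nb <- semlink:::neighbors_of(kg, i)
      if (nrow(nb) == 0L) next
      d <- ncol(E)
      s_rel <- s_ent <- s_tri <- numeric(d)
      keys_rel <- lapply(nb$rel, function(q) R[q, ])
      keys_ent <- lapply(nb$nbr, function(j) E[j, ])
      keys_tri <- lapply(seq_len(nrow(nb)), function(e) {
        if (params$composition == "multiply") E[nb$nbr[e], ] * R[nb$rel[e], ]
        else E[nb$nbr[e], ] + R[nb$rel[e], ]
      })
      agg <- function(keys, W) {
        a <- ref_softmax(vapply(keys, function(k) sum(k * E[i, ]), numeric(1)))
        s <- numeric(d)
        for (e in seq_along(keys)) s <- s + a[e] * as.numeric(W %*% keys[[e]])
        act(s)
      }
      u <- agg(keys_rel, lay$W_rel) + agg(keys_ent, lay$W_ent) +
        agg(keys_tri, lay$W_tri)
      E_new[i, ] <- E[i, ] + act(as.numeric(lay$F %*% u))
    }
    R <- R %*% t(lay$U)
    E <- E_new
  }
  list(entity_out = E, relation_out = R)
}

# random connected-ish KG with labelled triples
random_kg <- function(n_ent, n_rel, n_tri, seed = 1) {
  withr::local_seed(seed)
  repeat {
    df <- tibble::tibble(
      head = paste0("e", sample.int(n_ent, n_tri, replace = TRUE)),
      relation = paste0("r", sample.int(n_rel, n_tri, replace = TRUE)),
      tail = paste0("e", sample.int(n_ent, n_tri, replace = TRUE))
    )
    df <- df[!duplicated(df), ]
    if (nrow(df) >= n_tri * 0.8) break
  }
  kg_add_reciprocals(kg_build(df, quiet = TRUE))
}

# small random parameter set compatible with a kg
random_params <- function(kg, d, L, seed = 1, activation = "leakyrelu",
                          f_non = "leakyrelu", composition = "multiply") {
  cfg <- kge_config(hidden_dim = d, gnn_layers = L, activation = activation,
                    f_non = f_non, composition = composition,
                    input_dropout = 0, hidden_dropout1 = 0,
                    hidden_dropout2 = 0)
  kge_init(kg, cfg, seed = seed)
}

# full training loss as a function of parameters (no dropout), for
# finite-difference gradient checks
loss_at <- function(params, kg, qh, qr, y) {
  enc <- semlink:::encode_forward(params, kg, cache = FALSE)
  dec <- semlink:::decoder_slice(params)
  sc <- semlink:::score_queries(dec, enc, qh, qr, training = FALSE)
  semlink:::bce_from_logits(sc$scores, y)
}
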