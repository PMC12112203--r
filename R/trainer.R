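#' Training configuration
#'
#' Collects every tunable of the model and its training protocol. Defaults:
#' Xavier initialisation, Adam, 1-N binary cross-entropy with label
#' smoothing, up to 500 epochs with patience-50 early stopping on filtered
#' validation MRR, seed 1234, learning rate 0.001, batch 256, one encoder
#' layer, dimension 200, dropouts 0.1/0.2/0.3, and leaky-ReLU activations —
#' a setting suited to curated graphs of roughly a thousand entities.
#'
#' @param hidden_dim Embedding dimension d (entities and relations share it).
#' @param gnn_layers Encoder depth L in 0..3; 0 disables the encoder.
#' @param activation Encoder activation name.
#' @param composition Triple-level composition: `"multiply"` or `"add"`.
#' @param f_non Decoder nonlinearity; `"identity"` gives the plain linear
#'   Tucker decoder.
#' @param input_dropout,hidden_dropout1,hidden_dropout2 Decoder dropout rates.
#' @param learning_rate,batch_size Adam step size and mini-batch size.
#' @param label_smoothing Smoothing epsilon in `[0, 0.5)` for the 1-N targets.
#' @param epochs_max,patience Epoch cap and early-stopping patience
#'   (consecutive non-improving validation evaluations tolerated).
#' @param eval_every Validate every this many epochs.
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and epsilon.
#' @param prelu_slope Fixed negative slope used by `"prelu"`.
#' @param verbose Print per-evaluation progress.
#' @return A list of class `kge_config`.
#' @export
kge_config <- function(hidden_dim = 200, gnn_layers = 1,
                       activation = "leakyrelu", composition = "multiply",
                       f_non = "leakyrelu",
                       input_dropout = 0.1, hidden_dropout1 = 0.2,
                       hidden_dropout2 = 0.3,
                       learning_rate = 0.001, batch_size = 256,
                       label_smoothing = 0.1,
                       epochs_max = 500, patience = 50, eval_every = 1,
                       seed = 1234,
                       adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
                       prelu_slope = 0.25, verbose = FALSE) {
  stopifnot(hidden_dim >= 1, gnn_layers %in% 0:3,
            learning_rate > 0, batch_size >= 1,
            label_smoothing >= 0, label_smoothing < 0.5,
            epochs_max >= 1, patience >= 1)
  activation <- match.arg(tolower(activation), activation_names())
  f_non <- match.arg(tolower(f_non), activation_names())
  composition <- match.arg(composition, c("multiply", "add"))
  structure(as.list(environment()), class = "kge_config")
}

xavier <- function(nr, nc) {
  b <- sqrt(6) / sqrt(nr + nc)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

#' Initialise model parameters
#'
#' Draws all learnable state from the given seed: Xavier-uniform embedding
#' tables and encoder transforms, and a uniform(-1, 1) core tensor.
#' Identical `(kg, config, seed)` give bit-identical parameters.
#'
#' @param kg A reciprocal-augmented `semlink_kg` (relation table covers the
#'   augmented vocabulary).
#' @param config A [kge_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `kge_params` holding the entity/relation tables,
#'   per-layer transforms, the core tensor, and the architecture settings
#'   needed to evaluate the model.
#' @export
kge_init <- function(kg, config, seed = config$seed) {
  stopifnot(inherits(kg, "semlink_kg"))
  if (!isTRUE(kg$reciprocal)) {
    stop("kg must be reciprocal-augmented before initialisation", call. = FALSE)
  }
  d <- config$hidden_dim
  n_ent <- length(kg$entities)
  n_rel <- length(kg$relations)
  set.seed(seed)
  E <- xavier(n_ent, d)
  R <- xavier(n_rel, d)
  layers <- purrr::map(seq_len(config$gnn_layers), function(l) {
    list(W_rel = xavier(d, d), W_ent = xavier(d, d), W_tri = xavier(d, d),
         F = xavier(d, d), U = xavier(d, d))
  })
  core <- array(stats::runif(d^3, -1, 1), c(d, d, d))
  structure(
    list(E = E, R = R, layers = layers, core = core,
         activation = config$activation, composition = config$composition,
         f_non = config$f_non, prelu_slope = config$prelu_slope,
         input_dropout = config$input_dropout,
         hidden_dropout1 = config$hidden_dropout1,
         hidden_dropout2 = config$hidden_dropout2),
    class = "kge_params"
  )
}

#' Binary cross-entropy over 1-N targets
#'
#' Reference form of the training loss for a single query: targets are 1 for
#' observed tails and 0 elsewhere, smoothed as `y (1 - eps) + eps / n_ent`,
#' and the loss is the mean over all candidate entities of
#' `-(y log p + (1 - y) log(1 - p))`.
#'
#' @param probabilities Numeric vector of predicted probabilities in (0, 1),
#'   one per candidate entity.
#' @param true_tails Integer indices of the observed tails (non-empty).
#' @param eps Label-smoothing epsilon.
#' @return Scalar loss.
#' @export
bce_loss <- function(probabilities, true_tails, eps = 0) {
  if (length(true_tails) == 0L) {
    stop("every training query must have at least one observed tail", call. = FALSE)
  }
  n <- length(probabilities)
  y <- numeric(n)
  y[true_tails] <- 1
  y <- y * (1 - eps) + eps / n
  p <- pmin(pmax(probabilities, 1e-12), 1 - 1e-12)
  mean(-(y * log(p) + (1 - y) * log1p(-p)))
}

# numerically stable BCE from logits; y may be smoothed. Returns the mean
# over all entries; gradient wrt logits is (sigmoid(s) - y) / length(s).
bce_from_logits <- function(scores, y) {
  mean(pmax(scores, 0) - scores * y + log1p(exp(-abs(scores))))
}

# ---- flat parameter traversal for the optimiser ----------------------------

param_flatten <- function(params) {
  out <- list(E = params$E, R = params$R, core = params$core)
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      out[[paste0("L", l, ".", nm)]] <- params$layers[[l]][[nm]]
    }
  }
  out
}

param_unflatten <- function(params, flat) {
  params$E <- flat$E
  params$R <- flat$R
  params$core <- flat$core
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      params$layers[[l]][[nm]] <- flat[[paste0("L", l, ".", nm)]]
    }
  }
  params
}

adam_init <- function(flat) {
  list(m = purrr::map(flat, ~ .x * 0), v = purrr::map(flat, ~ .x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$adam_beta1^state$t
  bc2 <- 1 - cfg$adam_beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$adam_beta1 * state$m[[nm]] + (1 - cfg$adam_beta1) * g
    state$v[[nm]] <- cfg$adam_beta2 * state$v[[nm]] + (1 - cfg$adam_beta2) * g^2
    flat[[nm]] <- flat[[nm]] - cfg$learning_rate *
      (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$adam_eps)
  }
  list(flat = flat, state = state)
}

# ---- training queries -------------------------------------------------------

# group the augmented train split into (head, relation) 1-N queries
train_queries <- function(kg) {
  key <- paste0(kg$train$h, ":", kg$train$r)
  first <- !duplicated(key)
  tails <- split(kg$train$t, key)
  qh <- kg$train$h[first]
  qr <- kg$train$r[first]
  qkey <- key[first]
  list(h = qh, r = qr, tails = tails[qkey])
}

#' Fit the encoder-decoder link-prediction model
#'
#' Trains the full model with mini-batch 1-N binary cross-entropy and Adam.
#' Every training step re-encodes the graph with the current parameters,
#' scores a batch of `(head, relation)` queries against all entities, and
#' back-propagates through decoder and encoder. After each `eval_every`
#' epochs, filtered MRR is computed on the evaluation triples
#' (default: the validation split); the best-scoring parameter snapshot is
#' kept and training stops after `patience` consecutive non-improving
#' evaluations or at the epoch cap. Head prediction is trained symmetrically
#' through the reciprocal-augmented queries.
#'
#' @param kg A `semlink_kg`; reciprocal augmentation is applied if missing.
#' @param config A [kge_config()].
#' @param eval_triples Tibble of `(h, r, t)` index triples for model
#'   selection; defaults to `kg$valid`. Required non-empty (pass a training
#'   probe for memorisation studies).
#' @return An object of class `kge_model`: `params` (best snapshot),
#'   `history` tibble (epoch, mean training loss, validation MRR),
#'   `best_epoch`, `best_mrr`, `config`, and the augmented `kg`.
#' @export
kge_fit <- function(kg, config = kge_config(), eval_triples = NULL) {
  stopifnot(inherits(kg, "semlink_kg"))
  if (!isTRUE(kg$reciprocal)) kg <- kg_add_reciprocals(kg)
  eval_triples <- eval_triples %||% kg$valid
  if (nrow(kg$train) == 0L || NROW(eval_triples) == 0L) {
    stop("training requires a non-empty train split and evaluation triples",
         call. = FALSE)
  }
  params <- kge_init(kg, config)
  flat <- param_flatten(params)
  opt <- adam_init(flat)
  qs <- train_queries(kg)
  nq <- length(qs$h)
  n_ent <- length(kg$entities)
  eps <- config$label_smoothing

  best <- list(mrr = -Inf, epoch = 0L, flat = flat)
  since_improve <- 0L
  history <- vector("list", config$epochs_max)

  for (epoch in seq_len(config$epochs_max)) {
    ord <- sample.int(nq)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      params <- param_unflatten(params, flat)
      enc <- encode_forward(params, kg, cache = TRUE)
      dec <- decoder_slice(params)
      sc <- score_queries(dec, enc, qs$h[b], qs$r[b], training = TRUE)
      # smoothed 1-N targets
      y <- matrix(eps / n_ent, length(b), n_ent)
      tl <- qs$tails[b]
      rows <- rep.int(seq_along(b), lengths(tl))
      y[cbind(rows, unlist(tl, use.names = FALSE))] <- 1 - eps + eps / n_ent
      loss <- bce_from_logits(sc$scores, y)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
      }
      losses[bi] <- loss
      dscores <- (logistic(sc$scores) - y) / length(y)
      dsc <- score_queries_backward(dec, enc, qs$h[b], qs$r[b], sc, dscores)
      denc <- encode_backward(params, kg, enc, dsc$dE, dsc$dR)
      grads <- list(E = denc$E, R = denc$R, core = dsc$dcore)
      for (l in seq_along(denc$layers)) {
        for (nm in names(denc$layers[[l]])) {
          grads[[paste0("L", l, ".", nm)]] <- denc$layers[[l]][[nm]]
        }
      }
      upd <- adam_step(flat, grads, opt, config)
      flat <- upd$flat
      opt <- upd$state
    }
    mean_loss <- mean(losses)
    valid_mrr <- NA_real_
    if (epoch %% config$eval_every == 0L || epoch == config$epochs_max) {
      params <- param_unflatten(params, flat)
      valid_mrr <- quick_mrr(params, kg, eval_triples)
      if (valid_mrr > best$mrr) {
        best <- list(mrr = valid_mrr, epoch = epoch, flat = flat)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
      }
      if (config$verbose) {
        message(sprintf("epoch %d  loss %.4f  eval MRR %.4f", epoch,
                        mean_loss, valid_mrr))
      }
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean_loss,
                                       valid_mrr = valid_mrr)
    if (since_improve >= config$patience) break
  }

  structure(
    list(params = param_unflatten(params, best$flat),
         history = dplyr::bind_rows(history),
         best_epoch = best$epoch, best_mrr = best$mrr,
         config = config, kg = kg),
    class = "kge_model"
  )
}

# filtered MRR of a triple set under current parameters (both directions)
quick_mrr <- function(params, kg, triples) {
  rec <- rank_triples(params, kg, triples, tie_policy = "mean")
  mean(1 / rec$filtered_rank)
}

#' @export
print.kge_model <- function(x, ...) {
  cat("<kge_model>\n")
  cat(sprintf("  d = %d, encoder layers = %d, f_non = %s\n",
              ncol(x$params$E), length(x$params$layers), x$params$f_non))
  cat(sprintf("  trained %d epoch(s); best eval MRR %.4f at epoch %d\n",
              nrow(x$history), x$best_mrr, x$best_epoch))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history
#'
#' @param x A `kge_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, mean training `loss`, and `valid_mrr`
#'   (NA on epochs without an evaluation).
#' @export
tidy.kge_model <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x A `kge_model`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, depth, epochs run, best validation MRR.
#' @export
glance.kge_model <- function(x, ...) {
  tibble::tibble(
    hidden_dim = ncol(x$params$E),
    gnn_layers = length(x$params$layers),
    f_non = x$params$f_non,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_mrr = x$best_mrr,
    final_loss = x$history$loss[nrow(x$history)]
  )
}
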