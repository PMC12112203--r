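#' Generate candidate triples for graph completion
#'
#' Forms the cross product `heads x relation x tails` and removes every
#' triple already present in any split of the graph (candidates must be new
#' facts). Order is deterministic: lexicographic by head label, then tail
#' label.
#'
#' @param kg A `semlink_kg`.
#' @param heads,tails Character labels or integer indices of the candidate
#'   head and tail pools (e.g. all tea entities and all population
#'   entities).
#' @param relation Single relation label or base-relation index.
#' @return Tibble of candidates with label columns `head`, `relation`,
#'   `tail` and index columns `h`, `r`, `t`. Zero rows (with a warning) when
#'   the pools are fully covered by existing triples.
#' @export
kg_candidates <- function(kg, heads, relation, tails) {
  to_ent <- function(x) {
    if (is.character(x)) {
      i <- match(x, kg$entities)
      if (anyNA(i)) stop("unknown entity label(s): ",
                         paste(x[is.na(i)], collapse = ", "), call. = FALSE)
      i
    } else as.integer(x)
  }
  h <- sort(unique(to_ent(heads)))
  t <- sort(unique(to_ent(tails)))
  r <- if (is.character(relation)) match(relation, kg$relations) else as.integer(relation)
  if (is.na(r) || r < 1L || r > kg$n_rel_base) {
    stop("unknown or non-base relation", call. = FALSE)
  }
  stopifnot(length(h) > 0, length(t) > 0, length(r) == 1L)
  cand <- tidyr::expand_grid(h = h, t = t)
  cand <- cand[order(kg$entities[cand$h], kg$entities[cand$t]), ]
  existing <- dplyr::bind_rows(
    kg$train[kg$train$r == r, c("h", "t")],
    kg$valid[kg$valid$r == r, c("h", "t")],
    kg$test[kg$test$r == r, c("h", "t")]
  )
  cand <- dplyr::anti_join(cand, existing, by = c("h", "t"))
  if (nrow(cand) == 0L) {
    warning("all candidate triples already exist in the graph")
  }
  tibble::tibble(
    head = kg$entities[cand$h], relation = kg$relations[r],
    tail = kg$entities[cand$t],
    h = cand$h, r = r, t = cand$t
  )
}

#' Score candidate triples in both directions
#'
#' For each candidate `(h, r, t)`, computes the logistic probability of the
#' triple under both query directions: `head_score` from the head-prediction
#' query `(t, r_rev, ?)` read at `h`, and `tail_score` from the
#' tail-prediction query `(h, r, ?)` read at `t`. The final score is the
#' head score — with many more candidate heads than tails, the
#' head-prediction direction is the more discriminative read-out — but both
#' are reported so the choice is auditable.
#'
#' @param model A fitted `kge_model`.
#' @param candidates Tibble from [kg_candidates()].
#' @return `candidates` with `head_score`, `tail_score`, `final_score`
#'   columns appended. Deterministic (no dropout).
#' @export
kg_score_candidates <- function(model, candidates) {
  kg <- model$kg
  params <- model$params
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, head_score = numeric(0),
                         tail_score = numeric(0), final_score = numeric(0)))
  }
  enc <- encode(params, kg)
  dec <- decoder_slice(params)
  nr <- kg$n_rel_base
  n <- nrow(candidates)
  head_score <- tail_score <- numeric(n)
  step <- max(1L, floor(2e6 / length(kg$entities)))
  for (start in seq(1L, n, by = step)) {
    idx <- start:min(n, start + step - 1L)
    St <- score_queries(dec, enc, candidates$h[idx], candidates$r[idx])$scores
    Sh <- score_queries(dec, enc, candidates$t[idx], candidates$r[idx] + nr)$scores
    tail_score[idx] <- logistic(St[cbind(seq_along(idx), candidates$t[idx])])
    head_score[idx] <- logistic(Sh[cbind(seq_along(idx), candidates$h[idx])])
  }
  dplyr::mutate(candidates, head_score = head_score, tail_score = tail_score,
                final_score = head_score)
}

#' Accept candidates above a probability threshold
#'
#' Flags every scored candidate whose final score reaches the threshold
#' (default 0.9 — a deliberately high bar so that only high-confidence
#' predictions enter the graph).
#'
#' @param results Tibble with a `final_score` column
#'   ([kg_score_candidates()] output, or any tibble of scores).
#' @param threshold Acceptance cutoff in `[0, 1]` applied as
#'   `final_score >= threshold` (0 accepts everything; 1 accepts nothing for
#'   logistic scores).
#' @return `results` with a logical `accepted` column.
#' @export
apply_threshold <- function(results, threshold = 0.9) {
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  dplyr::mutate(results, accepted = .data$final_score >= threshold)
}

#' Histogram of completion scores
#'
#' Bins the head- and tail-direction probabilities of scored candidates —
#' the view used to judge whether the acceptance threshold separates
#' confident predictions from the rest.
#'
#' @param results Output of [kg_score_candidates()].
#' @param binwidth Bin width on the probability axis.
#' @return Long tibble with `direction` (head/tail), `bin` (left edge) and
#'   `count`.
#' @export
score_histogram <- function(results, binwidth = 0.05) {
  breaks <- seq(0, 1, by = binwidth)
  long <- tidyr::pivot_longer(
    results[, c("head_score", "tail_score")],
    dplyr::everything(), names_to = "direction", values_to = "p"
  )
  long$direction <- sub("_score$", "", long$direction)
  long$bin <- breaks[pmin(findInterval(long$p, breaks, rightmost.closed = TRUE),
                          length(breaks) - 1L)]
  dplyr::count(long, .data$direction, .data$bin, name = "count")
}

#' Complete a knowledge graph
#'
#' End-to-end completion: generate the unseen `heads x relation x tails`
#' candidates, score both directions with the trained model, and accept
#' those whose head-direction probability reaches the threshold.
#'
#' @inheritParams kg_candidates
#' @param model A fitted `kge_model` (its `$kg` is the graph completed).
#' @param threshold Acceptance cutoff.
#' @return Tibble of all candidates with scores and the `accepted` flag.
#' @export
kg_complete <- function(model, heads, relation, tails, threshold = 0.9) {
  cand <- kg_candidates(model$kg, heads, relation, tails)
  apply_threshold(kg_score_candidates(model, cand), threshold)
}

#' Original-plus-accepted triple set
#'
#' The augmented graph as a label triple table: every (non-reciprocal)
#' triple of every split, plus the accepted completions, deduplicated.
#' Write it with [write_triples()].
#'
#' @param kg A `semlink_kg`.
#' @param completions Output of [kg_complete()] / [apply_threshold()].
#' @return Tibble with `head`, `relation`, `tail`.
#' @export
kg_augmented_triples <- function(kg, completions) {
  tr <- kg$train
  if (kg$reciprocal) tr <- tr[tr$r <= kg$n_rel_base, ]
  lab <- function(df) tibble::tibble(head = kg$entities[df$h],
                                     relation = kg$relations[df$r],
                                     tail = kg$entities[df$t])
  out <- dplyr::bind_rows(lab(tr), lab(kg$valid), lab(kg$test),
                          completions[completions$accepted,
                                      c("head", "relation", "tail")])
  dplyr::distinct(out)
}
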