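#' Filtered rank of the true candidate
#'
#' Ranks the true candidate within a score vector under the filtered
#' protocol: every other known-true candidate is removed from the
#' competition first. Ties are handled by policy: `"mean"` (default) gives
#' half-credit per tied competitor, `"optimistic"` ranks the true candidate
#' above ties, `"pessimistic"` below.
#'
#' @param scores Numeric score vector over all candidates.
#' @param true_index Index of the true candidate.
#' @param known_true Integer indices of all known-true candidates for this
#'   query (the filter set; may or may not include `true_index`).
#' @param tie_policy One of `"mean"`, `"optimistic"`, `"pessimistic"`.
#' @return One-row tibble with `raw_rank`, `filtered_rank` and `score` (the
#'   true candidate's score). `filtered_rank <= raw_rank` always.
#' @export
filtered_rank <- function(scores, true_index, known_true = integer(),
                          tie_policy = c("mean", "optimistic", "pessimistic")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(true_index >= 1L, true_index <= length(scores))
  s_true <- scores[true_index]
  excl <- setdiff(known_true, true_index)
  rank_of <- function(s) {
    greater <- sum(s > s_true)
    ties <- sum(s == s_true)
    greater + switch(tie_policy,
                     mean = ties / 2,
                     optimistic = 0,
                     pessimistic = ties) + 1
  }
  others <- scores[-true_index]
  raw <- rank_of(others)
  filt <- if (length(excl)) rank_of(scores[-c(true_index, excl)]) else raw
  tibble::tibble(raw_rank = raw, filtered_rank = filt, score = s_true)
}

rank_vector <- function(records) {
  if (is.data.frame(records)) records$filtered_rank else as.numeric(records)
}

#' Hits@k
#'
#' Fraction of queries whose true candidate ranks within the top k:
#' `(1/|N|) sum I(rank <= k)`.
#'
#' @param records Numeric rank vector, or a records tibble with a
#'   `filtered_rank` column.
#' @param k Cutoff.
#' @return Fraction in `[0, 1]`.
#' @export
hits_at_k <- function(records, k) {
  r <- rank_vector(records)
  if (length(r) == 0L) stop("no rank records", call. = FALSE)
  mean(r <= k)
}

#' Mean rank
#'
#' Arithmetic mean of the ranks over all evaluated queries.
#'
#' @inheritParams hits_at_k
#' @return Mean rank (>= 1).
#' @export
mean_rank <- function(records) {
  r <- rank_vector(records)
  if (length(r) == 0L) stop("no rank records", call. = FALSE)
  mean(r)
}

#' Mean reciprocal rank
#'
#' Mean of `1 / rank` over all evaluated queries.
#'
#' @inheritParams hits_at_k
#' @return MRR in `(0, 1]`.
#' @export
mrr <- function(records) {
  r <- rank_vector(records)
  if (length(r) == 0L) stop("no rank records", call. = FALSE)
  mean(1 / r)
}

# score and rank a triple table in both directions (tail query (h, r, ?) and
# head query via the reciprocal (t, r + n_rel_base, ?)); deterministic.
rank_triples <- function(params, kg, triples, tie_policy = "mean",
                         encoded = NULL) {
  enc <- encoded %||% encode(params, kg)
  nr <- kg$n_rel_base
  qh <- c(triples$h, triples$t)
  qr <- c(triples$r, triples$r + nr)
  truth <- c(triples$t, triples$h)
  dir <- rep(c("tail", "head"), each = nrow(triples))
  dec <- decoder_slice(params)
  n <- length(qh)
  raw <- filt <- sc_true <- numeric(n)
  # batch the score matrix to bound memory
  step <- max(1L, floor(2e6 / length(kg$entities)))
  for (start in seq(1L, n, by = step)) {
    idx <- start:min(n, start + step - 1L)
    S <- score_queries(dec, enc, qh[idx], qr[idx], training = FALSE)$scores
    for (j in seq_along(idx)) {
      i <- idx[j]
      known <- kg_known_tails(kg, qh[i], qr[i])
      rec <- filtered_rank(S[j, ], truth[i], known, tie_policy)
      raw[i] <- rec$raw_rank; filt[i] <- rec$filtered_rank
      sc_true[i] <- rec$score
    }
  }
  tibble::tibble(h = rep(triples$h, 2L),
                 r = rep(triples$r, 2L), t = rep(triples$t, 2L),
                 direction = dir, raw_rank = raw, filtered_rank = filt,
                 score = sc_true)
}

#' Evaluate a model with the filtered ranking protocol
#'
#' Scores every triple of a split in both directions — the tail query
#' `(h, r, ?)` and the head query expressed through the reciprocal relation
#' `(t, r_rev, ?)` — and aggregates filtered MRR, MR and Hits@1/3/10 over
#' the pooled `2 x |split|` rank records. Evaluation is deterministic (no
#' dropout).
#'
#' @param model A fitted `kge_model` (or a list with `params` and `kg`).
#' @param split `"test"`, `"valid"` or `"train"`; or a tibble of `(h, r, t)`
#'   index triples.
#' @param tie_policy Tie handling for [filtered_rank()].
#' @return An object of class `kge_eval` with `records` (per-query tibble,
#'   including raw ranks for diagnostics) and `metrics` (one-row tibble).
#'   Use [tidy()] / [glance()] to extract them.
#' @export
kge_evaluate <- function(model, split = "test", tie_policy = "mean") {
  kg <- model$kg
  triples <- if (is.character(split)) kg[[match.arg(split, c("test", "valid", "train"))]] else split
  if (NROW(triples) == 0L) stop("no evaluable triples in split", call. = FALSE)
  records <- rank_triples(model$params, kg, triples, tie_policy)
  metrics <- tibble::tibble(
    mrr = mrr(records), mr = mean_rank(records),
    hits1 = hits_at_k(records, 1), hits3 = hits_at_k(records, 3),
    hits10 = hits_at_k(records, 10),
    raw_mrr = mean(1 / records$raw_rank),
    n_queries = nrow(records)
  )
  structure(list(records = records, metrics = metrics,
                 tie_policy = tie_policy),
            class = "kge_eval")
}

#' @export
print.kge_eval <- function(x, ...) {
  m <- x$metrics
  cat("<kge_eval> filtered ranking over", m$n_queries, "queries\n")
  cat(sprintf("  MRR %.4f  MR %.1f  H@1 %.4f  H@3 %.4f  H@10 %.4f\n",
              m$mrr, m$mr, m$hits1, m$hits3, m$hits10))
  invisible(x)
}

#' Per-query rank records
#'
#' @param x A `kge_eval`.
#' @param ... Unused.
#' @return Tibble with one row per (triple, direction): raw and filtered
#'   rank and the true candidate's score.
#' @export
tidy.kge_eval <- function(x, ...) x$records

#' Aggregated ranking metrics
#'
#' @param x A `kge_eval`.
#' @param ... Unused.
#' @return One-row tibble: `mrr`, `mr`, `hits1`, `hits3`, `hits10`,
#'   `raw_mrr`, `n_queries`.
#' @export
glance.kge_eval <- function(x, ...) x$metrics
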