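#' Synthetic knowledge-graph configuration
#'
#' Describes a seeded synthetic graph whose structure exercises the three
#' semantic-evidence signals the encoder aggregates:
#' \describe{
#'   \item{relation-determined}{some relations map any head to a small set of
#'     designated tails, so the relation alone predicts the answer;}
#'   \item{compositional}{two-hop chains `(a, r_a, b)`, `(b, r_b, c)` imply a
#'     direct triple `(a, r_implies, c)`, some of which are held out for
#'     valid/test;}
#'   \item{near-duplicate}{pairs of triples share `(head, relation)` with
#'     related tails, so similar trained queries support each other;}
#'   \item{noise}{uniform random triples.}
#' }
#' The default scale (1064 entities, 28 relations, 6698 triples, roughly
#' 80/10/10 split) mirrors a real curated tea-and-health graph with 330 tea
#' varieties and 12 target-population entities; head/tail pools of matching
#' proportion are labelled `tea_*` and `pop_*` and connected by the
#' `suitable_for` relation, so completion studies have designated pools.
#'
#' @param n_entities,n_relations,n_triples Graph scale (relations >= 5).
#' @param motif_mix Named fractions for `relation_determined`,
#'   `compositional`, `near_duplicate`, `noise`; must sum to 1.
#' @param n_head_pool,n_tail_pool Sizes of the designated completion pools;
#'   defaults scale with `n_entities` (31% and 1.1%, floors 3 and 2).
#' @param split_frac Train/valid/test fractions (sum to 1).
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output files.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_entities = 1064, n_relations = 28,
                         n_triples = 6698,
                         motif_mix = c(relation_determined = 0.4,
                                       compositional = 0.3,
                                       near_duplicate = 0.2,
                                       noise = 0.1),
                         n_head_pool = NULL, n_tail_pool = NULL,
                         split_frac = c(train = 0.8, valid = 0.1, test = 0.1),
                         seed = 1234) {
  stopifnot(n_entities >= 10, n_relations >= 5, n_triples >= 20,
            abs(sum(motif_mix) - 1) < 1e-8, abs(sum(split_frac) - 1) < 1e-8,
            all(motif_mix >= 0), all(split_frac > 0))
  req <- c("relation_determined", "compositional", "near_duplicate", "noise")
  stopifnot(setequal(names(motif_mix), req))
  n_head_pool <- n_head_pool %||% max(3L, round(0.31 * n_entities))
  n_tail_pool <- n_tail_pool %||% max(2L, round(0.0113 * n_entities))
  stopifnot(n_head_pool + n_tail_pool <= n_entities)
  structure(list(n_entities = n_entities, n_relations = n_relations,
                 n_triples = n_triples, motif_mix = motif_mix[req],
                 n_head_pool = n_head_pool, n_tail_pool = n_tail_pool,
                 split_frac = split_frac, seed = seed),
            class = "synth_config")
}

pad_label <- function(prefix, i, n) {
  sprintf(paste0(prefix, "_%0", nchar(as.character(n)), "d"), i)
}

# sample k unique (h, r, t) rows from a generator function, avoiding `seen`
sample_unique <- function(k, gen, seen, max_iter = 60L) {
  out <- character(0)
  for (iter in seq_len(max_iter)) {
    need <- k - length(out)
    if (need <= 0L) break
    cand <- gen(max(need * 2L, 16L))
    key <- paste(cand$h, cand$r, cand$t)
    keep <- !(key %in% seen) & !duplicated(key)
    out <- c(out, key[keep][seq_len(min(need, sum(keep)))])
    seen <- c(seen, key[keep])
  }
  out
}

key_to_df <- function(keys) {
  m <- matrix(as.integer(unlist(strsplit(keys, " ", fixed = TRUE))),
              ncol = 3L, byrow = TRUE)
  tibble::tibble(h = m[, 1L], r = m[, 2L], t = m[, 3L])
}

#' Generate a synthetic knowledge graph
#'
#' Draws the motif-structured triple set described by the config, assigns
#' train/valid/test splits so that every valid/test entity and relation is
#' seen in training and no held-out triple is the reciprocal duplicate of a
#' retained one, and (optionally) writes the dataset directory:
#' `train.txt` / `valid.txt` / `test.txt`, a `motifs.tsv` sidecar labelling
#' each triple's motif and split, and the config as `config.dcf`.
#'
#' Held-out triples are preferentially the implied targets of compositional
#' chains (the structure multi-hop aggregation should recover), topped up
#' with other motifs.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory.
#' @return A list of class `semlink_sim`: `kg` (a built `semlink_kg`),
#'   `triples` (label tibble with `motif` and `split` columns), `config`.
#' @export
kg_simulate <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_ent <- config$n_entities
  n_rel <- config$n_relations
  ents <- c(pad_label("tea", seq_len(config$n_head_pool), config$n_head_pool),
            pad_label("pop", seq_len(config$n_tail_pool), config$n_tail_pool),
            pad_label("ent", seq_len(n_ent - config$n_head_pool - config$n_tail_pool),
                      n_ent))
  head_pool <- seq_len(config$n_head_pool)
  tail_pool <- config$n_head_pool + seq_len(config$n_tail_pool)
  # relation roles: 1 completion, 3 chain, remainder cycles det/nd/generic
  roles <- c("suitable", "chain_a", "chain_b", "chain_implies",
             rep_len(c("det", "nd", "gen"), n_rel - 4L))
  rels <- character(n_rel)
  rels[1:4] <- c("suitable_for", "precedes", "follows", "implies")
  for (role in c("det", "nd", "gen")) {
    ix <- which(roles == role)
    if (length(ix)) {
      rels[ix] <- pad_label(switch(role, det = "has_attr", nd = "related_to",
                                   gen = "rel"), seq_along(ix), length(ix))
    }
  }
  det_rels <- which(roles == "det")
  other_rels <- which(roles %in% c("nd", "gen"))
  if (!length(other_rels)) other_rels <- det_rels

  counts <- round(config$motif_mix * config$n_triples)
  n_chain <- floor(counts[["compositional"]] / 3)
  counts[["compositional"]] <- 3L * n_chain
  counts[["noise"]] <- config$n_triples - counts[["relation_determined"]] -
    counts[["compositional"]] - counts[["near_duplicate"]]
  if (counts[["noise"]] < 0) stop("infeasible motif counts", call. = FALSE)

  # capacity: relation-determined triples live on suitable_for + det relations
  det_tails <- lapply(det_rels, function(r) sample.int(n_ent, 3L))
  cap_sf <- config$n_head_pool * config$n_tail_pool
  cap_det <- length(det_rels) * n_ent * 3L
  n_rd <- counts[["relation_determined"]]
  n_sf <- min(max(n_rd - cap_det, ceiling(n_rd / 2)), floor(0.8 * cap_sf))
  n_det <- n_rd - n_sf
  if (n_det > cap_det || n_sf > cap_sf) {
    stop("infeasible motif counts: relation-determined capacity exceeded",
         call. = FALSE)
  }

  seen <- character(0)
  motif_of <- list()

  gen_sf <- function(k) tibble::tibble(h = sample(head_pool, k, replace = TRUE),
                                       r = 1L,
                                       t = sample(tail_pool, k, replace = TRUE))
  gen_det <- function(k) {
    ri <- sample.int(length(det_rels), k, replace = TRUE)
    tibble::tibble(h = sample.int(n_ent, k, replace = TRUE),
                   r = det_rels[ri],
                   t = vapply(ri, function(i) sample(det_tails[[i]], 1L), 1L))
  }
  k_sf <- sample_unique(n_sf, gen_sf, seen); seen <- c(seen, k_sf)
  k_det <- if (n_det > 0) sample_unique(n_det, gen_det, seen) else character(0)
  seen <- c(seen, k_det)
  if (length(k_sf) + length(k_det) < n_rd) {
    stop("infeasible motif counts: could not place relation-determined triples",
         call. = FALSE)
  }
  motif_of$relation_determined <- c(k_sf, k_det)

  # compositional chains a -(2)-> b -(3)-> c with implied (a, 4, c)
  chains <- tibble::tibble(a = sample.int(n_ent, 4L * n_chain, replace = TRUE),
                           b = sample.int(n_ent, 4L * n_chain, replace = TRUE),
                           c = sample.int(n_ent, 4L * n_chain, replace = TRUE))
  chains <- chains[chains$a != chains$b & chains$b != chains$c & chains$a != chains$c, ]
  chains <- chains[!duplicated(chains), ]
  keys_of <- function(ch) {
    if (nrow(ch) == 0L) {
      return(list(ab = character(0), bc = character(0), ac = character(0)))
    }
    list(ab = paste(ch$a, 2L, ch$b), bc = paste(ch$b, 3L, ch$c),
         ac = paste(ch$a, 4L, ch$c))
  }
  kk <- keys_of(chains)
  ok <- !(kk$ab %in% seen) & !(kk$bc %in% seen) & !(kk$ac %in% seen) &
    !duplicated(c(kk$ab)) & !duplicated(kk$bc) & !duplicated(kk$ac)
  chains <- chains[ok, ][seq_len(min(n_chain, sum(ok))), ]
  if (nrow(chains) < n_chain) {
    stop("infeasible motif counts: not enough distinct compositional chains",
         call. = FALSE)
  }
  kk <- keys_of(chains)
  seen <- c(seen, kk$ab, kk$bc, kk$ac)
  motif_of$compositional <- c(kk$ab, kk$bc)
  motif_of$compositional_implied <- kk$ac

  # near-duplicate pairs share (head, relation), tails adjacent in index
  n_nd_pairs <- floor(counts[["near_duplicate"]] / 2)
  gen_nd_pair <- function(k) {
    h <- sample.int(n_ent, k, replace = TRUE)
    r <- other_rels[sample.int(length(other_rels), k, replace = TRUE)]
    t1 <- sample.int(n_ent - 1L, k, replace = TRUE)
    tibble::tibble(h = rep(h, each = 2L), r = rep(r, each = 2L),
                   t = as.integer(rbind(t1, t1 + 1L)))
  }
  k_nd <- sample_unique(2L * n_nd_pairs, gen_nd_pair, seen)
  seen <- c(seen, k_nd)
  motif_of$near_duplicate <- k_nd
  leftover_nd <- counts[["near_duplicate"]] - length(k_nd)

  # noise stays off the typed relations (suitable_for and the
  # relation-determined set) so their structure remains clean
  noise_rels <- setdiff(seq_len(n_rel), c(1L, det_rels))
  if (!length(noise_rels)) noise_rels <- setdiff(seq_len(n_rel), 1L)
  n_noise <- counts[["noise"]] + leftover_nd

  # coverage pass: every entity and relation must occur in >= 1 triple
  placed <- key_to_df(unlist(motif_of, use.names = FALSE))
  missing_e <- setdiff(seq_len(n_ent), unique(c(placed$h, placed$t)))
  missing_r <- setdiff(seq_len(n_rel), unique(placed$r))
  k_cover <- character(0)
  if (length(missing_e) || length(missing_r)) {
    n_cover <- max(ceiling(length(missing_e) / 2), length(missing_r))
    if (n_cover > n_noise) {
      stop("infeasible motif counts: noise budget too small to cover all ",
           "entities and relations", call. = FALSE)
    }
    slots_h <- missing_e[seq_len(n_cover) * 2L - 1L]
    slots_t <- missing_e[seq_len(n_cover) * 2L]
    slots_h[is.na(slots_h)] <- sample.int(n_ent, sum(is.na(slots_h)), replace = TRUE)
    slots_t[is.na(slots_t)] <- sample.int(n_ent, sum(is.na(slots_t)), replace = TRUE)
    slots_r <- c(missing_r,
                 noise_rels[sample.int(length(noise_rels),
                                       n_cover - length(missing_r),
                                       replace = TRUE)])
    k_cover <- paste(slots_h, slots_r, slots_t)
    seen <- c(seen, k_cover)
  }

  gen_noise <- function(k) tibble::tibble(
    h = sample.int(n_ent, k, replace = TRUE),
    r = noise_rels[sample.int(length(noise_rels), k, replace = TRUE)],
    t = sample.int(n_ent, k, replace = TRUE)
  )
  k_noise <- sample_unique(n_noise - length(k_cover), gen_noise, seen)
  seen <- c(seen, k_noise)
  motif_of$noise <- c(k_cover, k_noise)

  all_keys <- unlist(motif_of, use.names = FALSE)
  if (length(all_keys) != config$n_triples) {
    stop("infeasible motif counts: generated ", length(all_keys),
         " of ", config$n_triples, " requested triples", call. = FALSE)
  }
  triples <- key_to_df(all_keys)
  triples$motif <- rep(sub("_implied$", "", names(motif_of)), lengths(motif_of))
  implied <- rep(grepl("implied", names(motif_of)), lengths(motif_of))

  # ---- split assignment -----------------------------------------------------
  n <- nrow(triples)
  n_valid <- round(config$split_frac[["valid"]] * n)
  n_test <- round(config$split_frac[["test"]] * n)
  rev_key <- paste(triples$t, triples$r, triples$h)
  has_reverse <- rev_key %in% all_keys
  ent_ct <- tabulate(c(triples$h, triples$t), n_ent)
  rel_ct <- tabulate(triples$r, n_rel)
  cand_order <- c(sample(which(implied)),
                  sample(which(!implied & triples$motif != "compositional")))
  heldout <- integer(0)
  for (i in cand_order) {
    if (length(heldout) >= n_valid + n_test) break
    if (has_reverse[i]) next
    h <- triples$h[i]; t <- triples$t[i]; r <- triples$r[i]
    need <- if (h == t) c(ent_ct[h] >= 3L) else c(ent_ct[h] >= 2L, ent_ct[t] >= 2L)
    if (all(need) && rel_ct[r] >= 2L) {
      heldout <- c(heldout, i)
      ent_ct[h] <- ent_ct[h] - 1L; ent_ct[t] <- ent_ct[t] - 1L
      rel_ct[r] <- rel_ct[r] - 1L
    }
  }
  if (length(heldout) < n_valid + n_test) {
    stop("could not hold out enough triples without orphaning entities",
         call. = FALSE)
  }
  heldout <- sample(heldout)
  split <- rep("train", n)
  split[heldout[seq_len(n_valid)]] <- "valid"
  split[heldout[n_valid + seq_len(n_test)]] <- "test"
  triples$split <- split

  lab <- tibble::tibble(head = ents[triples$h], relation = rels[triples$r],
                        tail = ents[triples$t], motif = triples$motif,
                        split = triples$split)
  kg <- kg_build(lab[lab$split == "train", 1:3],
                 lab[lab$split == "valid", 1:3],
                 lab[lab$split == "test", 1:3], quiet = TRUE)
  sim <- structure(list(kg = kg, triples = lab, config = config),
                   class = "semlink_sim")
  if (!is.null(dir)) {
    kg_write(kg, dir)
    readr::write_tsv(lab, file.path(dir, "motifs.tsv"))
    write.dcf(data.frame(
      n_entities = config$n_entities, n_relations = config$n_relations,
      n_triples = config$n_triples,
      motif_mix = paste(sprintf("%s=%g", names(config$motif_mix),
                                config$motif_mix), collapse = ","),
      n_head_pool = config$n_head_pool, n_tail_pool = config$n_tail_pool,
      split_frac = paste(sprintf("%s=%g", names(config$split_frac),
                                 config$split_frac), collapse = ","),
      seed = config$seed
    ), file.path(dir, "config.dcf"))
  }
  sim
}

#' Deterministic 8-entity fixture graph
#'
#' A hard-coded 8-entity, 2-relation, 12-triple graph used for exact
#' memorisation and oracle tests. All triples are in the train split:
#'
#' \preformatted{
#' a likes b    b likes c    c likes d    d likes a
#' a likes e    b likes f    c likes g    d likes h
#' e part_of a  f part_of b  g part_of c  h part_of d
#' }
#'
#' @return An (unaugmented) `semlink_kg`.
#' @export
kg_tiny <- function() {
  tr <- tibble::tribble(
    ~head, ~relation, ~tail,
    "a", "likes", "b",
    "b", "likes", "c",
    "c", "likes", "d",
    "d", "likes", "a",
    "a", "likes", "e",
    "b", "likes", "f",
    "c", "likes", "g",
    "d", "likes", "h",
    "e", "part_of", "a",
    "f", "part_of", "b",
    "g", "part_of", "c",
    "h", "part_of", "d"
  )
  kg_build(tr, quiet = TRUE)
}
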