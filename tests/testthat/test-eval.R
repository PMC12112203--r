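test_that("filtered ranking counts strictly better and tied competitors", {
  # four candidates, truth is the third best; the best one is a known true
  rec <- filtered_rank(c(0.9, 0.8, 0.7, 0.6), true_index = 3, known_true = 1)
  expect_equal(rec$raw_rank, 3)
  expect_equal(rec$filtered_rank, 2)
  expect_equal(rec$score, 0.7)

  # unique maximum ranks first under any policy
  for (pol in c("mean", "optimistic", "pessimistic")) {
    expect_equal(filtered_rank(c(1, 5, 2), 2, tie_policy = pol)$filtered_rank, 1)
  }

  # complete tie: mean policy gives the average over random tie-breaks
  n <- 7
  expect_equal(filtered_rank(rep(2, n), 4, tie_policy = "mean")$filtered_rank,
               (n + 1) / 2)
  expect_equal(filtered_rank(rep(2, n), 4, tie_policy = "optimistic")$filtered_rank, 1)
  expect_equal(filtered_rank(rep(2, n), 4, tie_policy = "pessimistic")$filtered_rank, n)
})

test_that("rank metrics have their closed forms", {
  ranks <- c(1, 2, 4)
  expect_equal(mrr(ranks), (1 + 1 / 2 + 1 / 4) / 3)
  expect_equal(mean_rank(ranks), 7 / 3)
  expect_equal(hits_at_k(ranks, 1), 1 / 3)
  expect_equal(hits_at_k(c(1, 10, 11), 10), 2 / 3)
  expect_equal(hits_at_k(rep(1, 5), 3), 1)
  expect_equal(mrr(rep(1, 5)), 1)
  expect_error(mrr(numeric()), "no rank")
  # sampling check: uniform ranks on 1..100 have mean near 50.5
  withr::local_seed(81)
  expect_lt(abs(mean_rank(sample.int(100, 1000, replace = TRUE)) - 50.5), 3)
})

test_that("hits is monotone in k and metrics ignore record order", {
  withr::local_seed(82)
  ranks <- sample.int(50, 200, replace = TRUE)
  ks <- c(1, 3, 10, 50)
  hs <- vapply(ks, function(k) hits_at_k(ranks, k), numeric(1))
  expect_true(all(diff(hs) >= 0))
  expect_equal(hs[length(hs)], 1)
  perm <- sample(length(ranks))
  expect_equal(mrr(ranks), mrr(ranks[perm]))
  expect_equal(mean_rank(ranks), mean_rank(ranks[perm]))
})

test_that("filtered rank never exceeds raw rank", {
  withr::local_seed(83)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    scores <- rnorm(n)
    truth <- sample.int(n, 1)
    known <- sample.int(n, sample.int(4, 1))
    rec <- filtered_rank(scores, truth, known)
    expect_lte(rec$filtered_rank, rec$raw_rank)
    expect_gte(rec$filtered_rank, 1)
  }
})

test_that("a perfect scorer attains filtered MRR, MR and H@1 of exactly 1", {
  # one-hot embeddings turn the core tensor into a freely chosen score
  # table: core[h, r, t] = 1 exactly on the true (augmented) triples
  kg <- kg_add_reciprocals(kg_tiny())
  d <- length(kg$entities)
  p <- random_params(kg, d, L = 0, f_non = "identity", seed = 1)
  p$E <- diag(d)
  p$R <- diag(d)[seq_along(kg$relations), , drop = FALSE]
  p$core[] <- 0
  for (i in seq_len(nrow(kg$train))) {
    p$core[kg$train$h[i], kg$train$r[i], kg$train$t[i]] <- 1
  }
  model <- structure(list(params = p, kg = kg), class = "kge_model")
  probe <- kg$train[kg$train$r <= kg$n_rel_base, ]
  ev <- kge_evaluate(model, split = probe)
  expect_equal(ev$metrics$mrr, 1)
  expect_equal(ev$metrics$mr, 1)
  expect_equal(ev$metrics$hits1, 1)
})

test_that("pooled metrics average the two directions when counts match", {
  withr::local_seed(84)
  recs <- tibble::tibble(
    direction = rep(c("tail", "head"), each = 25),
    filtered_rank = sample.int(40, 50, replace = TRUE)
  )
  pooled <- mrr(recs)
  by_dir <- tapply(recs$filtered_rank, recs$direction, function(r) mean(1 / r))
  expect_equal(pooled, mean(by_dir))
})

test_that("evaluation pools both directions and filtering can only help", {
  sim <- kg_simulate(synth_config(n_entities = 50, n_relations = 5,
                                  n_triples = 260, seed = 9))
  kg <- kg_add_reciprocals(sim$kg)
  p <- random_params(kg, 8, L = 1, seed = 3)
  model <- structure(list(params = p, kg = kg), class = "kge_model")
  ev <- kge_evaluate(model, split = "test")
  expect_equal(nrow(ev$records), 2L * nrow(kg$test))
  expect_setequal(unique(ev$records$direction), c("tail", "head"))
  expect_true(all(ev$records$filtered_rank <= ev$records$raw_rank))
  expect_gte(ev$metrics$mrr, ev$metrics$raw_mrr)
  expect_true(ev$metrics$hits1 <= ev$metrics$hits3,
              ev$metrics$hits3 <= ev$metrics$hits10)
  expect_equal(glance(ev), ev$metrics)
  # a random model ranks the truth roughly uniformly: MRR near the harmonic
  # expectation H_n / n, far below a trained model's
  n <- length(kg$entities)
  expect_lt(ev$metrics$mrr, 5 * sum(1 / seq_len(n)) / n)
})
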