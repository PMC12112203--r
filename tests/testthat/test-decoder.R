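test_that("mode-product chain contracts head and relation against the core", {
  expect_equal(mode_product_chain(array(2, c(1, 1, 1)), 3, 0.5), 3)
  expect_equal(mode_product_chain(array(0, c(3, 3, 3)), rnorm(3), rnorm(3)),
               rep(0, 3))
  withr::local_seed(4)
  d <- 4
  core <- array(rnorm(d^3), c(d, d, d))
  e_s <- rnorm(d); r <- rnorm(d)
  ref <- numeric(d)
  for (k in seq_len(d)) {
    for (i in seq_len(d)) for (j in seq_len(d)) {
      ref[k] <- ref[k] + core[i, j, k] * e_s[i] * r[j]
    }
  }
  expect_equal(mode_product_chain(core, e_s, r), ref, tolerance = 1e-10)
  expect_error(mode_product_chain(core, rnorm(3), r))
})

test_that("linear Tucker scoring matches the per-entity trilinear loop", {
  core1 <- array(2, c(1, 1, 1))
  expect_equal(tucker_score(3, 0.5, rbind(1, -1), core1), c(3, -3))
  expect_equal(tucker_score(rep(0, 3), rnorm(3), matrix(rnorm(15), 5),
               array(rnorm(27), c(3, 3, 3))), rep(0, 5))
  withr::local_seed(11)
  d <- 3
  core <- array(rnorm(d^3), c(d, d, d))
  e_s <- rnorm(d); r <- rnorm(d); E <- matrix(rnorm(10 * d), 10)
  expect_equal(tucker_score(e_s, r, E, core), ref_tucker_all(core, e_s, r, E),
               tolerance = 1e-10)
})

test_that("the nonlinearity wraps the contraction before the tail read-out", {
  withr::local_seed(12)
  d <- 2
  core <- array(rnorm(d^3), c(d, d, d))
  e_s <- rnorm(d); r <- rnorm(d); E <- matrix(rnorm(8 * d), 8)
  pid <- decoder_params(core, f_non = "identity")
  expect_identical(ftucker_score(e_s, r, E, pid), tucker_score(e_s, r, E, core))

  prelu <- decoder_params(array(1, c(1, 1, 1)), f_non = "relu")
  expect_equal(ftucker_score(-2, 1, rbind(5), prelu), 0)

  plk <- decoder_params(core, f_non = "leakyrelu")
  lk <- activation("leakyrelu")$fn
  expect_equal(ftucker_score(e_s, r, E, plk),
               ref_tucker_all(core, e_s, r, E, f = lk), tolerance = 1e-10)
})

test_that("scores are multilinear when the nonlinearity is off", {
  withr::local_seed(13)
  d <- 3
  core <- array(rnorm(d^3), c(d, d, d))
  e_s <- rnorm(d); r <- rnorm(d); E <- matrix(rnorm(6 * d), 6)
  s <- tucker_score(e_s, r, E, core)
  expect_equal(tucker_score(2.5 * e_s, r, E, core), 2.5 * s, tolerance = 1e-12)
  expect_equal(tucker_score(e_s, -3 * r, E, core), -3 * s, tolerance = 1e-12)
  e2 <- rnorm(d)
  expect_equal(tucker_score(e_s + e2, r, E, core),
               s + tucker_score(e2, r, E, core), tolerance = 1e-10)
})

test_that("full-model scoring reduces to plain Tucker with L=0 and identity", {
  kg <- random_kg(9, 3, 22, seed = 31)
  p <- random_params(kg, 3, L = 0, f_non = "identity", seed = 2)
  sc <- gnn_ftucker_score(2, 1, p, kg)
  expect_identical(sc$score, tucker_score(p$E[2, ], p$R[1, ], p$E, p$core))
  expect_equal(sc$probability, 1 / (1 + exp(-sc$score)))
})

test_that("score of zero maps to probability one half", {
  kg <- random_kg(5, 2, 8, seed = 3)
  p <- random_params(kg, 2, L = 0, f_non = "identity", seed = 5)
  p$core[] <- 0
  sc <- gnn_ftucker_score(1, 1, p, kg)
  expect_equal(sc$probability, rep(0.5, length(kg$entities)))
})

test_that("full-model scoring matches an end-to-end reference loop", {
  kg <- random_kg(7, 2, 16, seed = 17)
  p <- random_params(kg, 2, L = 1, seed = 8)
  ref <- ref_encode(p, kg)
  lk <- activation("leakyrelu")$fn
  want <- ref_tucker_all(p$core, ref$entity_out[3, ], ref$relation_out[2, ],
                         ref$entity_out, f = lk)
  expect_equal(gnn_ftucker_score(3, 2, p, kg)$score, want, tolerance = 1e-8)
  expect_error(gnn_ftucker_score(99, 1, p, kg), "out of range")
})

test_that("evaluation-mode scoring is deterministic", {
  kg <- random_kg(8, 2, 18, seed = 23)
  p <- random_params(kg, 3, L = 1, seed = 4)
  p$input_dropout <- 0.3; p$hidden_dropout1 <- 0.2; p$hidden_dropout2 <- 0.2
  s1 <- gnn_ftucker_score(1, 1, p, kg)
  s2 <- gnn_ftucker_score(1, 1, p, kg)
  expect_identical(s1, s2)
  # batched evaluation path is also dropout-free
  enc <- encode(p, kg)
  dec <- semlink:::decoder_slice(p)
  b1 <- semlink:::score_queries(dec, enc, c(1, 2), c(1, 2))$scores
  b2 <- semlink:::score_queries(dec, enc, c(1, 2), c(1, 2))$scores
  expect_identical(b1, b2)
})

test_that("batched scorer agrees with the single-query scorer", {
  kg <- random_kg(10, 3, 30, seed = 41)
  p <- random_params(kg, 4, L = 2, seed = 6)
  enc <- encode(p, kg)
  dec <- semlink:::decoder_slice(p)
  S <- semlink:::score_queries(dec, enc, c(1, 4, 7), c(2, 1, 5))$scores
  for (b in 1:3) {
    expect_equal(S[b, ], gnn_ftucker_score(c(1, 4, 7)[b], c(2, 1, 5)[b],
                                           p, kg, encoded = enc)$score,
                 tolerance = 1e-10)
  }
})
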