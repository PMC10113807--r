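test_that("embedding enumerates lagged coordinates with next-step targets", {
  emb <- embed_series(c(1, 2, 3, 4, 5), E = 2, tau = 1)
  expect_equal(nrow(emb$library), 3L)
  expect_equal(emb$library, rbind(c(2, 1), c(3, 2), c(4, 3)))
  expect_equal(emb$targets, c(3, 4, 5))

  emb1 <- embed_series(c(1, 2, 3, 4, 5), E = 1, tau = 1)
  expect_equal(drop(emb1$library), c(1, 2, 3, 4))
  expect_equal(emb1$targets, c(2, 3, 4, 5))

  # E = 3, tau = 2 on a 10-point series: 10 - 1 - 4 = 5 rows, checked
  # against hand index arithmetic
  s <- c(11, 12, 13, 14, 15, 16, 17, 18, 19, 20)
  emb32 <- embed_series(s, E = 3, tau = 2)
  expect_equal(nrow(emb32$library), 5L)
  for (row in seq_len(5)) {
    t <- emb32$time_labels[row]
    expect_equal(emb32$library[row, ], s[c(t, t - 2, t - 4)])
    expect_equal(emb32$targets[row], s[t + 1])
  }
  # coordinate 1 reproduces the series segment exactly
  expect_equal(emb32$library[, 1], s[5:9])
})

test_that("embedding rejects bad input", {
  expect_error(embed_series(1:3, E = 3, tau = 1), "insufficient length")
  expect_error(embed_series(c(1, NA, 3, 4), E = 2), "invalid series")
  expect_error(embed_series(c(1, Inf, 3, 4), E = 2), "invalid series")
  expect_error(embed_series(1:10, E = 0), "E must be")
})

test_that("knn_search matches exhaustive search with tie-break by time label", {
  set.seed(1)
  x <- logistic_series(60)
  emb <- embed_series(x, E = 3, tau = 1)
  for (rep in 1:50) {
    q <- stats::runif(3)
    k <- sample(1:5, 1)
    excl <- sample(nrow(emb$library), sample(0:3, 1))
    nn <- knn_search(emb, q, k, exclude = excl)
    # brute force
    d <- sqrt(colSums((t(emb$library) - q)^2))
    d[excl] <- Inf
    ord <- order(d, emb$time_labels)[seq_len(k)]
    expect_equal(nn$id, ord)
    expect_equal(nn$dist, d[ord])
  }
  # exact-match query: distance 0; excluded -> next closest
  q <- emb$library[7, ]
  expect_equal(knn_search(emb, q, 1)$id, 7L)
  expect_equal(knn_search(emb, q, 1)$dist, 0)
  nn2 <- knn_search(emb, q, 1, exclude = 7L)
  expect_true(nn2$id != 7L && nn2$dist > 0)
  expect_error(knn_search(emb, q, nrow(emb$library) + 1), "not enough neighbours")
})

test_that("simplex forecast equals the independent brute-force oracle", {
  x <- logistic_series(30)
  emb <- embed_series(x, E = 2, tau = 1)
  set.seed(2)
  for (rep in 1:25) {
    q <- c(stats::runif(1, 0.05, 0.95), stats::runif(1, 0.05, 0.95))
    expect_equal(simplex_forecast(emb, q),
                 brute_simplex(emb$library, emb$targets, emb$time_labels, q),
                 tolerance = 1e-12)
  }
  # with exclusions
  for (rep in 1:10) {
    q <- stats::runif(2)
    excl <- sample(nrow(emb$library), 2)
    expect_equal(simplex_forecast(emb, q, exclude = excl),
                 brute_simplex(emb$library, emb$targets, emb$time_labels, q,
                               exclude = excl),
                 tolerance = 1e-12)
  }
})

test_that("simplex forecast honours the convexity and zero-distance rules", {
  # constant series: all targets equal -> forecast exact
  embc <- embed_series(rep(5, 20), E = 2, tau = 1)
  expect_identical(simplex_forecast(embc, c(5, 5)), 5)

  # query equal to a unique library row -> that row's target
  x <- logistic_series(40)
  emb <- embed_series(x, E = 2, tau = 1)
  expect_equal(simplex_forecast(emb, emb$library[5, ]), emb$targets[5])

  # convex combination: prediction within neighbour target range
  set.seed(3)
  for (rep in 1:20) {
    q <- stats::runif(2)
    nn <- knn_search(emb, q, emb$E + 1)
    p <- simplex_forecast(emb, q)
    expect_gte(p, min(emb$targets[nn$id]) - 1e-12)
    expect_lte(p, max(emb$targets[nn$id]) + 1e-12)
  }
  expect_error(simplex_forecast(embed_series(1:4, E = 2), c(1, 2)),
               "library too small")
})

test_that("simplex state update shifts the lag register", {
  x <- logistic_series(50)
  emb <- embed_series(x, E = 3, tau = 1)
  st <- c(0.3, 0.6, 0.2)
  out <- simplex_state_update(emb, st)
  expect_equal(out[2:3], st[1:2])
  expect_equal(out[1], simplex_forecast(emb, st))

  # constant series: fixed point
  embc <- embed_series(rep(2, 20), E = 3, tau = 1)
  expect_equal(simplex_state_update(embc, c(2, 2, 2)), c(2, 2, 2))

  # period-2 series: on-cycle state maps to the next on-cycle state
  per <- rep(c(0.2, 0.8), 15)
  emb2 <- embed_series(per, E = 2, tau = 1)
  expect_equal(simplex_state_update(emb2, c(0.2, 0.8)), c(0.8, 0.2))
  expect_equal(simplex_state_update(emb2, c(0.8, 0.2)), c(0.2, 0.8))

  # tau > 1: full register of length (E-1)*tau + 1 shifts by one
  emb_t2 <- embed_series(x, E = 2, tau = 2)
  reg <- c(0.5, 0.4, 0.3)
  out2 <- simplex_state_update(emb_t2, reg)
  expect_length(out2, 3L)
  expect_equal(out2[2:3], reg[1:2])
  expect_equal(out2[1], simplex_forecast(emb_t2, reg[c(1, 3)]))
  expect_error(simplex_state_update(emb_t2, c(0.5, 0.4)), "full lag register")
})

test_that("embedding dimension selection is deterministic and sensible", {
  x <- logistic_series(120)
  sel <- select_embedding_dimension(x, E_max = 10)
  expect_lte(sel$E, 3L)
  expect_gt(max(sel$skill), 0.95)
  sel2 <- select_embedding_dimension(x, E_max = 10)
  expect_identical(sel, sel2)

  # white noise: no forecastable structure
  set.seed(4)
  wn <- stats::rnorm(200)
  seln <- select_embedding_dimension(wn, E_max = 6)
  expect_lt(max(abs(seln$skill)), 0.2)

  expect_error(select_embedding_dimension(c(1, 2), E_max = 5),
               "insufficient length")
})

test_that("leave-one-out simplex predictions agree with per-row exclusion", {
  x <- logistic_series(40)
  emb <- embed_series(x, E = 2, tau = 1)
  preds <- ecoreserv:::loo_simplex(emb)
  for (i in c(1, 10, 25)) {
    expect_equal(preds[i],
                 simplex_forecast(emb, emb$library[i, ], exclude = i),
                 tolerance = 1e-12)
  }
})
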