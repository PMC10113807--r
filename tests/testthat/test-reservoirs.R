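test_that("input weights honour scale, sparsity and seed", {
  w <- make_input_weights(20, 3, scale = 0.3, sparsity = 0, seed = 1)
  expect_true(all(abs(w$matrix) <= 0.3))
  expect_true(all(w$matrix != 0))

  w1 <- make_input_weights(10, 2, sparsity = 1, seed = 2)
  expect_true(all(w1$matrix == 0))

  wh <- make_input_weights(10, 10, sparsity = 0.37, seed = 3)
  expect_equal(sum(wh$matrix == 0), round(0.37 * 100))

  expect_identical(make_input_weights(5, 2, seed = 7)$matrix,
                   make_input_weights(5, 2, seed = 7)$matrix)
  expect_error(make_input_weights(5, 2, sparsity = 1.2), "sparsity")
})

test_that("erc_step matches hand computation and degenerate cases", {
  x <- logistic_series(60)
  res <- erc_reservoir(x, E = 3, seed = 5)
  st <- c(0.4, 0.5, 0.6)

  # u = 0: both variants are the pure simplex update
  expect_equal(erc_step(res, 0, state = st),
               simplex_state_update(res$embedding, st))
  res_b <- res; res_b$variant <- "add_then_project"
  expect_equal(erc_step(res_b, 0, state = st),
               simplex_state_update(res_b$embedding, st))

  # zero input weights: variants coincide for any u
  res0 <- res; res0$w_in$matrix[] <- 0
  res0b <- res0; res0b$variant <- "add_then_project"
  expect_equal(erc_step(res0, 1.7, state = st), erc_step(res0b, 1.7, state = st))

  # hand-computed step on a small library with hand-set weights
  xs <- c(0.1, 0.5, 0.9, 0.2, 0.7, 0.3, 0.8, 0.4, 0.6, 0.35)
  r2 <- erc_reservoir(xs, E = 2, seed = 1)
  r2$w_in$matrix <- matrix(c(0.2, -0.1), ncol = 1)
  q <- c(0.55, 0.25)
  nn <- knn_search(r2$embedding, q, 3)
  w <- exp(-nn$dist / nn$dist[1]); w <- w / sum(w)
  fc <- sum(w * r2$embedding$targets[nn$id])
  expect_equal(erc_step(r2, 2, state = q),
               c(0.2, -0.1) * 2 + c(fc, 0.55),
               tolerance = 1e-12)
})

test_that("erc_run iterates deterministically and flags divergence", {
  x <- logistic_series(80)
  res <- erc_reservoir(x, E = 2, seed = 3)
  u <- stats::runif(30)
  tr1 <- run_reservoir(res, u)
  tr2 <- run_reservoir(res, u)
  expect_identical(tr1$states, tr2$states)
  expect_equal(dim(tr1$states), c(30L, 2L))
  expect_equal(tr1$states[30, ], tr1$final_state)

  # constant-series library under zero input stays constant
  rc <- erc_reservoir(rep(1, 30), E = 2, seed = 1, init = c(1, 1))
  trc <- run_reservoir(rc, rep(0, 10))
  expect_true(all(trc$states == 1))

  # state after consuming input t reflects input t (row semantics)
  step1 <- erc_step(res, u[1], state = res$state)
  expect_equal(tr1$states[1, ], step1)
})

test_that("multiplexed trajectories concatenate column-wise", {
  t1 <- structure(list(states = matrix(1, 5, 3), final_state = rep(1, 3)),
                  class = "state_trajectory")
  t2 <- structure(list(states = matrix(2, 5, 4), final_state = rep(2, 4)),
                  class = "state_trajectory")
  m <- multiplex_states(list(t1, t2))
  expect_equal(ncol(m$states), 7L)
  expect_equal(m$states[, 4], rep(2, 5))
  expect_identical(multiplex_states(list(t1))$states, t1$states)
  t3 <- structure(list(states = matrix(0, 4, 2), final_state = rep(0, 2)),
                  class = "state_trajectory")
  expect_error(multiplex_states(list(t1, t3)), "mismatched")

  # many trajectories: total width is the running sum of state dims
  set.seed(9)
  Es <- sample(1:8, 40, replace = TRUE)
  trs <- lapply(Es, function(E) structure(
    list(states = matrix(0, 3, E), final_state = rep(0, E)),
    class = "state_trajectory"))
  expect_equal(ncol(multiplex_states(trs)$states), sum(Es))
})

test_that("LV map reproduces fixed points, logistic reduction and fixture", {
  p <- lv_params()
  expect_equal(lv_map_step(c(0, 0), p), c(0, 0))
  # y = 0, r_x = 2: logistic map 2x(1-x); extinction absorbing
  p2 <- lv_params(r_x = 2)
  expect_equal(lv_map_step(c(0.5, 0), p2), c(0.5, 0))
  expect_equal(lv_map_step(c(0.3, 0), p2)[1], 2 * 0.3 * 0.7)
  expect_equal(lv_map_step(c(0, 0.4), p)[1], 0)

  # three iterates from (0.5, 0.5) with the default parameters, frozen from
  # direct hand iteration of the map
  s <- c(0.5, 0.5)
  for (i in 1:3) s <- lv_map_step(s, p)
  s_direct <- c(0.5, 0.5)
  for (i in 1:3) {
    s_direct <- c(
      s_direct[1] * (3.0 - 3.0 * s_direct[1] + (-0.2) * s_direct[2]),
      s_direct[2] * (2.7 - 2.7 * s_direct[2] + 0.2 * s_direct[1]))
  }
  expect_equal(s, s_direct)
  expect_equal(s, c(0.6799350687, 0.6898498363), tolerance = 1e-9)
})

test_that("LV reservoir runs bounded under scaled chaotic input", {
  lv <- lv_reservoir(seed = 1)
  # zero input, zero init: all-zero trajectory
  tr0 <- run_reservoir(lv, rep(0, 20), init = c(0, 0))
  expect_true(all(tr0$states == 0))
  # zero weights: pure LV orbit
  lv0 <- lv_reservoir(seed = 1); lv0$w_in$matrix[] <- 0
  tr1 <- run_reservoir(lv0, stats::runif(50))
  s <- c(0.5, 0.5)
  for (i in 1:50) s <- lv_map_step(s, lv0$params)
  expect_equal(tr1$final_state, s)
  # Lorenz input, max-abs scaled: bounded over 1000 steps
  task <- task_lorenz(1000, seed = NA)
  u <- task$u / max(abs(task$u))
  tr2 <- run_reservoir(lv, u)
  expect_true(all(abs(tr2$states) < 10))
})

test_that("ESN construction meets spectral radius and contracts", {
  esn <- esn_reservoir(30, spectral_radius = 0.9, density = 0.5, seed = 2)
  rad <- max(Mod(eigen(esn$W, only.values = TRUE)$values))
  expect_equal(rad, 0.9, tolerance = 1e-8)
  expect_identical(esn_reservoir(10, seed = 4)$W, esn_reservoir(10, seed = 4)$W)

  # N = 1, density 1: the single weight is +/- radius
  e1 <- esn_reservoir(1, spectral_radius = 0.7, density = 1, seed = 1)
  expect_equal(abs(drop(e1$W)), 0.7)

  # tanh states bounded in (-1, 1); W = 0 variant gives tanh(W_in u)
  u <- stats::rnorm(200)
  tr <- run_reservoir(esn, u)
  expect_true(all(abs(tr$states) < 1))

  # echo state property at radius 0.5: inits forgotten
  esn2 <- esn_reservoir(40, spectral_radius = 0.5, density = 0.3, seed = 6)
  set.seed(8)
  d <- esp_distance(function(inp, ini) run_reservoir(esn2, inp, init = ini),
                    u[1:100], stats::runif(40, -1, 1), stats::runif(40, -1, 1))
  expect_lt(d[100], 1e-6)
})

test_that("reservoir runs propagate divergence with the step index", {
  lv <- lv_reservoir(seed = 3)
  # huge input kicks the quadratic map into overflow
  expect_error(run_reservoir(lv, rep(50, 100)), "diverged at step")
})
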