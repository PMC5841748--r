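test_that("evaluate_expr implements window semantics with zero-padded history", {
  e_all <- bn_all("X", 3)
  e_any <- bn_any("X", 4)
  cur <- c(X = 0L)
  expect_equal(evaluate_expr(e_all, cur, list(X = c(1, 1, 1))), 1L)
  expect_equal(evaluate_expr(e_all, cur, list(X = c(1, 1))), 0L)   # short history
  expect_equal(evaluate_expr(e_all, cur, list(X = c(0, 1, 1, 1))), 1L)
  expect_equal(evaluate_expr(e_all, cur, list(X = c(1, 1, 0))), 0L)
  expect_equal(evaluate_expr(e_any, cur, list(X = c(0, 0, 1, 0))), 1L)
  expect_equal(evaluate_expr(e_any, cur, list(X = c(0, 0))), 0L)
  expect_equal(evaluate_expr(e_any, cur, list()), 0L)
  # symbolic widths resolve through the parameter table
  expect_equal(evaluate_expr(bn_all("X", "w"), cur, list(X = c(1, 1)),
                             parameters = c(w = 2L)), 1L)
  expect_error(evaluate_expr(bn_atom("Y"), cur), "unresolved node")
})

test_that("absorbing and oscillating one-node fixtures behave exactly", {
  fx <- named_fixtures()
  for (scheme in c("synchronous", "asynchronous", "asynchronous_single")) {
    tr <- simulate_network(fx$constant,
                           sim_config(iterations = 50, repetitions = 2,
                                      update_scheme = scheme, seed = 7))
    expect_true(all(tr$states == 0))   # absorbing zero
  }
  tr <- simulate_network(fx$negation_oscillator,
                         sim_config(iterations = 10, repetitions = 1,
                                    update_scheme = "synchronous"))
  expect_equal(as.vector(tr$states[1, , 1]), rep(c(1, 0), 5))
  s <- summarize_activation(simulate_network(
    fx$negation_oscillator,
    sim_config(iterations = 100, repetitions = 1,
               update_scheme = "synchronous")), window_fraction = 1)
  expect_equal(unname(s$mean), 0.5)
})

test_that("identical seeds give bit-identical ensembles; seeds differ otherwise", {
  m <- build_ibd_model()
  cfg <- ibd_sim_config(iterations = 80, repetitions = 3, seed = 11)
  t1 <- simulate_network(m, cfg)
  t2 <- simulate_network(m, cfg)
  expect_identical(t1$states, t2$states)
  cfg2 <- ibd_sim_config(iterations = 80, repetitions = 3, seed = 12)
  expect_false(identical(t1$states, simulate_network(m, cfg2)$states))
  # repetitions draw distinct streams
  expect_false(identical(t1$states[1, , ], t1$states[2, , ]))
})

test_that("clamps hold at every recorded iteration and beat the rules", {
  fx <- named_fixtures()$clamped_input
  cfg <- sim_config(iterations = 30, repetitions = 2,
                    perturbations = c(IN = "overexpress"), seed = 1)
  tr <- simulate_network(fx, cfg)
  expect_true(all(tr$states[, , "IN"] == 1))
  expect_true(all(tr$states[, 2:30, "OUT"] == 1))
  cfg$perturbations <- c(IN = "knockout")
  tr0 <- simulate_network(fx, sim_config(iterations = 30, repetitions = 1,
                                         perturbations = c(IN = "knockout"),
                                         initial_state = c(IN = 1, OUT = 1)))
  expect_true(all(tr0$states[, , "IN"] == 0))  # knockout overrides initial 1
  expect_error(simulate_network(fx, sim_config(perturbations = c(Z = "knockout"))),
               "not in model")
})

test_that("window terms of width 1 reduce to the lagged atom under synchronous updating", {
  m <- parse_model(c("X = !X", "A1 = X", "A2 = ALL(X, 1)", "A3 = ANY(X, 1)"))
  tr <- simulate_network(m, sim_config(iterations = 40, repetitions = 1,
                                       update_scheme = "synchronous"))
  expect_identical(tr$states[1, , "A2"], tr$states[1, , "A1"])
  expect_identical(tr$states[1, , "A3"], tr$states[1, , "A1"])
})

test_that("synchronous engine matches the brute-force oracle on all initial states", {
  for (seed in c(3, 8)) {
    m <- random_model(n_nodes = 5, density = 0.5, seed = seed)
    inits <- all_binary_states(5)
    for (i in seq_len(nrow(inits))) {
      init <- stats::setNames(inits[i, ], model_nodes(m))
      tr <- simulate_network(m, sim_config(iterations = 12, repetitions = 1,
                                           update_scheme = "synchronous",
                                           initial_state = init))
      expect_equal(unname(tr$states[1, , ]), oracle_sync_traj(m, init, 12))
    }
  }
})

test_that("temporal models match the oracle trajectory", {
  m <- random_model(n_nodes = 6, density = 0.5, temporal_fraction = 0.4,
                    max_width = 3, seed = 21)
  init <- stats::setNames(c(1, 0, 1, 1, 0, 0), model_nodes(m))
  tr <- simulate_network(m, sim_config(iterations = 15, repetitions = 1,
                                       update_scheme = "synchronous",
                                       initial_state = init))
  expect_equal(unname(tr$states[1, , ]), oracle_sync_traj(m, init, 15))
})

test_that("attractor detection finds exact periods under synchronous updating", {
  fx <- named_fixtures()
  rep_cfg <- function(model, init = NULL)
    detect_attractor(model, sim_config(iterations = 64, repetitions = 1,
                                       update_scheme = "synchronous",
                                       initial_state = init))
  r <- rep_cfg(fx$negation_oscillator)
  expect_equal(r$kind, "simple_cycle")
  expect_equal(r$period, 2L)
  expect_equal(rep_cfg(fx$constant)$kind, "fixed_point")
  expect_equal(rep_cfg(fx$constant, c(A = 1))$kind, "fixed_point")
  r4 <- rep_cfg(fx$two_node_feedback)
  expect_equal(r4$period, 4L)
  # periods agree with the state-transition-graph oracle on random fixtures
  m <- random_model(n_nodes = 6, density = 0.4, seed = 5)
  inits <- all_binary_states(6)
  for (i in seq(1, nrow(inits), by = 7)) {
    init <- stats::setNames(inits[i, ], model_nodes(m))
    got <- detect_attractor(m, sim_config(iterations = 200, repetitions = 1,
                                          update_scheme = "synchronous",
                                          initial_state = init))
    want <- oracle_sync_attractor(m, init)
    expect_equal(got$period, want$period)
    expect_equal(got$transient, want$transient)
  }
})

test_that("asynchronous runs report a stationarity gap instead of a period", {
  m <- build_ibd_model()
  r <- detect_attractor(m, ibd_sim_config(iterations = 600, repetitions = 5,
                                          seed = 2))
  expect_equal(r$kind, "complex_or_stochastic")
  expect_true(r$stationarity_gap >= 0)
})

test_that("temporal toy fires ANY at iteration 2 and ALL at iteration 4", {
  fx <- named_fixtures()$temporal_toy
  tr <- simulate_network(fx, sim_config(iterations = 8, repetitions = 1,
                                        update_scheme = "synchronous"))
  expect_equal(as.vector(tr$states[1, , "DANY"]), c(0, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(as.vector(tr$states[1, , "DALL"]), c(0, 0, 0, 1, 1, 1, 1, 1))
})

test_that("iterations below the maximum window width are rejected", {
  m <- named_fixtures()$temporal_toy
  expect_error(simulate_network(m, sim_config(iterations = 2, repetitions = 1)),
               "window width")
})

test_that("trajectory export writes the full long table", {
  tr <- simulate_network(named_fixtures()$two_node_feedback,
                         sim_config(iterations = 5, repetitions = 2,
                                    update_scheme = "synchronous"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 2 * 5 * 2)
  expect_equal(sort(unique(df$node)), c("A", "B"))
})
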