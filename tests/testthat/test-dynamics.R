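test_that("normalized Hill response hits its anchors", {
  expect_equal(hill_activation(0), 0)
  expect_equal(hill_activation(1), 1)
  expect_equal(hill_activation(0.5, n = 3, k = 0.5), 0.5625)
  # general exponent path agrees with the direct formula
  x <- seq(0, 1, by = 0.1)
  expect_equal(hill_activation(x, n = 2.5, k = 0.3),
               x^2.5 * (1 + 0.3^2.5) / (x^2.5 + 0.3^2.5))
})

test_that("regulatory drive handles the canonical single-link cases", {
  act <- signed_network(data.frame(source = "A", target = "B",
                                   sign = "activation"))
  p <- model_parameters(act, 1)
  expect_equal(regulatory_drive(p, c(A = 1, B = 0))[["B"]], 1)
  expect_equal(regulatory_drive(p, c(A = 0.5, B = 0))[["B"]], 0.5625)
  expect_equal(regulatory_drive(p, c(A = 0.5, B = 0))[["A"]], 1)  # input-free

  inh <- signed_network(data.frame(source = "A", target = "B",
                                   sign = "inhibition"))
  p2 <- model_parameters(inh, 1)
  expect_equal(regulatory_drive(p2, c(A = 0, B = 0))[["B"]], 1)
  expect_equal(regulatory_drive(p2, c(A = 1, B = 0))[["B"]], 0)
})

test_that("drive matches the naive oracle and is monotone and bounded", {
  for (seed in 1:25) {
    net <- random_signed_net(12, density = 0.15, seed = seed)
    p <- model_parameters(net, 1)
    set.seed(seed + 100)
    x <- runif(length(net$nodes))
    f <- regulatory_drive(p, x)
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(unname(f), unname(naive_drive(p, x)), tolerance = 1e-12)

    # monotonicity: raising an activator never lowers the target drive,
    # raising an inhibitor never raises it
    lk <- net$links[sample(nrow(net$links), 1), ]
    idx <- match(lk$source, net$nodes)
    x2 <- x
    x2[idx] <- min(1, x[idx] + 0.2)
    f2 <- regulatory_drive(p, x2)
    if (lk$sign == "activation") {
      expect_gte(f2[[lk$target]], f[[lk$target]] - 1e-12)
    } else {
      expect_lte(f2[[lk$target]], f[[lk$target]] + 1e-12)
    }
  }
})

test_that("fixed points: input-free relaxation and acyclic closed forms", {
  iso <- signed_network(data.frame(source = character(),
                                   target = character(),
                                   sign = character()), nodes = "A")
  p <- model_parameters(iso, c(A = 0.7))
  for (x0 in c(0, 0.33, 1)) {
    res <- simulate_steady_state(p, x0, tol = 1e-8)
    expect_true(res$converged)
    expect_lt(abs(unname(res$state) - 0.7), 1e-8)
  }

  chain <- signed_network(data.frame(source = "A", target = "B",
                                     sign = "activation"))
  pc <- model_parameters(chain, c(A = 1, B = 0.8))
  res <- simulate_steady_state(pc, c(0.2, 0.9), tol = 1e-8)
  expect_equal(res$state[["A"]], 1, tolerance = 1e-6)
  expect_equal(res$state[["B"]], 0.8, tolerance = 1e-6)  # e_B * H(1)

  inh <- signed_network(data.frame(source = "A", target = "B",
                                   sign = "inhibition"))
  p_inh <- model_parameters(inh, c(A = 1, B = 0.8))
  res2 <- simulate_steady_state(p_inh, c(0.5, 0.9), tol = 1e-8)
  expect_equal(res2$state[["B"]], 0, tolerance = 1e-6)  # e_B * (1 - H(1))
})

test_that("integrated steady states match topological propagation on DAGs", {
  for (seed in 1:5) {
    net <- random_dag(10, density = 0.25, seed = seed)
    set.seed(seed)
    p <- model_parameters(net, setNames(runif(10, 0.2, 1), net$nodes))
    expected <- closed_form_acyclic(p)
    res <- simulate_steady_state(p, runif(10), tol = 1e-8)
    expect_true(res$converged)
    expect_equal(res$state, expected, tolerance = 1e-6)
    expect_equal(res$clamp_hits, 0)
  }
})

test_that("zero capacity drives every steady state to zero", {
  net <- random_signed_net(10, density = 0.2, seed = 4)
  p <- model_parameters(net, 0)
  res <- simulate_steady_state(p, rep(1, 10))
  expect_true(all(res$state < 1e-5))
})

test_that("integrator rejects bad control parameters", {
  p <- model_parameters(chain_net(), 0.5)
  expect_error(simulate_steady_state(p, rep(0, 3), dt = 0),
               "dt", class = "netdasc_validation_error")
  expect_error(simulate_steady_state(p, rep(0, 3), t_max = -1),
               "t_max", class = "netdasc_validation_error")
  expect_error(simulate_steady_state(p, rep(0, 3), tol = 0),
               "tol", class = "netdasc_validation_error")
  expect_error(simulate_steady_state(p, c(-0.1, 0, 0)),
               class = "netdasc_validation_error")
})

test_that("compiled and reference integrators agree bit for bit", {
  for (seed in 1:5) {
    net <- random_signed_net(8, density = 0.25, seed = seed)
    set.seed(seed)
    p <- model_parameters(net, setNames(runif(8), net$nodes))
    st <- netdasc:::sim_struct(p)
    X0 <- matrix(runif(8 * 20), 8)
    a <- netdasc:::integrate_batch_r(st, X0, 0.1, 50, 1e-6)
    b <- netdasc:::integrate_batch(st, X0, 0.1, 50, 1e-6)
    expect_identical(a$state, b$state)
    expect_identical(a$steps, b$steps)
    expect_identical(a$converged, b$converged)
  }
})

test_that("Monte-Carlo activities are deterministic and batch-invariant", {
  net <- toggle_net()
  p <- model_parameters(net, 1)
  a <- monte_carlo_activities(p, n_init = 60, seed = 11)
  b <- monte_carlo_activities(p, n_init = 60, seed = 11)
  expect_identical(a, b)
  c <- monte_carlo_activities(p, n_init = 60, seed = 11, batch_size = 7L)
  expect_identical(a$activities, c$activities)
  d <- monte_carlo_activities(p, n_init = 60, seed = 12)
  expect_false(identical(a$activities, d$activities))
  expect_true(all(a$activities >= 0 & a$activities <= 1))
  # summary is recomputable from the draws
  expect_equal(a$summary$mean, unname(rowMeans(a$activities)))
  expect_equal(a$n_init, ncol(a$activities))
})

test_that("joint cohort simulation equals per-sample simulation", {
  spec <- synth_spec(n_nodes = 10, density = 0.15, n_per_group = 2,
                     planted = 1, seed = 5)
  gn <- generate_network(spec)
  co <- generate_cohort(gn$network, spec)
  acts <- simulate_cohort(gn$network, co$normalized, n_init = 25, seed = 3)
  for (i in seq_along(acts)) {
    solo <- monte_carlo_activities(
      build_parameters(gn$network, co$normalized, names(acts)[i]),
      n_init = 25, seed = netdasc:::derive_seed(3, i)
    )
    expect_identical(acts[[i]]$activities, solo$activities)
    expect_identical(acts[[i]]$summary, solo$summary)
  }
})

test_that("monostable fixture collapses to a point mass", {
  chain <- signed_network(data.frame(source = "A", target = "B",
                                     sign = "activation"))
  p <- model_parameters(chain, c(A = 0.9, B = 0.7))
  ad <- monte_carlo_activities(p, n_init = 100, seed = 2)
  expect_true(all(apply(ad$activities, 1, stats::sd) < 1e-6))
})

test_that("toggle switch gives a symmetric bimodal distribution", {
  p <- model_parameters(toggle_net(), 1)
  ad <- monte_carlo_activities(p, n_init = 2000, seed = 8)
  a_act <- ad$activities["A", ]
  expect_true(all(a_act < 0.2 | a_act > 0.8))  # two clean modes
  expect_equal(mean(a_act > 0.5), 0.5, tolerance = 0.05)
})

test_that("standard error of the mean activity scales as 1/sqrt(n)", {
  p <- model_parameters(toggle_net(), 1)
  sds <- vapply(c(500, 8000), function(n) {
    means <- vapply(1:12, function(r) {
      mean(monte_carlo_activities(p, n_init = n,
                                  seed = 1000 + r)$activities["A", ])
    }, numeric(1))
    stats::sd(means)
  }, numeric(1))
  ratio <- sds[1] / sds[2]  # theory: sqrt(8000/500) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("activity tidiers and long export are consistent", {
  p <- model_parameters(chain_net(), c(A = 1, B = 0.5, C = 0.5))
  ad <- monte_carlo_activities(p, n_init = 10, seed = 1)
  long <- activities_long(ad)
  expect_equal(nrow(long), 30)
  expect_equal(long$activity[long$node == "A" & long$run == 3],
               unname(ad$activities["A", 3]))
  expect_identical(tidy(ad), ad$summary)
  expect_equal(glance(ad)$convergence_rate, 1)
})
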