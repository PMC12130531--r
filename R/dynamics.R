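#' Normalized Hill response
#'
#' `H(x) = x^n (1 + K^n) / (x^n + K^n)`: a Hill curve rescaled so that
#' `H(0) = 0` and `H(1) = 1`, keeping link responses on the same `[0, 1]`
#' activity scale as the state variables.
#'
#' @param x Activity value(s) in `[0, 1]` (vector or matrix).
#' @param n Hill exponent (`>= 1`).
#' @param k Hill threshold in `(0, 1)`.
#' @return Same shape as `x`, values in `[0, 1]`.
#' @examples
#' hill_activation(0.5, n = 3, k = 0.5) # 0.5625
#' @export
hill_activation <- function(x, n = 3, k = 0.5) {
  xn <- if (n == 3) x * x * x else x^n
  kn <- if (n == 3) k * k * k else k^n
  xn * (1 + kn) / (xn + kn)
}

# Precomputed index structure for fast vectorized drive evaluation.
# Incoming activator links are aggregated per target with rowsum() (stable,
# column-count-independent accumulation, so batching runs never changes
# per-run results); inhibitors combine as a product of (1 - H).
sim_struct <- function(params) {
  net <- params$network
  nodes <- net$nodes
  idx <- setNames(seq_along(nodes), nodes)
  lk <- net$links
  act <- lk[lk$sign == "activation", ]
  inh <- lk[lk$sign == "inhibition", ]
  a_tgt <- unname(idx[act$target])
  i_tgt <- unname(idx[inh$target])
  wsum <- numeric(length(nodes))
  if (nrow(act) > 0) {
    ws <- rowsum(act$weight, group = a_tgt)
    wsum[as.integer(rownames(ws))] <- ws[, 1]
  }
  list(
    n = length(nodes),
    a_src = unname(idx[act$source]), a_tgt = a_tgt, a_w = act$weight,
    a_nodes = sort(unique(a_tgt)),            # nodes with >= 1 activator
    i_src = unname(idx[inh$source]), i_tgt = i_tgt,
    i_nodes = sort(unique(i_tgt)),            # nodes with >= 1 inhibitor
    wsum = wsum,
    e = unname(params$capacity),
    tau = params$tau, hill_n = params$hill_n, hill_k = params$hill_k
  )
}

# F(x) for a state matrix X (nodes x runs). Activator-free nodes have
# activation part 1; nodes with no incoming links therefore return 1.
drive_matrix <- function(st, X) {
  H <- hill_activation(clamp01(X), st$hill_n, st$hill_k)
  FA <- matrix(1, nrow(X), ncol(X))
  if (length(st$a_src) > 0) {
    contrib <- st$a_w * H[st$a_src, , drop = FALSE]
    agg <- rowsum(contrib, group = st$a_tgt)
    FA[st$a_nodes, ] <- agg / st$wsum[st$a_nodes]
  }
  if (length(st$i_src) > 0) {
    # product of (1 - H) per target, accumulated in link order (the
    # compiled engine mirrors this order exactly)
    acc <- matrix(1, nrow(X), ncol(X))
    for (l in seq_along(st$i_src)) {
      t <- st$i_tgt[l]
      acc[t, ] <- acc[t, ] * (1 - pmin(H[st$i_src[l], ], 1))
    }
    FA[st$i_nodes, ] <- FA[st$i_nodes, , drop = FALSE] *
      acc[st$i_nodes, , drop = FALSE]
  }
  FA
}

# E is the capacity: a per-node vector (recycled over runs) or a full
# nodes x runs matrix when runs of several samples are integrated jointly.
deriv_matrix <- function(st, X, E = st$e) (E * drive_matrix(st, X) - X) / st$tau

#' Regulatory drive of the normalized model
#'
#' The regulatory function `F_i(x)` combining a node's inputs on `[0, 1]`:
#' a weighted mean of the Hill-transformed activator activities (1 if the
#' node has no activators) multiplied by `prod(1 - H(x_k))` over its
#' inhibitors. Input-free nodes return 1, so they relax to their capacity.
#' The result is guaranteed to lie in `[0, 1]` and is monotone increasing
#' in every activator and monotone decreasing in every inhibitor.
#'
#' @param params A `model_params` object.
#' @param state Numeric state vector in network node order (or a named
#'   vector covering all nodes), components in `[0, 1]`.
#' @param node Optional single node identifier; if given, returns that
#'   node's drive only.
#' @return Named numeric vector of drives (or a single value).
#' @export
regulatory_drive <- function(params, state, node = NULL) {
  stopifnot(inherits(params, "model_params"))
  nodes <- params$network$nodes
  if (!is.null(names(state))) state <- state[nodes]
  if (length(state) != length(nodes) || any(!is.finite(state))) {
    abort_validation("state must cover every network node with finite values")
  }
  st <- sim_struct(params)
  f <- drive_matrix(st, matrix(state, ncol = 1))[, 1]
  names(f) <- nodes
  if (is.null(node)) f else f[[node]]
}

# Integrate a batch of initial conditions (columns of X0) with fixed-step
# RK4 until max_i |dx_i/dt| < tol in every column or t_max is reached.
# Columns evolve independently, so results are identical however runs are
# batched. States are clamped to [0,1] after each full step (and inside
# drive evaluation); with the default step the clamp never fires.
# Engine dispatch: the compiled integrator is the default; the pure-R
# reference below implements the identical arithmetic (tested for
# bit-identity) and is selected with options(netdasc.engine = "r").
integrate_batch <- function(st, X0, dt, t_max, tol, E = NULL) {
  engine <- getOption("netdasc.engine", "cpp")
  if (identical(engine, "r")) {
    return(integrate_batch_r(st, X0, dt, t_max, tol, E))
  }
  N <- nrow(X0)
  M <- ncol(X0)
  Em <- if (is.null(E)) matrix(st$e, N, M) else
    if (is.matrix(E)) E else matrix(E, N, M)
  res <- .integrate_batch_cpp(
    X0, Em,
    as.integer(st$a_src - 1L), as.integer(st$a_tgt - 1L),
    as.numeric(st$a_w), as.numeric(st$wsum),
    as.integer(st$i_src - 1L), as.integer(st$i_tgt - 1L),
    st$hill_n, st$hill_k, st$tau,
    dt, as.integer(ceiling(t_max / dt)), tol
  )
  res$steps <- as.integer(res$steps)
  res$clamp_hits <- as.integer(res$clamp_hits)
  res
}

integrate_batch_r <- function(st, X0, dt, t_max, tol, E = NULL) {
  n_steps <- as.integer(ceiling(t_max / dt))
  M <- ncol(X0)
  X <- X0
  steps <- rep(NA_integer_, M)
  active <- seq_len(M)
  clamp_hits <- 0L
  Xa <- X
  Ea <- if (is.null(E)) st$e else E
  e_is_matrix <- is.matrix(Ea)
  for (s in seq_len(n_steps + 1L)) {
    k1 <- deriv_matrix(st, Xa, Ea)
    done <- col_max_abs(k1) < tol
    if (any(done)) {
      steps[active[done]] <- s - 1L
      X[, active[done]] <- Xa[, done, drop = FALSE]
      active <- active[!done]
      if (length(active) == 0L) break
      Xa <- Xa[, !done, drop = FALSE]
      if (e_is_matrix) Ea <- Ea[, !done, drop = FALSE]
      k1 <- k1[, !done, drop = FALSE]
    }
    if (s > n_steps) break
    k2 <- deriv_matrix(st, Xa + (dt / 2) * k1, Ea)
    k3 <- deriv_matrix(st, Xa + (dt / 2) * k2, Ea)
    k4 <- deriv_matrix(st, Xa + dt * k3, Ea)
    Xn <- Xa + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    clamp_hits <- clamp_hits + sum(Xn < 0 | Xn > 1)
    Xa <- clamp01(Xn)
  }
  if (length(active) > 0L) X[, active] <- Xa
  converged <- !is.na(steps)
  steps[!converged] <- n_steps
  list(state = X, converged = converged, steps = steps,
       clamp_hits = clamp_hits)
}

#' Integrate the network ODE to steady state
#'
#' Integrates `dx_i/dt = (e_i F_i(x) - x_i) / tau_i` with classical
#' fixed-step fourth-order Runge--Kutta from one initial state, stopping
#' when `max_i |dx_i/dt|` falls below `tol` or the horizon is reached.
#' A fixed step keeps trajectories bit-reproducible across platforms.
#'
#' @param params A `model_params` object.
#' @param x0 Initial state in `[0, 1]^N`, in node order (or named).
#' @param dt Step size (> 0).
#' @param t_max Integration horizon (> 0).
#' @param tol Convergence tolerance on the derivative (> 0).
#' @return A list with `state` (named steady-state vector), `converged`
#'   (logical), `steps` (RK4 steps taken) and `clamp_hits` (number of
#'   state components the post-step clamp had to touch; 0 in practice).
#' @export
simulate_steady_state <- function(params, x0, dt = 0.1, t_max = 100,
                                  tol = 1e-6) {
  stopifnot(inherits(params, "model_params"))
  check_number(dt, "dt", 0, Inf, open_lower = TRUE)
  check_number(t_max, "t_max", 0, Inf, open_lower = TRUE)
  check_number(tol, "tol", 0, Inf, open_lower = TRUE)
  nodes <- params$network$nodes
  if (!is.null(names(x0))) x0 <- x0[nodes]
  if (length(x0) != length(nodes) || any(!is.finite(x0)) ||
      any(x0 < 0 | x0 > 1)) {
    abort_validation("x0 must lie in [0,1] and cover every network node")
  }
  st <- sim_struct(params)
  res <- integrate_batch(st, matrix(as.numeric(x0), ncol = 1), dt, t_max, tol)
  list(state = setNames(res$state[, 1], nodes),
       converged = res$converged[1], steps = res$steps[1],
       clamp_hits = res$clamp_hits)
}

#' Monte-Carlo steady-state activity distribution for one sample
#'
#' Draws `n_init` initial states uniformly on `[0, 1]^N`, integrates each
#' to steady state and collects the endpoints: the per-node empirical
#' distribution of attained activities for this sample. Each run has its
#' own RNG substream derived from `(seed, run_index)`, so results are
#' bit-identical however the runs are batched or distributed, and merging
#' is by run index.
#'
#' @param params A `model_params` object (one sample's capacities).
#' @param n_init Number of random initial conditions (`>= 1`).
#' @param seed Master seed (integer).
#' @param dt,t_max,tol Passed to the integrator; see
#'   [simulate_steady_state()].
#' @param batch_size Runs integrated per internal batch (speed only;
#'   never affects results).
#' @return An object of class `activity_distribution`: steady-state matrix
#'   `activities` (nodes x runs), `summary` tibble (per-node mean, median,
#'   q05, q95), `n_init`, `convergence_rate` and the `sample` id. Warns
#'   (does not fail) when fewer than 99% of runs converged.
#' @examples
#' net <- signed_network(data.frame(source = "A", target = "B",
#'                                  sign = "activation"))
#' p <- model_parameters(net, c(A = 1, B = 0.8))
#' ad <- monte_carlo_activities(p, n_init = 20, seed = 1)
#' tidy(ad)
#' @export
monte_carlo_activities <- function(params, n_init = 1000, seed,
                                   dt = 0.1, t_max = 100, tol = 1e-6,
                                   batch_size = 512L) {
  stopifnot(inherits(params, "model_params"))
  if (missing(seed)) abort_validation("`seed` is required")
  check_number(n_init, "n_init", 1, Inf)
  nodes <- params$network$nodes
  N <- length(nodes)
  st <- sim_struct(params)
  acts <- matrix(NA_real_, N, n_init, dimnames = list(nodes, NULL))
  converged <- logical(n_init)
  steps <- integer(n_init)
  clamp_hits <- 0L
  run <- 1L
  while (run <= n_init) {
    batch <- run:min(run + batch_size - 1L, n_init)
    X0 <- vapply(batch, function(r) {
      withr::with_seed(derive_seed(seed, r), runif(N))
    }, numeric(N))
    X0 <- matrix(X0, nrow = N)
    res <- integrate_batch(st, X0, dt, t_max, tol)
    acts[, batch] <- res$state
    converged[batch] <- res$converged
    steps[batch] <- res$steps
    clamp_hits <- clamp_hits + res$clamp_hits
    run <- batch[length(batch)] + 1L
  }
  conv_rate <- mean(converged)
  if (conv_rate < 0.99) {
    warn(sprintf("only %.1f%% of %d runs converged (tol %g, t_max %g)",
                 100 * conv_rate, n_init, tol, t_max))
  }
  structure(list(
    sample = params$sample,
    activities = acts,
    n_init = as.integer(n_init),
    convergence_rate = conv_rate,
    steps = steps,
    clamp_hits = clamp_hits,
    seed = seed,
    summary = summarise_activities(acts, params$sample, n_init, conv_rate)
  ), class = "activity_distribution")
}

# Joint Monte-Carlo over several samples sharing one network topology and
# global parameters, differing only in capacities. All runs of all samples
# integrate as one column batch; since columns evolve independently this is
# bit-identical to calling monte_carlo_activities() per sample with the
# same per-sample seeds -- just much faster at cohort scale.
mc_cohort_joint <- function(params_list, n_init, seeds, dt, t_max, tol) {
  p1 <- params_list[[1]]
  nodes <- p1$network$nodes
  N <- length(nodes)
  S <- length(params_list)
  st <- sim_struct(p1)
  E <- matrix(NA_real_, N, S * n_init)
  X0 <- matrix(NA_real_, N, S * n_init)
  for (i in seq_len(S)) {
    cols <- (i - 1L) * n_init + seq_len(n_init)
    E[, cols] <- unname(params_list[[i]]$capacity)
    X0[, cols] <- vapply(seq_len(n_init), function(r) {
      withr::with_seed(derive_seed(seeds[i], r), runif(N))
    }, numeric(N))
  }
  res <- integrate_batch(st, X0, dt, t_max, tol, E = E)
  lapply(seq_len(S), function(i) {
    cols <- (i - 1L) * n_init + seq_len(n_init)
    acts <- res$state[, cols, drop = FALSE]
    rownames(acts) <- nodes
    conv <- res$converged[cols]
    conv_rate <- mean(conv)
    if (conv_rate < 0.99) {
      warn(sprintf("sample %s: only %.1f%% of %d runs converged",
                   params_list[[i]]$sample, 100 * conv_rate, n_init))
    }
    structure(list(
      sample = params_list[[i]]$sample,
      activities = acts,
      n_init = as.integer(n_init),
      convergence_rate = conv_rate,
      steps = res$steps[cols],
      clamp_hits = NA_integer_,
      seed = seeds[i],
      summary = summarise_activities(acts, params_list[[i]]$sample,
                                     n_init, conv_rate)
    ), class = "activity_distribution")
  })
}

summarise_activities <- function(acts, sample, n_init, conv_rate) {
  tibble(
    sample = sample,
    node = rownames(acts),
    mean = unname(rowMeans(acts)),
    median = unname(apply(acts, 1, median)),
    q05 = unname(apply(acts, 1, quantile, probs = 0.05, names = FALSE)),
    q95 = unname(apply(acts, 1, quantile, probs = 0.95, names = FALSE)),
    n_init = as.integer(n_init),
    convergence_rate = conv_rate
  )
}

#' @export
print.activity_distribution <- function(x, ...) {
  cat(sprintf(
    "<activity_distribution> sample %s: %d nodes x %d runs, %.1f%% converged\n",
    x$sample, nrow(x$activities), x$n_init, 100 * x$convergence_rate
  ))
  invisible(x)
}

#' @method tidy activity_distribution
#' @export
tidy.activity_distribution <- function(x, ...) x$summary

#' Long-format activities
#'
#' @param x An `activity_distribution`.
#' @return Tibble with columns `sample`, `node`, `run`, `activity`.
#' @export
activities_long <- function(x) {
  stopifnot(inherits(x, "activity_distribution"))
  tibble(
    sample = x$sample,
    node = rep(rownames(x$activities), times = ncol(x$activities)),
    run = rep(seq_len(ncol(x$activities)), each = nrow(x$activities)),
    activity = as.vector(x$activities)
  )
}

#' @method glance activity_distribution
#' @export
glance.activity_distribution <- function(x, ...) {
  tibble(sample = x$sample, nodes = nrow(x$activities),
         n_init = x$n_init, convergence_rate = x$convergence_rate,
         mean_steps = mean(x$steps), clamp_hits = x$clamp_hits)
}
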