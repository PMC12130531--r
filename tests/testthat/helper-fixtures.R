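# Fixtures and independent oracles shared across the test files.
# Oracles deliberately use naive/brute-force formulations, independent of
# the package's implementation paths.

signor_fixture <- function() {
  system.file("extdata", "signor_mini.tsv", package = "netdasc")
}

# A -> B -| C (acyclic chain with one inhibition)
chain_net <- function() {
  signed_network(data.frame(
    source = c("A", "B"),
    target = c("B", "C"),
    sign = c("activation", "inhibition")
  ))
}

# mutual inhibition toggle switch
toggle_net <- function() {
  signed_network(data.frame(
    source = c("A", "B"),
    target = c("B", "A"),
    sign = c("inhibition", "inhibition")
  ))
}

random_signed_net <- function(n_nodes, density = 0.1, seed = 1) {
  gn <- generate_network(synth_spec(n_nodes = n_nodes, density = density,
                                    n_per_group = 2, planted = 0,
                                    seed = seed))
  gn$network
}

# random DAG: only links from lexicographically earlier to later nodes
random_dag <- function(n_nodes, density = 0.2, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("D%02d", seq_len(n_nodes))
  pairs <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
  pairs <- pairs[pairs$i < pairs$j, ]
  pairs <- pairs[runif(nrow(pairs)) < density, ]
  if (nrow(pairs) == 0) pairs <- data.frame(i = 1, j = 2)
  signed_network(data.frame(
    source = nodes[pairs$i],
    target = nodes[pairs$j],
    sign = sample(c("activation", "inhibition"), nrow(pairs),
                  replace = TRUE)
  ), nodes = nodes)
}

# Naive per-node drive: direct loops over the link table.
naive_drive <- function(params, state) {
  net <- params$network
  H <- function(x) {
    n <- params$hill_n; k <- params$hill_k
    x^n * (1 + k^n) / (x^n + k^n)
  }
  st <- setNames(state, net$nodes)
  vapply(net$nodes, function(nd) {
    inc <- net$links[net$links$target == nd, ]
    act <- inc[inc$sign == "activation", ]
    inh <- inc[inc$sign == "inhibition", ]
    a <- if (nrow(act) > 0) {
      sum(act$weight * H(st[act$source])) / sum(act$weight)
    } else 1
    i <- if (nrow(inh) > 0) prod(1 - H(st[inh$source])) else 1
    a * i
  }, numeric(1))
}

# Closed-form steady state on an acyclic network: propagate x* = e * F(x*)
# in topological order (igraph supplies the order; drive is the naive one).
closed_form_acyclic <- function(params) {
  net <- params$network
  g <- igraph::graph_from_data_frame(
    net$links[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
  topo <- names(igraph::topo_sort(g, mode = "out"))
  x <- setNames(rep(NA_real_, length(net$nodes)), net$nodes)
  for (nd in topo) {
    f <- naive_drive(params, ifelse(is.na(x), 0, x))[[nd]]
    x[nd] <- params$capacity[[nd]] * f
  }
  x[net$nodes]
}

# Brute-force two-sample KS: evaluate the ECDF difference at every pooled
# point, O(n^2).
ks_oracle <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# Two-sided Fisher p by direct hypergeometric enumeration: sum the
# probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed one.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c       # column 1 total
  n <- b + d       # column 2 total
  k <- a + b       # row 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny two-cohort toy dasc_result for intersection tests
fake_dasc <- function(nodes, called, direction = "up-in-B",
                      cohort = "x") {
  tb <- tibble::tibble(
    node = nodes,
    D = ifelse(nodes %in% called, 1, 0.1),
    delta_median = ifelse(nodes %in% called, 0.5, 0.01) *
      ifelse(direction == "up-in-B", 1, -1),
    p = ifelse(nodes %in% called, 1e-6, 0.5),
    q = ifelse(nodes %in% called, 1e-5, 0.6),
    direction = direction,
    called = nodes %in% called
  )
  structure(tb, class = c("dasc_result", class(tb)),
            cohort = cohort, alpha = 0.05, min_effect = 0.1)
}
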