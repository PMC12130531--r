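#' Specification for synthetic networks and cohorts
#'
#' Bundles every knob of the synthetic benchmark: an Erdos--Renyi-style
#' signed directed network (optionally with spliced-in chain and
#' toggle-switch motifs) and two-group expression cohorts in which a
#' planted subset of nodes carries a group-shifted capacity plus additive
#' Gaussian observation noise. All generator output is bit-reproducible
#' given the spec (the seed is mandatory).
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param density Probability of each directed link (no self-loops).
#' @param activation_frac Fraction of links that activate (the rest
#'   inhibit).
#' @param n_toggles Number of toggle-switch motifs (mutual inhibition
#'   2-cycles) spliced onto dedicated node pairs.
#' @param n_chains,chain_len Number and length of activation chains
#'   spliced onto dedicated nodes.
#' @param n_per_group Samples per phenotype group.
#' @param planted Either how many nodes to plant differential signal in,
#'   or a character vector of node ids.
#' @param shift Capacity difference added to group B at planted nodes,
#'   in `(0, 1]` (clipped into `[0, 1]`).
#' @param noise_sd Standard deviation of additive observation noise on
#'   the `[0, 1]` capacity scale.
#' @param seed Master seed (required).
#' @return A validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_nodes = 50, density = 0.04, activation_frac = 0.7,
                       n_toggles = 0, n_chains = 0, chain_len = 3,
                       n_per_group = 20, planted = 5, shift = 0.3,
                       noise_sd = 0.05, seed) {
  if (missing(seed)) abort_validation("`seed` is required in a synth_spec")
  check_number(n_nodes, "n_nodes", 2, Inf)
  check_number(density, "density", 0, 1, open_lower = TRUE)
  check_number(activation_frac, "activation_frac", 0, 1)
  check_number(n_toggles, "n_toggles", 0, Inf)
  check_number(n_chains, "n_chains", 0, Inf)
  check_number(chain_len, "chain_len", 2, Inf)
  check_number(n_per_group, "n_per_group", 1, Inf)
  check_number(shift, "shift", 0, 1, open_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0, Inf)
  motif_nodes <- 2 * n_toggles + n_chains * chain_len
  if (motif_nodes > n_nodes) {
    abort_validation(sprintf(
      "infeasible spec: motifs need %d dedicated nodes but n_nodes = %d",
      motif_nodes, n_nodes
    ))
  }
  if (is.numeric(planted)) check_number(planted, "planted", 0, n_nodes)
  structure(list(
    n_nodes = as.integer(n_nodes), density = density,
    activation_frac = activation_frac,
    n_toggles = as.integer(n_toggles), n_chains = as.integer(n_chains),
    chain_len = as.integer(chain_len),
    n_per_group = as.integer(n_per_group), planted = planted,
    shift = shift, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synth_spec")
}

#' Generate a synthetic signed network
#'
#' Independent Bernoulli(density) draws over all ordered node pairs
#' (no self-loops), each realized link activating with probability
#' `activation_frac`; requested motifs are then spliced onto dedicated
#' nodes (reserved from the random part, so a toggle really is a clean
#' mutual-inhibition 2-cycle).
#'
#' @param spec A [synth_spec()].
#' @return List with `network` (a [signed_network]) and `truth`
#'   (generator ground truth: link table, motif node assignments, counts).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  nodes <- sprintf("N%03d", seq_len(spec$n_nodes))
  n_reserved <- 2 * spec$n_toggles + spec$n_chains * spec$chain_len
  reserved <- nodes[seq_len(n_reserved)]
  free <- setdiff(nodes, reserved)
  links <- withr::with_seed(derive_seed(spec$seed, 11L), {
    pairs <- expand.grid(source = free, target = free,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    hit <- runif(nrow(pairs)) < spec$density
    pairs <- pairs[hit, ]
    pairs$sign <- ifelse(runif(nrow(pairs)) < spec$activation_frac,
                         "activation", "inhibition")
    pairs
  })
  toggles <- list()
  chains <- list()
  extra <- list()
  pos <- 1L
  for (t in seq_len(spec$n_toggles)) {
    a <- reserved[pos]; b <- reserved[pos + 1L]; pos <- pos + 2L
    toggles[[t]] <- c(a, b)
    extra[[length(extra) + 1L]] <- data.frame(
      source = c(a, b), target = c(b, a),
      sign = "inhibition", stringsAsFactors = FALSE
    )
  }
  for (cn in seq_len(spec$n_chains)) {
    path <- reserved[pos:(pos + spec$chain_len - 1L)]
    pos <- pos + spec$chain_len
    chains[[cn]] <- path
    extra[[length(extra) + 1L]] <- data.frame(
      source = path[-length(path)], target = path[-1],
      sign = "activation", stringsAsFactors = FALSE
    )
  }
  all_links <- bind_rows(c(list(links), extra))
  if (nrow(all_links) == 0) {
    abort_validation("infeasible spec: density too low, no links generated")
  }
  all_links$weight <- 1
  net <- signed_network(all_links, nodes = nodes)
  truth <- list(
    spec = spec, nodes = nodes,
    toggles = toggles, chains = chains,
    n_random_links = nrow(links),
    planted = planted_nodes_for(net, spec)
  )
  list(network = net, truth = truth)
}

# Deterministic planted-node choice shared by all cohorts of one spec.
# Differential signal is planted at input nodes (expression is the sole
# determinant of their activity, matching "group-shifted upstream
# expression"); if there are fewer input nodes than requested, the
# remaining slots go to the nodes with fewest incoming links.
planted_nodes_for <- function(net, spec) {
  if (is.character(spec$planted)) {
    bad <- setdiff(spec$planted, net$nodes)
    if (length(bad) > 0) {
      abort_validation(sprintf("planted node(s) not in network: %s",
                               paste(bad, collapse = ", ")))
    }
    return(sort_c(spec$planted))
  }
  k <- as.integer(spec$planted)
  if (k == 0) return(character())
  candidates <- input_nodes(net)
  chosen <- if (length(candidates) >= k) {
    withr::with_seed(derive_seed(spec$seed, 777L),
                     sample(sort_c(candidates), k))
  } else {
    indeg <- table(factor(net$links$target, levels = net$nodes))
    rest <- setdiff(net$nodes, candidates)
    rest <- rest[order(as.integer(indeg[rest]), rest, method = "radix")]
    c(candidates, rest[seq_len(k - length(candidates))])
  }
  sort_c(chosen)
}

#' Generate one two-group expression cohort
#'
#' Per node, a baseline capacity is drawn uniformly on `(0.2, 0.8)`;
#' group B additionally receives `+shift` (clipped into `[0, 1]`) at the
#' planted nodes. Each sample observes `capacity + N(0, noise_sd)`,
#' clipped. The capacity-scale observations are returned twice: as
#' `normalized` (already on `[0, 1]`, ready for [build_parameters()]) and
#' as `expression`, pushed through the inverse of a per-gene min--max map
#' (random affine anchors) to emulate raw measurements --
#' [normalize_expression()] recovers the capacity-scale values up to the
#' per-gene observed-range affine factor (exactly affinely, correlation 1
#' within each gene).
#'
#' @param net A [signed_network] (usually from [generate_network()]).
#' @param spec The [synth_spec()].
#' @param seed Cohort seed; defaults to the spec seed. Give each cohort
#'   of a multi-cohort study its own seed.
#' @param cohort Cohort identifier.
#' @return List with `expression` (raw-scale tibble), `normalized`
#'   (capacity-scale tibble with the normalized attribute set), `labels`
#'   (tibble `sample`, `group` with groups `"A"`/`"B"`), and `truth`
#'   (baseline and per-group capacities, planted nodes and direction,
#'   observation matrix, affine anchors, parameter echo).
#' @export
generate_cohort <- function(net, spec, seed = spec$seed, cohort = "cohort1") {
  stopifnot(inherits(net, "signed_network"), inherits(spec, "synth_spec"))
  nodes <- net$nodes
  N <- length(nodes)
  n <- spec$n_per_group
  planted <- planted_nodes_for(net, spec)
  baseline <- withr::with_seed(derive_seed(seed, 21L),
                               runif(N, 0.2, 0.8))
  names(baseline) <- nodes
  cap_a <- baseline
  cap_b <- baseline
  cap_b[planted] <- clamp01(cap_b[planted] + spec$shift)
  samples <- sprintf("S%02d", seq_len(2 * n))
  groups <- rep(c("A", "B"), each = n)
  cap <- cbind(matrix(cap_a, N, n), matrix(cap_b, N, n))
  dimnames(cap) <- list(nodes, samples)
  noise <- withr::with_seed(derive_seed(seed, 22L),
                            matrix(rnorm(N * 2 * n, 0, spec$noise_sd), N))
  obs <- clamp01(cap + noise)
  anchors <- withr::with_seed(derive_seed(seed, 23L), {
    list(lo = runif(N, 0, 10), span = runif(N, 5, 50))
  })
  raw <- anchors$lo + obs * anchors$span
  expression <- dplyr::bind_cols(tibble(gene = nodes),
                                 as_tibble(as.data.frame(raw)))
  normalized <- dplyr::bind_cols(tibble(gene = nodes),
                                 as_tibble(as.data.frame(obs)))
  attr(normalized, "normalized") <- TRUE
  labels <- tibble(sample = samples, group = groups)
  truth <- list(
    cohort = cohort, seed = seed, spec = spec,
    baseline = baseline,
    capacity = list(A = cap_a, B = cap_b),
    observations = obs,
    planted = planted,
    direction = "up-in-B",
    anchors = anchors
  )
  list(expression = expression, normalized = normalized,
       labels = labels, truth = truth)
}

#' Generate a multi-cohort synthetic study
#'
#' One network, several cohorts with independent cohort seeds but a
#' shared planted-node set: the desk-scale stand-in for running the same
#' signaling analysis on several patient databases.
#'
#' @param spec A [synth_spec()].
#' @param cohort_seeds Integer vector, one seed per cohort.
#' @return List with `network`, `network_truth` and `cohorts` (a named
#'   list of [generate_cohort()] outputs).
#' @export
generate_study <- function(spec, cohort_seeds) {
  gn <- generate_network(spec)
  cohorts <- lapply(seq_along(cohort_seeds), function(i) {
    generate_cohort(gn$network, spec, seed = cohort_seeds[i],
                    cohort = paste0("cohort", i))
  })
  names(cohorts) <- paste0("cohort", seq_along(cohort_seeds))
  list(network = gn$network, network_truth = gn$truth, cohorts = cohorts)
}
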