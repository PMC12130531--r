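#' Pool Monte-Carlo activities by phenotype group
#'
#' Concatenates, per node, the steady-state draws of every sample in each
#' of the two groups (samples taken in sorted-id order, runs in run order,
#' so pooling is invariant to label-row order). Pools larger than
#' `max_per_group` draws are thinned by a deterministic stride
#' (`floor(available / cap)`), bounding memory without biasing the
#' distribution.
#'
#' @param activities List of `activity_distribution` objects (one per
#'   sample) from [monte_carlo_activities()].
#' @param labels Data frame with columns `sample` and `group`; every
#'   simulated sample must be labeled and both groups must be non-empty.
#' @param max_per_group Thinning cap on draws per group per node.
#' @param cohort Optional cohort identifier carried to outputs.
#' @return An object of class `grouped_activities`: per-group pooled
#'   matrices (nodes x draws), group names (sorted; the first is the
#'   reference group "A"), and per-group sample counts (the independent
#'   units used for significance downstream).
#' @export
pool_by_group <- function(activities, labels, max_per_group = 10000,
                          cohort = NA_character_) {
  stopifnot(is.list(activities), length(activities) > 0)
  labels <- as_tibble(labels)
  if (!all(c("sample", "group") %in% names(labels))) {
    abort_validation("labels must have columns 'sample' and 'group'")
  }
  ids <- vapply(activities, function(a) a$sample, character(1))
  if (anyDuplicated(ids)) abort_validation("duplicate sample ids in activities")
  lab <- setNames(as.character(labels$group), as.character(labels$sample))
  unlabeled <- setdiff(ids, names(lab))
  if (length(unlabeled) > 0) {
    abort_validation(sprintf("unlabeled sample(s): %s",
                             paste(head(unlabeled, 5), collapse = ", ")))
  }
  groups <- sort_c(unique(unname(lab[ids])))
  if (length(groups) != 2) {
    abort_validation(sprintf("need exactly 2 groups among simulated samples, got %d",
                             length(groups)))
  }
  names(activities) <- ids
  pools <- lapply(groups, function(g) {
    members <- sort_c(ids[lab[ids] == g])
    m <- do.call(cbind, lapply(activities[members], function(a) a$activities))
    if (ncol(m) > max_per_group) {
      stride <- max(1L, floor(ncol(m) / max_per_group))
      m <- m[, seq.int(1L, by = stride, length.out = max_per_group),
             drop = FALSE]
    }
    m
  })
  n_samples <- vapply(groups, function(g) sum(lab[ids] == g), integer(1))
  structure(list(
    cohort = cohort,
    groups = groups,
    pool_a = pools[[1]],
    pool_b = pools[[2]],
    n_samples = setNames(n_samples, groups)
  ), class = "grouped_activities")
}

#' @export
print.grouped_activities <- function(x, ...) {
  cat(sprintf(
    "<grouped_activities> cohort %s: %d nodes; %s: %d samples / %d draws, %s: %d samples / %d draws\n",
    x$cohort, nrow(x$pool_a),
    x$groups[1], x$n_samples[1], ncol(x$pool_a),
    x$groups[2], x$n_samples[2], ncol(x$pool_b)
  ))
  invisible(x)
}

#' @method tidy grouped_activities
#' @export
tidy.grouped_activities <- function(x, ...) {
  bind_rows(
    tibble(node = rep(rownames(x$pool_a), ncol(x$pool_a)),
           group = x$groups[1], activity = as.vector(x$pool_a)),
    tibble(node = rep(rownames(x$pool_b), ncol(x$pool_b)),
           group = x$groups[2], activity = as.vector(x$pool_b))
  )
}

# Two-sample KS statistic D = sup_t |ECDF_A(t) - ECDF_B(t)|, tie-exact,
# by a single sorted merge of both pools.
ks_statistic <- function(a, b) {
  n <- length(a)
  m <- length(b)
  z <- c(a, b)
  o <- order(z, method = "radix")
  w <- c(rep(1 / n, n), rep(-1 / m, m))[o]
  cw <- cumsum(w)
  zs <- z[o]
  # evaluate only at the last occurrence of each distinct value
  keep <- c(diff(zs) != 0, TRUE)
  max(abs(cw[keep]))
}

# Asymptotic two-sample KS p-value at effective sizes (na, nb): the
# Kolmogorov distribution Q(lambda) with lambda = sqrt(na nb/(na+nb)) D,
# using the alternating series for large lambda and the theta-function
# expansion for small lambda (numerically stable near p = 1).
ks_p_asymptotic <- function(D, na, nb) {
  ne <- na * nb / (na + nb)
  lambda <- sqrt(ne) * D
  if (lambda < 1e-10) return(1)
  if (lambda < 1) {
    # P(K <= lambda) via theta expansion, p = 1 - that
    k <- 1:20
    s <- sum(exp(-((2 * k - 1)^2) * pi^2 / (8 * lambda^2)))
    p <- 1 - sqrt(2 * pi) / lambda * s
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  min(max(p, 0), 1)
}

#' Score one node's group difference
#'
#' Computes the two-sample Kolmogorov--Smirnov statistic `D` between the
#' pooled activity draws of the two groups, the median difference
#' `median(B) - median(A)`, and an asymptotic KS p-value. Because pooled
#' Monte-Carlo draws from one patient are not independent observations,
#' the p-value is evaluated at effective sample sizes equal to the number
#' of patients per group (the default when `n_eff_a`/`n_eff_b` are not
#' given is the pool lengths, appropriate only for genuinely independent
#' pools). These p-values rank nodes; the effect gate and the
#' cross-cohort intersection carry the inferential weight.
#'
#' @param pool_a,pool_b Numeric vectors of pooled activities (non-empty).
#' @param n_eff_a,n_eff_b Effective (independent-unit) sample sizes for
#'   the p-value.
#' @return One-row tibble with columns `D`, `delta_median`, `p`.
#' @examples
#' score_node(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)) # D = 1/3
#' @export
score_node <- function(pool_a, pool_b,
                       n_eff_a = length(pool_a), n_eff_b = length(pool_b)) {
  if (length(pool_a) == 0 || length(pool_b) == 0) {
    abort_validation("both pools must be non-empty")
  }
  D <- ks_statistic(pool_a, pool_b)
  tibble(
    D = D,
    delta_median = median(pool_b) - median(pool_a),
    p = ks_p_asymptotic(D, n_eff_a, n_eff_b)
  )
}

#' Call differentially activated signaling components (DASCs)
#'
#' Scores every node of a [pool_by_group()] object, adjusts p-values by
#' Benjamini--Hochberg across the cohort's nodes, and calls a node a DASC
#' when `q < alpha` and `|delta_median| >= min_effect`. The direction is
#' `"up-in-B"` for a positive median shift (second group higher), else
#' `"up-in-A"`; group names are recorded in the result's attributes.
#' Significance uses patient-level effective sample sizes (see
#' [score_node()]).
#'
#' @param grouped A `grouped_activities` object.
#' @param alpha FDR threshold (default 0.05).
#' @param min_effect Minimum absolute median difference (default 0.1); on
#'   huge pooled draws tiny shifts become nominally significant, so calls
#'   are additionally gated on effect size.
#' @return A `dasc_result` tibble: `node`, `D`, `delta_median`, `p`, `q`,
#'   `direction`, `called`; attributes record cohort, groups, thresholds
#'   and per-group sample counts.
#' @export
call_dascs <- function(grouped, alpha = 0.05, min_effect = 0.1) {
  stopifnot(inherits(grouped, "grouped_activities"))
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE)
  check_number(min_effect, "min_effect", 0, 1)
  nodes <- rownames(grouped$pool_a)
  na <- grouped$n_samples[[1]]
  nb <- grouped$n_samples[[2]]
  scores <- lapply(nodes, function(nd) {
    score_node(grouped$pool_a[nd, ], grouped$pool_b[nd, ],
               n_eff_a = na, n_eff_b = nb)
  })
  out <- dplyr::bind_cols(tibble(node = nodes), bind_rows(scores))
  out$q <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$delta_median > 0, "up-in-B", "up-in-A")
  out$called <- out$q < alpha & abs(out$delta_median) >= min_effect
  out <- out[order(out$node, method = "radix"), ]
  structure(
    out,
    class = c("dasc_result", class(out)),
    cohort = grouped$cohort,
    groups = grouped$groups,
    alpha = alpha,
    min_effect = min_effect,
    n_samples = grouped$n_samples,
    p_note = "p-values use patient-level effective n; pooled draws are dependent"
  )
}

#' @method tidy dasc_result
#' @export
tidy.dasc_result <- function(x, ...) {
  out <- x
  attributes(out)[c("cohort", "groups", "alpha", "min_effect",
                    "n_samples", "p_note")] <- NULL
  class(out) <- setdiff(class(out), "dasc_result")
  as_tibble(out)
}

#' @method glance dasc_result
#' @export
glance.dasc_result <- function(x, ...) {
  tibble(
    cohort = attr(x, "cohort"),
    nodes = nrow(x),
    called = sum(x$called),
    up_in_a = sum(x$called & x$direction == "up-in-A"),
    up_in_b = sum(x$called & x$direction == "up-in-B"),
    alpha = attr(x, "alpha"),
    min_effect = attr(x, "min_effect")
  )
}

#' Intersect DASC calls across cohorts
#'
#' Returns the nodes called in every cohort, by default additionally
#' requiring the direction of activation to agree across cohorts. The
#' result is independent of the order in which cohorts are supplied.
#'
#' @param results Named list (>= 2) of `dasc_result` objects; unnamed
#'   lists get names `cohort1, cohort2, ...` in supplied order.
#' @param require_concordant Drop nodes whose direction differs between
#'   cohorts (default `TRUE`).
#' @return Tibble with one row per (common node, cohort): `node`,
#'   `cohort`, `D`, `delta_median`, `q`, `direction`; attribute
#'   `common_nodes` holds the intersected node set. Warns when cohorts
#'   score disjoint node universes.
#' @export
intersect_cohorts <- function(results, require_concordant = TRUE) {
  stopifnot(is.list(results), length(results) >= 2)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("cohort", seq_along(results))
  }
  results <- results[sort_c(names(results))]
  universes <- lapply(results, function(r) r$node)
  shared_universe <- Reduce(intersect, universes)
  if (length(shared_universe) == 0) {
    warn(sprintf(
      "cohorts have disjoint node universes (sizes: %s); nothing can intersect",
      paste(sprintf("%s=%d", names(results), lengths(universes)),
            collapse = ", ")
    ))
  }
  called_sets <- lapply(results, function(r) r$node[r$called])
  common <- sort_c(Reduce(intersect, called_sets))
  if (require_concordant && length(common) > 0) {
    dirs <- vapply(common, function(nd) {
      d <- vapply(results, function(r) r$direction[r$node == nd], character(1))
      length(unique(d)) == 1L
    }, logical(1))
    common <- common[dirs]
  }
  rows <- purrr::imap(results, function(r, nm) {
    r <- tidy(r)
    r <- r[r$node %in% common, c("node", "D", "delta_median", "q", "direction")]
    tibble(node = r$node, cohort = nm, D = r$D,
           delta_median = r$delta_median, q = r$q, direction = r$direction)
  })
  out <- bind_rows(rows)
  out <- out[order(out$node, out$cohort, method = "radix"), ]
  structure(out, common_nodes = common)
}

#' Write / read per-cohort DASC tables
#'
#' TSV with columns `node`, `D`, `delta_median`, `p`, `q`, `direction`,
#' `called`.
#'
#' @param x A `dasc_result`.
#' @param path File path.
#' @export
write_dasc_tsv <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dasc_tsv
#' @param alpha,min_effect Thresholds recorded on the re-read object.
#' @param cohort Cohort id recorded on the re-read object.
#' @export
read_dasc_tsv <- function(path, cohort = NA_character_, alpha = 0.05,
                          min_effect = 0.1) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(out, class = c("dasc_result", class(out)), cohort = cohort,
            alpha = alpha, min_effect = min_effect)
}
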