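make_ad <- function(sample, values) {
  # values: nodes x runs matrix with rownames
  structure(list(sample = sample, activities = values,
                 n_init = ncol(values), convergence_rate = 1),
            class = "activity_distribution")
}

two_group_acts <- function(n_per_group = 2, n_runs = 100, nodes = c("X", "Y"),
                           shift_node = NULL, shift = 0) {
  samples <- sprintf("S%02d", seq_len(2 * n_per_group))
  labels <- tibble::tibble(
    sample = samples,
    group = rep(c("A", "B"), each = n_per_group)
  )
  acts <- lapply(seq_along(samples), function(i) {
    set.seed(i)
    m <- matrix(runif(length(nodes) * n_runs), length(nodes),
                dimnames = list(nodes, NULL))
    if (!is.null(shift_node) && labels$group[i] == "B") {
      m[shift_node, ] <- pmin(1, m[shift_node, ] + shift)
    }
    make_ad(samples[i], m)
  })
  list(acts = acts, labels = labels)
}

test_that("pooling counts draws and is invariant to label order", {
  tg <- two_group_acts(n_per_group = 2, n_runs = 100)
  g <- pool_by_group(tg$acts, tg$labels)
  expect_equal(ncol(g$pool_a), 200)
  expect_equal(ncol(g$pool_b), 200)
  expect_equal(unname(g$n_samples), c(2L, 2L))

  shuffled <- tg$labels[c(3, 1, 4, 2), ]
  g2 <- pool_by_group(tg$acts[c(2, 4, 1, 3)], shuffled)
  expect_identical(g$pool_a, g2$pool_a)
  expect_identical(g$pool_b, g2$pool_b)
})

test_that("pool thinning takes a deterministic stride", {
  tg <- two_group_acts(n_per_group = 1, n_runs = 200)
  g <- pool_by_group(tg$acts, tg$labels, max_per_group = 50)
  expect_equal(ncol(g$pool_a), 50)
  full <- tg$acts[[1]]$activities
  expect_identical(g$pool_a, full[, seq(1, by = 4, length.out = 50)])
})

test_that("pooling rejects unlabeled samples and degenerate groups", {
  tg <- two_group_acts()
  expect_error(pool_by_group(tg$acts, tg$labels[-1, ]), "S01",
               class = "netdasc_validation_error")
  one <- tg$labels
  one$group <- "A"
  expect_error(pool_by_group(tg$acts, one), "2 groups",
               class = "netdasc_validation_error")
})

test_that("KS statistic matches hand-derived and brute-force values", {
  expect_equal(score_node(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(score_node(c(0.1, 0.3, 0.4), c(0.6, 0.7, 0.9))$D, 1)
  expect_equal(score_node(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))$D, 1 / 3)

  set.seed(77)
  for (i in 1:60) {
    # discrete support forces ties within and across pools
    a <- sample(seq(0, 1, by = 0.1), sample(3:20, 1), replace = TRUE)
    b <- sample(seq(0, 1, by = 0.1), sample(3:20, 1), replace = TRUE)
    expect_equal(score_node(a, b)$D, ks_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("KS statistic is invariant under common monotone transforms", {
  set.seed(5)
  a <- runif(40)
  b <- runif(35)^2
  d0 <- score_node(a, b)$D
  expect_equal(score_node(a^2, b^2)$D, d0)
  expect_equal(score_node(log1p(a), log1p(b))$D, d0)
})

test_that("asymptotic KS p-value matches stats::ks.test", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(sample(20:60, 1))
    b <- rnorm(sample(20:60, 1), mean = runif(1, 0, 1))
    ours <- score_node(a, b)$p
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))$p.value
    # both evaluate the Kolmogorov series; truncation rules differ slightly
    expect_equal(ours, ref, tolerance = 1e-5)
  }
})

test_that("DASC calling gates on q and effect size with direction", {
  nodes <- c("N1", "N2")
  same <- matrix(rep(runif(50), each = 2), 2, dimnames = list(nodes, NULL))
  g0 <- pool_by_group(list(make_ad("a1", same), make_ad("b1", same)),
                      tibble::tibble(sample = c("a1", "b1"),
                                     group = c("A", "B")))
  r0 <- call_dascs(g0)
  expect_equal(sum(r0$called), 0)
  expect_true(all(r0$q >= r0$p))

  tg <- two_group_acts(n_per_group = 10, n_runs = 50,
                       nodes = c("N1", "N2", "N3"),
                       shift_node = "N2", shift = 0.9)
  g1 <- pool_by_group(tg$acts, tg$labels)
  r1 <- call_dascs(g1)
  expect_true(r1$called[r1$node == "N2"])
  expect_equal(r1$direction[r1$node == "N2"], "up-in-B")
  expect_equal(sum(r1$called), 1)
  expect_identical(tidy(r1)$q, r1$q)
  expect_equal(glance(r1)$called, 1)
})

test_that("cohort intersection with concordance filtering", {
  r1 <- fake_dasc(LETTERS[1:4], called = c("A", "B", "C"), cohort = "c1")
  r2 <- fake_dasc(LETTERS[1:4], called = c("B", "C"), cohort = "c2")
  r3 <- fake_dasc(LETTERS[1:5], called = c("B", "C", "D"), cohort = "c3")
  out <- intersect_cohorts(list(c1 = r1, c2 = r2, c3 = r3))
  expect_setequal(attr(out, "common_nodes"), c("B", "C"))

  # order independence
  out2 <- intersect_cohorts(list(c3 = r3, c1 = r1, c2 = r2))
  expect_identical(as.data.frame(out), as.data.frame(out2))

  # discordant direction excluded when concordance is required
  r2b <- fake_dasc(LETTERS[1:4], called = c("B", "C"),
                   direction = c("up-in-B", "up-in-A", "up-in-B", "up-in-B"),
                   cohort = "c2")
  strict <- intersect_cohorts(list(c1 = r1, c2 = r2b, c3 = r3))
  expect_setequal(attr(strict, "common_nodes"), "C")
  loose <- intersect_cohorts(list(c1 = r1, c2 = r2b, c3 = r3),
                             require_concordant = FALSE)
  expect_setequal(attr(loose, "common_nodes"), c("B", "C"))

  expect_warning(
    intersect_cohorts(list(fake_dasc(c("A", "B"), "A"),
                           fake_dasc(c("Y", "Z"), "Z"))),
    "disjoint"
  )
})

test_that("DASC tables survive the TSV round trip", {
  tg <- two_group_acts(n_per_group = 3, n_runs = 30)
  r <- call_dascs(pool_by_group(tg$acts, tg$labels))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_dasc_tsv(r, tmp)
  back <- read_dasc_tsv(tmp)
  expect_equal(back$node, r$node)
  expect_equal(back$D, r$D, tolerance = 1e-12)
  expect_equal(back$called, r$called)
})
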