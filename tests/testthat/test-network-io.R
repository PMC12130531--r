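test_that("SIGNOR parsing maps effects to signs and drops unknowns", {
  net <- read_signor(signor_fixture())
  expect_s3_class(net, "signed_network")
  # 5 rows: 2 up-regulates, 2 down-regulates, 1 unknown
  expect_equal(nrow(net$links), 4)
  expect_equal(sum(net$links$sign == "activation"), 2)
  expect_equal(sum(net$links$sign == "inhibition"), 2)
  expect_false("ITGB1" %in% net$nodes)  # only reached via the unknown row
  expect_true("SIGNOR-C1" %in% net$nodes)  # complexes kept as plain nodes

  act_only <- read_signor(signor_fixture(), keep_signs = "activation")
  expect_true(all(act_only$links$sign == "activation"))
})

test_that("duplicate rows collapse and parsing is order-independent", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "ENTITYA\tENTITYB\tEFFECT",
    "A\tB\tup-regulates",
    "A\tB\tup-regulates",
    "B\tC\tdown-regulates activity",
    "C\tA\tup-regulates quantity"
  )
  writeLines(rows, tmp)
  net1 <- read_signor(tmp)
  expect_equal(nrow(net1$links), 3)  # duplicate collapsed

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(rows[c(1, 5, 4, 3, 2)], tmp2)
  expect_identical(read_signor(tmp2), net1)
})

test_that("malformed SIGNOR input fails loudly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ENTITYA\tENTITYB\tNOTE", "A\tB\tx"), tmp)
  expect_error(read_signor(tmp), "EFFECT", class = "netdasc_format_error")

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ENTITYA\tENTITYB\tEFFECT", "A\tB\tunknown"), tmp2)
  expect_error(read_signor(tmp2), "empty network",
               class = "netdasc_format_error")
})

test_that("network summary counts are consistent", {
  s <- network_summary(chain_net())
  expect_equal(s$nodes, 3)
  expect_equal(s$links, 2)
  expect_equal(s$activation, 1)
  expect_equal(s$inhibition, 1)
  expect_equal(s$input_nodes, 1)
  expect_identical(input_nodes(chain_net()), "A")
  expect_equal(s$activation + s$inhibition, s$links)

  iso <- signed_network(data.frame(source = character(),
                                   target = character(),
                                   sign = character()),
                        nodes = c("X", "Y"))
  expect_setequal(input_nodes(iso), c("X", "Y"))
  expect_equal(network_summary(iso)$lcc_size, 1)
})

test_that("input nodes are exactly the indegree-zero nodes", {
  for (seed in 1:10) {
    net <- random_signed_net(15, density = 0.1, seed = seed)
    g <- igraph::graph_from_data_frame(
      net$links[, c("source", "target")], directed = TRUE,
      vertices = data.frame(name = net$nodes)
    )
    indeg <- igraph::degree(g, mode = "in")
    expect_setequal(input_nodes(net), names(indeg)[indeg == 0])
  }
})

test_that("SIF round trip preserves nodes, links and signs", {
  net <- signed_network(
    data.frame(source = c("A", "B", "B"), target = c("B", "C", "B"),
               sign = c("activation", "inhibition", "activation")),
    nodes = c("A", "B", "C", "LONER")
  )
  tmp <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, tmp)
  back <- read_sif(tmp)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$links, net$links)

  tmp2 <- withr::local_tempfile(fileext = ".sif")
  writeLines("A\tactivates\tB", tmp2)
  one <- read_sif(tmp2)
  expect_equal(nrow(one$links), 1)
  expect_equal(one$links$sign, "activation")

  tmp3 <- withr::local_tempfile(fileext = ".sif")
  writeLines("A\tbinds\tB", tmp3)
  expect_error(read_sif(tmp3), "binds", class = "netdasc_format_error")
})

test_that("internal TSV round trip preserves the link table", {
  net <- random_signed_net(12, density = 0.15, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, tmp)
  expect_identical(read_network_tsv(tmp)$links, net$links)
})

test_that("identifier hygiene: trimming, collisions, weights", {
  expect_error(
    signed_network(data.frame(source = c("A ", "A"), target = c("B", "C"),
                              sign = "activation")),
    "collision", class = "netdasc_format_error"
  )
  expect_error(
    signed_network(data.frame(source = "A", target = "B",
                              sign = "activation", weight = -1)),
    "weight", class = "netdasc_validation_error"
  )
  expect_error(
    signed_network(data.frame(source = "A", target = "B", sign = "binds")),
    "sign", class = "netdasc_format_error"
  )
})

test_that("largest weak component restriction works", {
  net <- signed_network(data.frame(
    source = c("A", "B", "X"),
    target = c("B", "C", "Y"),
    sign = "activation"
  ))
  lcc <- largest_component(net)
  expect_setequal(lcc$nodes, c("A", "B", "C"))
  expect_equal(network_summary(net)$lcc_size, 3)
})

test_that("network tidiers expose links and summary", {
  net <- chain_net()
  expect_identical(tidy(net), tibble::as_tibble(net$links))
  expect_identical(glance(net), network_summary(net))
})
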