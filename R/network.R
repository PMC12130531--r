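#' Construct a signed directed network
#'
#' A `signed_network` is the simulation substrate of the package: an ordered
#' node set plus a table of signed directed links. Node order is always
#' C-locale lexicographic so that state vectors, Monte-Carlo draws and all
#' downstream outputs are reproducible. Input nodes (nodes with no incoming
#' link) are always derived from the current link table, never stored.
#'
#' @param links A data frame with columns `source`, `target`, `sign`
#'   (`"activation"` or `"inhibition"`) and optionally `weight`
#'   (positive, default 1). Duplicate `(source, target, sign)` rows are
#'   collapsed to one link.
#' @param nodes Optional character vector of node identifiers; link
#'   endpoints are always included. Use this to carry isolated nodes.
#'
#' @return An object of class `signed_network` with elements `nodes`
#'   (sorted character vector) and `links` (tibble).
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("A", "B"), target = c("B", "C"),
#'   sign = c("activation", "inhibition")
#' ))
#' input_nodes(net)
#' @export
signed_network <- function(links, nodes = NULL) {
  links <- as_tibble(links)
  if (nrow(links) > 0) {
    required <- c("source", "target", "sign")
    miss <- setdiff(required, names(links))
    if (length(miss) > 0) {
      abort_format(sprintf("links table lacks column(s): %s",
                           paste(miss, collapse = ", ")))
    }
    if (!"weight" %in% names(links)) links$weight <- 1
    links <- links[, c("source", "target", "sign", "weight")]
    links$source <- trim_id(as.character(links$source))
    links$target <- trim_id(as.character(links$target))
    bad_sign <- setdiff(unique(links$sign), c("activation", "inhibition"))
    if (length(bad_sign) > 0) {
      abort_format(sprintf("unknown link sign(s): %s",
                           paste(bad_sign, collapse = ", ")))
    }
    if (any(!is.finite(links$weight)) || any(links$weight <= 0)) {
      abort_validation("link weights must be positive and finite")
    }
    if (any(links$source == "") || any(links$target == "")) {
      abort_format("empty node identifier in link table")
    }
    links <- links[!duplicated(links[, c("source", "target", "sign")]), ]
  } else {
    links <- tibble(source = character(), target = character(),
                    sign = character(), weight = numeric())
  }
  nodes <- sort_c(unique(c(
    if (!is.null(nodes)) trim_id(as.character(nodes)) else character(),
    links$source, links$target
  )))
  nodes <- nodes[nodes != ""]
  links <- links[order(links$source, links$target, links$sign,
                       method = "radix"), ]
  # rebuild to shed any stray attributes carried in from the input frame
  links <- tibble(source = links$source, target = links$target,
                  sign = links$sign, weight = as.numeric(links$weight))
  structure(list(nodes = nodes, links = links), class = "signed_network")
}

# Whitespace-trim identifiers; distinct raw ids that collide after trimming
# are an error (silent merging of e.g. "TP53" and "TP53 " would hide a
# malformed source file; a single consistent spelling passes through).
trim_id <- function(x) {
  tr <- trimws(x)
  changed <- unique(x[x != tr])
  if (length(changed) > 0) {
    clash <- changed[trimws(changed) %in% x]
    if (length(clash) > 0) {
      abort_format(sprintf(
        "identifier collision after whitespace trimming: %s",
        paste(utils::head(dQuote(clash, FALSE), 5), collapse = ", ")
      ))
    }
  }
  tr
}

#' @export
print.signed_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<signed_network> %d nodes, %d links (%d activation / %d inhibition), %d input nodes\n",
    s$nodes, s$links, s$activation, s$inhibition, s$input_nodes
  ))
  invisible(x)
}

#' Input nodes of a signed network
#'
#' Nodes with zero incoming links; these relax to their expression-derived
#' capacity and carry the patient-specific signal into the network.
#'
#' @param net A [signed_network].
#' @return Character vector of node identifiers.
#' @export
input_nodes <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  setdiff(net$nodes, unique(net$links$target))
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$links[, c("source", "target")],
    directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
}

#' Summarise a signed network
#'
#' @param net A [signed_network].
#' @return One-row tibble: node count, link count, counts by sign, input-node
#'   count and the size of the largest weakly connected component.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  lcc <- if (length(net$nodes) == 0) {
    0L
  } else {
    max(igraph::components(as_igraph(net), mode = "weak")$csize)
  }
  tibble(
    nodes = length(net$nodes),
    links = nrow(net$links),
    activation = sum(net$links$sign == "activation"),
    inhibition = sum(net$links$sign == "inhibition"),
    input_nodes = length(input_nodes(net)),
    lcc_size = as.integer(lcc)
  )
}

#' Restrict a network to its largest weakly connected component
#'
#' @param net A [signed_network].
#' @return A [signed_network] induced on the largest weak component
#'   (ties broken towards the lexicographically first member node).
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (length(net$nodes) == 0) return(net)
  comp <- igraph::components(as_igraph(net), mode = "weak")
  best <- which(comp$csize == max(comp$csize))[1]
  keep <- net$nodes[comp$membership == best]
  links <- net$links[net$links$source %in% keep & net$links$target %in% keep, ]
  signed_network(links, nodes = keep)
}

#' Read a SIGNOR-style causal-interaction table
#'
#' Parses a tab-delimited causal-interaction export into a [signed_network].
#' Effect strings containing `"up-regulates"` map to activation and
#' `"down-regulates"` to inhibition (substring match, so sub-annotations
#' such as `"up-regulates activity"` are absorbed); any other effect row
#' (e.g. `"unknown"`) is dropped. Entities that are complexes, families,
#' chemicals or phenotypes are kept as ordinary named nodes -- they may
#' simply lack expression later and then receive the default capacity.
#'
#' @param path Path to a TSV file with a header row.
#' @param col_a,col_b,col_effect Column names for the regulator entity, the
#'   regulated entity and the effect string.
#' @param keep_signs Which signs to retain after mapping.
#' @param lcc If `TRUE`, restrict to the largest weakly connected component.
#'
#' @return A [signed_network]. Duplicated `(source, target, sign)` rows are
#'   collapsed; self-loops are retained.
#' @export
read_signor <- function(path,
                        col_a = "ENTITYA", col_b = "ENTITYB",
                        col_effect = "EFFECT",
                        keep_signs = c("activation", "inhibition"),
                        lcc = FALSE) {
  keep_signs <- match.arg(keep_signs, several.ok = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols(.default = "c"))
  for (col in c(col_a, col_b, col_effect)) {
    if (!col %in% names(raw)) {
      abort_format(sprintf("input file lacks required column '%s'", col))
    }
  }
  effect <- raw[[col_effect]]
  sign <- rep(NA_character_, nrow(raw))
  sign[grepl("up-regulates", effect, fixed = TRUE)] <- "activation"
  sign[grepl("down-regulates", effect, fixed = TRUE)] <- "inhibition"
  keep <- !is.na(sign) & sign %in% keep_signs
  if (!any(keep)) abort_format("empty network: no links left after filtering")
  net <- signed_network(tibble(
    source = raw[[col_a]][keep],
    target = raw[[col_b]][keep],
    sign = sign[keep],
    weight = 1
  ))
  if (lcc) largest_component(net) else net
}

#' Write / read networks as SIF
#'
#' Simple-interaction-format export with relation tokens `activates` /
#' `inhibits`. Isolated nodes are written as single-token lines so the
#' round trip preserves the node set exactly.
#'
#' @param net A [signed_network].
#' @param path Output (input) file path.
#' @return `write_sif()` returns `path` invisibly; `read_sif()` returns a
#'   [signed_network].
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  rel <- ifelse(net$links$sign == "activation", "activates", "inhibits")
  lines <- paste(net$links$source, rel, net$links$target, sep = "\t")
  iso <- setdiff(net$nodes, c(net$links$source, net$links$target))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  n_tok <- lengths(parts)
  if (any(!n_tok %in% c(1L, 3L))) {
    abort_format("malformed SIF line: expected 1 or 3 whitespace-delimited tokens")
  }
  triples <- parts[n_tok == 3L]
  rel <- vapply(triples, `[[`, "", 2L)
  bad <- setdiff(unique(rel), c("activates", "inhibits"))
  if (length(bad) > 0) {
    abort_format(sprintf("unknown SIF relation token(s): %s",
                         paste(bad, collapse = ", ")))
  }
  links <- tibble(
    source = vapply(triples, `[[`, "", 1L),
    target = vapply(triples, `[[`, "", 3L),
    sign = ifelse(rel == "activates", "activation", "inhibition"),
    weight = 1
  )
  signed_network(links, nodes = unlist(parts[n_tok == 1L]))
}

#' Write / read the internal links TSV
#'
#' Four-column table (`source`, `target`, `sign`, `weight`) with a header;
#' the package's own interchange format between pipeline stages.
#'
#' @inheritParams write_sif
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  readr::write_tsv(net$links, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  links <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             source = "c", target = "c",
                             sign = "c", weight = "d"
                           ))
  signed_network(links)
}

#' @method tidy signed_network
#' @export
tidy.signed_network <- function(x, ...) as_tibble(x$links)

#' @method glance signed_network
#' @export
glance.signed_network <- function(x, ...) network_summary(x)
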