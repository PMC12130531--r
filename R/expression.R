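#' Normalize an expression matrix to the unit interval
#'
#' Per gene, values are winsorized at the (`lower_q`, `upper_q`)
#' cross-sample quantiles and then min--max scaled to `[0, 1]`, the scale
#' on which the dynamical model operates (0 = minimal, 1 = maximal
#' activity). Winsorizing guards single outlying samples from compressing
#' everyone else against 0 or 1. Genes with zero cross-sample range map to
#' 0.5 everywhere (no information, neutral capacity). The alternative
#' `method = "logistic"` z-scores each gene and squashes through the
#' standard logistic curve.
#'
#' Normalization is monotone within each gene (ties allowed at the clip
#' boundaries), and re-normalizing an already-normalized table with
#' quantiles `(0, 1)` is the identity.
#'
#' @param expr Data frame whose first column holds gene identifiers and
#'   whose remaining columns are numeric per-sample values (one column per
#'   sample). This is the layout of the expression TSV: first column gene
#'   id, header row of sample ids.
#' @param lower_q,upper_q Winsorizing quantiles, `0 <= lower_q < upper_q <= 1`.
#' @param method `"winsor"` (default) or `"logistic"`.
#'
#' @return A tibble of the same shape with values in `[0, 1]` and attribute
#'   `normalized = TRUE`.
#' @examples
#' expr <- data.frame(gene = c("A", "B"), s1 = c(2, 5), s2 = c(4, 5), s3 = c(6, 5))
#' normalize_expression(expr, 0, 1)
#' @export
normalize_expression <- function(expr, lower_q = 0.01, upper_q = 0.99,
                                 method = c("winsor", "logistic")) {
  method <- match.arg(method)
  check_number(lower_q, "lower_q", 0, 1)
  check_number(upper_q, "upper_q", 0, 1)
  if (lower_q >= upper_q) abort_validation("`lower_q` must be < `upper_q`")
  expr <- as_tibble(expr)
  if (nrow(expr) == 0 || ncol(expr) < 2) {
    abort_validation("empty expression matrix: need >= 1 gene and >= 1 sample")
  }
  genes <- as.character(expr[[1]])
  if (anyDuplicated(genes)) {
    abort_validation(sprintf("duplicate gene identifier(s): %s",
                             paste(head(unique(genes[duplicated(genes)]), 5),
                                   collapse = ", ")))
  }
  samples <- names(expr)[-1]
  if (anyDuplicated(samples)) abort_validation("duplicate sample identifiers")
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) abort_validation("expression values must be numeric")
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)
    cells <- paste0(genes[idx[, 1]], "/", samples[idx[, 2]])
    abort_validation(sprintf("non-finite expression value(s) at: %s",
                             paste(head(cells, 10), collapse = ", ")))
  }
  norm <- apply(m, 1L, function(v) {
    if (method == "winsor") {
      lo <- as.numeric(quantile(v, lower_q))
      hi <- as.numeric(quantile(v, upper_q))
      if (hi - lo <= 0) return(rep(0.5, length(v)))
      (pmin(pmax(v, lo), hi) - lo) / (hi - lo)
    } else {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) return(rep(0.5, length(v)))
      1 / (1 + exp(-(v - mean(v)) / s))
    }
  })
  # apply() returns a vector for a single-sample table, else samples x genes
  norm <- if (is.null(dim(norm))) matrix(norm, ncol = 1L) else t(norm)
  out <- as_tibble(as.data.frame(norm))
  names(out) <- samples
  out <- dplyr::bind_cols(expr[, 1, drop = FALSE], out)
  attr(out, "normalized") <- TRUE
  out
}

#' Default model parameters
#'
#' Shared defaults for the normalized-HillCube model: unit time constants
#' and link weights, Hill exponent 3 and threshold 0.5 (a sigmoidal link
#' response centered mid-scale), and a neutral capacity of 0.5 for network
#' nodes absent from the expression table (complexes, families, chemicals).
#'
#' @param tau Per-node time constant, `> 0`.
#' @param hill_n Hill exponent, `>= 1`.
#' @param hill_k Hill threshold, in `(0, 1)`.
#' @param default_capacity Capacity assigned to unmeasured nodes, in `[0, 1]`.
#' @return A named list.
#' @export
model_defaults <- function(tau = 1, hill_n = 3, hill_k = 0.5,
                           default_capacity = 0.5) {
  check_number(tau, "tau", 0, Inf, open_lower = TRUE)
  check_number(hill_n, "hill_n", 1, Inf)
  check_number(hill_k, "hill_k", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(default_capacity, "default_capacity", 0, 1)
  list(tau = tau, hill_n = hill_n, hill_k = hill_k,
       default_capacity = default_capacity)
}

#' Construct model parameters directly
#'
#' Low-level constructor binding a network to explicit per-node capacities;
#' [build_parameters()] is the expression-driven front end.
#'
#' @param net A [signed_network].
#' @param capacity Either a single number in `[0, 1]` recycled to all nodes
#'   or a named numeric vector covering every node.
#' @param defaults A [model_defaults()] list.
#' @param sample Optional sample identifier carried through to outputs.
#' @param matched_fraction Fraction of nodes whose capacity came from data.
#' @return An object of class `model_params`.
#' @export
model_parameters <- function(net, capacity = 0.5, defaults = model_defaults(),
                             sample = NA_character_, matched_fraction = NA_real_) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  if (length(capacity) == 1L && is.null(names(capacity))) {
    capacity <- setNames(rep(as.numeric(capacity), n), net$nodes)
  } else {
    miss <- setdiff(net$nodes, names(capacity))
    if (length(miss) > 0) {
      abort_validation(sprintf("capacity missing for node(s): %s",
                               paste(head(miss, 5), collapse = ", ")))
    }
    capacity <- setNames(as.numeric(capacity[net$nodes]), net$nodes)
  }
  if (any(!is.finite(capacity)) || any(capacity < 0 | capacity > 1)) {
    abort_validation("capacities must lie in [0, 1]")
  }
  structure(list(
    network = net,
    capacity = capacity,
    tau = defaults$tau,
    hill_n = defaults$hill_n,
    hill_k = defaults$hill_k,
    sample = sample,
    matched_fraction = matched_fraction
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> sample %s: %d nodes, tau=%g, hill_n=%g, hill_k=%g, matched %.1f%%\n",
    x$sample, length(x$capacity), x$tau, x$hill_n, x$hill_k,
    100 * x$matched_fraction
  ))
  invisible(x)
}

#' @method tidy model_params
#' @export
tidy.model_params <- function(x, ...) {
  tibble(node = names(x$capacity), capacity = unname(x$capacity),
         input = names(x$capacity) %in% input_nodes(x$network))
}

#' Bind one sample's expression profile to a network
#'
#' For each network node present in the (case-insensitively matched)
#' gene column, the node capacity `e_i` is that gene's normalized value in
#' the chosen sample; absent nodes receive the neutral default. Expression
#' enters the model as a capacity bounding the node's regulatory drive,
#' not as an initial condition -- initial conditions are randomized per
#' Monte-Carlo run, so the patient-specific profile must shape the vector
#' field itself.
#'
#' @param net A [signed_network].
#' @param expr A normalized expression table from [normalize_expression()].
#' @param sample Sample (column) identifier.
#' @param defaults A [model_defaults()] list.
#' @return A `model_params` object; its `matched_fraction` element records
#'   the fraction of network nodes found in the expression table.
#' @export
build_parameters <- function(net, expr, sample, defaults = model_defaults()) {
  stopifnot(inherits(net, "signed_network"))
  if (!isTRUE(attr(expr, "normalized"))) {
    abort_validation("expression table is not normalized; call normalize_expression() first")
  }
  if (!sample %in% names(expr)[-1]) {
    abort_validation(sprintf("sample '%s' not found in expression table", sample))
  }
  genes <- toupper(as.character(expr[[1]]))
  vals <- setNames(expr[[sample]], genes)
  key <- toupper(net$nodes)
  hit <- key %in% genes
  capacity <- setNames(rep(defaults$default_capacity, length(net$nodes)),
                       net$nodes)
  capacity[hit] <- as.numeric(vals[key[hit]])
  model_parameters(net, capacity, defaults = defaults, sample = sample,
                   matched_fraction = mean(hit))
}

#' Read / write expression and label tables
#'
#' Expression TSV: first column gene id, header row of sample ids.
#' Labels TSV: columns `sample` and `group`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_expression_tsv
#' @export
read_labels_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("sample", "group") %in% names(out))) {
    abort_format("labels table must have columns 'sample' and 'group'")
  }
  out
}
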