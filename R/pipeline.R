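# File-based pipeline driver: network -> normalize -> simulate -> dasc ->
# intersect, with strict config validation, per-stage resume, a run log
# and a reproducibility manifest.

config_schema <- function() {
  list(
    paths = c("network", "network_format", "out_dir"),
    cohort = c("name", "expression", "labels"),
    model = c("tau", "hill_n", "hill_k", "default_capacity",
              "lower_q", "upper_q"),
    simulation = c("n_init", "dt", "t_max", "tol", "seed"),
    dasc = c("alpha", "min_effect", "max_per_group", "require_concordant"),
    top = c("paths", "cohorts", "model", "simulation", "dasc")
  )
}

#' Default pipeline configuration
#'
#' @param network Path to the network file.
#' @param cohorts List of lists with `name`, `expression`, `labels` paths.
#' @param out_dir Output directory.
#' @param seed Simulation master seed.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(network, cohorts, out_dir, seed = 1L) {
  list(
    paths = list(network = network, network_format = "tsv",
                 out_dir = out_dir),
    cohorts = cohorts,
    model = list(tau = 1, hill_n = 3, hill_k = 0.5, default_capacity = 0.5,
                 lower_q = 0.01, upper_q = 0.99),
    simulation = list(n_init = 1000, dt = 0.1, t_max = 100, tol = 1e-6,
                      seed = as.integer(seed)),
    dasc = list(alpha = 0.05, min_effect = 0.1, max_per_group = 10000,
                require_concordant = TRUE)
  )
}

#' Validate a pipeline configuration
#'
#' Strict schema validation: unknown keys are rejected (a typo'd key must
#' fail loudly, not be silently ignored) and every numeric field is
#' range-checked. Errors name the offending field.
#'
#' @param config Nested list (or path to a YAML file).
#' @return The validated config, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sch <- config_schema()
  reject_unknown <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      abort_validation(sprintf("unknown config key(s) in %s: %s",
                               where, paste(extra, collapse = ", ")))
    }
  }
  reject_unknown(config, sch$top, "top level")
  for (key in c("paths", "cohorts", "model", "simulation", "dasc")) {
    if (is.null(config[[key]])) {
      abort_validation(sprintf("config section '%s' is missing", key))
    }
  }
  reject_unknown(config$paths, sch$paths, "paths")
  reject_unknown(config$model, sch$model, "model")
  reject_unknown(config$simulation, sch$simulation, "simulation")
  reject_unknown(config$dasc, sch$dasc, "dasc")
  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    reject_unknown(co, config_schema()$cohort, sprintf("cohorts[[%d]]", i))
    for (f in c("name", "expression", "labels")) {
      if (is.null(co[[f]])) {
        abort_validation(sprintf("cohorts[[%d]]$%s is missing", i, f))
      }
    }
  }
  fmt <- config$paths$network_format %||% "tsv"
  if (!fmt %in% c("tsv", "sif", "signor")) {
    abort_validation("paths$network_format must be one of tsv, sif, signor")
  }
  m <- config$model
  check_number(m$tau, "model$tau", 0, Inf, open_lower = TRUE)
  check_number(m$hill_n, "model$hill_n", 1, Inf)
  check_number(m$hill_k, "model$hill_k", 0, 1, open_lower = TRUE,
               open_upper = TRUE)
  check_number(m$default_capacity, "model$default_capacity", 0, 1)
  check_number(m$lower_q, "model$lower_q", 0, 1)
  check_number(m$upper_q, "model$upper_q", 0, 1)
  if (m$lower_q >= m$upper_q) {
    abort_validation("model$lower_q must be < model$upper_q")
  }
  s <- config$simulation
  check_number(s$n_init, "simulation$n_init", 1, Inf)
  check_number(s$dt, "simulation$dt", 0, Inf, open_lower = TRUE)
  check_number(s$t_max, "simulation$t_max", 0, Inf, open_lower = TRUE)
  check_number(s$tol, "simulation$tol", 0, Inf, open_lower = TRUE)
  check_number(s$seed, "simulation$seed", -2147483646, 2147483646)
  d <- config$dasc
  check_number(d$alpha, "dasc$alpha", 0, 1, open_lower = TRUE)
  check_number(d$min_effect, "dasc$min_effect", 0, 1)
  check_number(d$max_per_group, "dasc$max_per_group", 1, Inf)
  if (!is.logical(d$require_concordant)) {
    abort_validation("dasc$require_concordant must be TRUE or FALSE")
  }
  config
}

# Atomic write: produce <path>.partial, rename into place on success, so
# an aborted stage leaves only a clearly-marked partial file behind.
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

stage_fresh <- function(outputs, inputs) {
  all(file.exists(outputs)) &&
    (length(inputs) == 0 ||
       min(file.mtime(outputs)) >= max(file.mtime(inputs)))
}

#' Run the full file-based pipeline
#'
#' Executes network import, per-gene normalization, per-sample Monte-Carlo
#' simulation, per-cohort DASC calling and (for two or more cohorts) the
#' cross-cohort intersection, reading and writing plain TSV between
#' stages under `paths$out_dir`. Stages whose outputs are newer than
#' their inputs are skipped (`force = TRUE` recomputes everything); a
#' failing stage aborts with its name, leaving any `.partial` file in
#' place. A `manifest.json` (input checksums, full config, per-stage
#' outputs, package version) and a `run.log` (one line per stage with
#' wall-clock and a parameter echo) document the run; re-running from the
#' manifest alone reproduces the outputs bit for bit.
#'
#' @param config Nested configuration list or path to a YAML file; see
#'   [default_config()] / [validate_config()].
#' @param force Recompute every stage even when outputs look fresh.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  config <- validate_config(config)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(stage, status, elapsed, params = "") {
    line <- sprintf("[%s] %s (%.2fs)%s", stage, status, elapsed,
                    if (nzchar(params)) paste0(" ", params) else "")
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    message(line)
  }
  run_stage <- function(stage, outputs, inputs, params, fun) {
    t0 <- proc.time()[["elapsed"]]
    if (!force && stage_fresh(outputs, inputs)) {
      log_line(stage, "skipped (outputs up to date)",
               proc.time()[["elapsed"]] - t0, params)
      return(invisible(FALSE))
    }
    ok <- tryCatch({
      fun()
      TRUE
    }, error = function(e) {
      log_line(stage, paste0("FAILED: ", conditionMessage(e)),
               proc.time()[["elapsed"]] - t0, params)
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
    log_line(stage, "done", proc.time()[["elapsed"]] - t0, params)
    invisible(ok)
  }

  net_in <- config$paths$network
  net_out <- file.path(out_dir, "net.tsv")
  run_stage("network", net_out, net_in,
            sprintf("format=%s", config$paths$network_format %||% "tsv"),
            function() {
              net <- switch(config$paths$network_format %||% "tsv",
                            tsv = read_network_tsv(net_in),
                            sif = read_sif(net_in),
                            signor = read_signor(net_in))
              write_atomic(function(p) write_network_tsv(net, p), net_out)
            })
  net <- read_network_tsv(net_out)

  m <- config$model
  defaults <- model_defaults(tau = m$tau, hill_n = m$hill_n,
                             hill_k = m$hill_k,
                             default_capacity = m$default_capacity)
  sim <- config$simulation
  dcfg <- config$dasc
  cohort_names <- vapply(config$cohorts, `[[`, "", "name")
  dasc_files <- character(0)
  results <- list()

  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    norm_out <- file.path(out_dir, sprintf("normalized_%s.tsv", co$name))
    run_stage(paste0("normalize:", co$name), norm_out, co$expression,
              sprintf("quantiles=(%g,%g)", m$lower_q, m$upper_q),
              function() {
                expr <- read_expression_tsv(co$expression)
                norm <- normalize_expression(expr, m$lower_q, m$upper_q)
                write_atomic(function(p) {
                  readr::write_tsv(norm, p, progress = FALSE)
                }, norm_out)
              })
    act_out <- file.path(out_dir, sprintf("activities_%s.tsv", co$name))
    sum_out <- file.path(out_dir, sprintf("activity_summary_%s.tsv", co$name))
    run_stage(paste0("simulate:", co$name), c(act_out, sum_out),
              c(net_out, norm_out, co$labels),
              sprintf("n_init=%d seed=%d dt=%g t_max=%g tol=%g",
                      sim$n_init, sim$seed, sim$dt, sim$t_max, sim$tol),
              function() {
                norm <- read_expression_tsv(norm_out)
                attr(norm, "normalized") <- TRUE
                labels <- read_labels_tsv(co$labels)
                acts <- simulate_cohort(
                  net, norm, samples = labels$sample,
                  n_init = sim$n_init,
                  seed = derive_seed(sim$seed, 10000L * i),
                  defaults = defaults,
                  dt = sim$dt, t_max = sim$t_max, tol = sim$tol
                )
                write_atomic(function(p) {
                  readr::write_tsv(bind_rows(lapply(acts, activities_long)),
                                   p, progress = FALSE)
                }, act_out)
                write_atomic(function(p) {
                  readr::write_tsv(bind_rows(lapply(acts, tidy)),
                                   p, progress = FALSE)
                }, sum_out)
              })
    dasc_out <- file.path(out_dir, sprintf("dasc_%s.tsv", co$name))
    run_stage(paste0("dasc:", co$name), dasc_out,
              c(act_out, co$labels),
              sprintf("alpha=%g min_effect=%g", dcfg$alpha, dcfg$min_effect),
              function() {
                acts <- read_activities_tsv(act_out)
                labels <- read_labels_tsv(co$labels)
                grouped <- pool_by_group(acts, labels,
                                         max_per_group = dcfg$max_per_group,
                                         cohort = co$name)
                res <- call_dascs(grouped, alpha = dcfg$alpha,
                                  min_effect = dcfg$min_effect)
                write_atomic(function(p) write_dasc_tsv(res, p), dasc_out)
              })
    dasc_files[co$name] <- dasc_out
  }

  common_out <- file.path(out_dir, "common_dascs.tsv")
  if (length(config$cohorts) >= 2) {
    run_stage("intersect", common_out, unname(dasc_files),
              sprintf("require_concordant=%s", dcfg$require_concordant),
              function() {
                results <- lapply(cohort_names, function(nm) {
                  read_dasc_tsv(dasc_files[[nm]], cohort = nm,
                                alpha = dcfg$alpha,
                                min_effect = dcfg$min_effect)
                })
                names(results) <- cohort_names
                common <- intersect_cohorts(
                  results, require_concordant = dcfg$require_concordant
                )
                write_atomic(function(p) {
                  readr::write_tsv(as_tibble(common), p, progress = FALSE)
                }, common_out)
              })
  }

  input_files <- c(net_in,
                   vapply(config$cohorts, `[[`, "", "expression"),
                   vapply(config$cohorts, `[[`, "", "labels"))
  manifest <- list(
    package = "netdasc",
    version = as.character(packageVersion("netdasc")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$simulation$seed,
    config = config,
    input_md5 = as.list(tools::md5sum(input_files)),
    outputs = list(
      network = net_out,
      dasc = as.list(dasc_files),
      common = if (length(config$cohorts) >= 2) common_out else NULL
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  write_atomic(function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }, manifest_path)
  invisible(manifest)
}

#' Re-run a pipeline from its manifest
#'
#' The manifest embeds the complete configuration; re-running with
#' `force = TRUE` reproduces every output bit for bit.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir Optional new output directory.
#' @return The new manifest, invisibly.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  config <- man$config
  # JSON round-trip turns the cohort list into a data frame; restore
  if (is.data.frame(config$cohorts)) {
    config$cohorts <- lapply(seq_len(nrow(config$cohorts)), function(i) {
      as.list(config$cohorts[i, ])
    })
  }
  if (!is.null(out_dir)) config$paths$out_dir <- out_dir
  run_pipeline(config, force = TRUE)
}

# Rebuild minimal per-sample activity objects from the long-format TSV.
read_activities_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            sample = "c", node = "c",
                            run = "i", activity = "d"
                          ))
  lapply(split(long, long$sample), function(d) {
    nodes <- sort_c(unique(d$node))
    runs <- sort(unique(d$run))
    m <- matrix(NA_real_, length(nodes), length(runs),
                dimnames = list(nodes, NULL))
    m[cbind(match(d$node, nodes), match(d$run, runs))] <- d$activity
    structure(list(sample = d$sample[1], activities = m,
                   n_init = length(runs), convergence_rate = NA_real_),
              class = "activity_distribution")
  })
}
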