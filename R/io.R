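#' Load a trajectory CSV
#'
#' Expects a header `t, <state names...>[, replicate]`; rows are sorted by
#' `(replicate, t)` and times must be strictly increasing within each
#' replicate.
#'
#' @param path CSV path.
#' @return A data frame with `t`, state columns, and `replicate`.
#' @export
load_timeseries <- function(path) {
  df <- utils::read.csv(path)
  if (!"t" %in% names(df))
    stop("malformed trajectory file: no 't' column in ", path)
  states <- setdiff(names(df), c("t", "replicate"))
  if (!length(states))
    stop("malformed trajectory file: no state columns in ", path)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df <- df[order(df$replicate, df$t), , drop = FALSE]
  rownames(df) <- NULL
  for (r in split(df, df$replicate))
    if (any(diff(r$t) <= 0))
      stop("non-monotone times within replicate ", r$replicate[1L])
  df[c("t", states, "replicate")]
}

#' Save a trajectory CSV
#'
#' Counterpart of [load_timeseries()]; `load_timeseries(save_timeseries(x))`
#' reproduces `x` to full float precision.
#'
#' @param df Trajectory data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_timeseries <- function(df, path) {
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a configured experiment end to end and persist its artifacts
#'
#' Orchestrates the full pipeline -- generate or load data, smooth
#' (optional), batch, MAP-train, run the selected posterior engine,
#' propagate coefficient posteriors, compute predictive bands and
#' diagnostics -- and writes every artifact plus a manifest to the output
#' directory.  Rerunning with the same configuration and seed reproduces
#' the artifacts.
#'
#' @param config A named list (or path to a JSON file) with entries:
#'   `system` (an [experiment_spec()] id) or `csv` (a trajectory file),
#'   `method`, `degree`, `hidden`, `window`, `smooth`, `n_samples`,
#'   `levels`, `seed`, `outdir`, and optional overrides `n_points`,
#'   `tspan`, `noise_sd`, `replicates`, `substeps`, `epochs`,
#'   `mcmc_warmup`, `mcmc_samples`, `vi_iterations`, `vi_n_mc`.
#' @return A list of class `run_artifacts`: the fitted [polynode()] object
#'   and the manifest of files written.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  defaults <- list(method = "laplace", hidden = 10L, smooth = "none",
                   n_samples = 2000L, levels = c(0.95, 0.997), seed = 1L,
                   substeps = 10L, outdir = tempfile("polynode_run_"))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$system) == is.null(cfg$csv))
    stop("config must name exactly one data source: 'system' or 'csv'")
  if (length(cfg$method) != 1L)
    stop("exactly one inference method must be selected")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$outdir, "log.txt")
  logline <- function(...) cat(sprintf("[%s] %s\n",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)),
                               file = logf, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logline("%s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  manifest <- character(0)
  emit <- function(name) manifest <<- c(manifest, name)

  data <- stage("data", {
    if (!is.null(cfg$csv)) {
      df <- load_timeseries(cfg$csv)
      cfg$degree <- cfg$degree %||% 2L
      cfg$window <- cfg$window %||% 12L
      df
    } else {
      over <- cfg[intersect(names(cfg),
                            c("n_points", "tspan", "noise_sd",
                              "replicates", "seed"))]
      spec <- do.call(experiment_spec, c(list(system = cfg$system), over))
      cfg$degree <- cfg$degree %||% spec$degree
      cfg$window <- cfg$window %||% spec$window
      if (identical(cfg$smooth, "auto") && !is.na(spec$kernel))
        cfg$smooth <- spec$kernel
      ds <- generate_dataset(spec)
      if (cfg$system == "lv_missing_terms") cfg$known_spec <- spec
      if (spec$system == "cubic") ds$replicates[c("x", "y")]
      else ds$replicates
    }
  })
  known <- if (!is.null(cfg$known_spec)) known_part(cfg$known_spec)
  ctrl <- map_control()
  if (!is.null(cfg$epochs)) {
    ctrl <- map_control(optimizer = "adam", epochs = cfg$epochs)
  }
  ms <- hmc_settings(warmup = cfg$mcmc_warmup %||% 1000L,
                     samples = cfg$mcmc_samples %||% 1000L)
  vs <- vi_settings(iterations = cfg$vi_iterations %||% 20000L,
                    n_mc = cfg$vi_n_mc %||% 1000L)
  fit <- stage("fit", polynode(
    data, degree = cfg$degree, method = cfg$method, hidden = cfg$hidden,
    window = cfg$window, smooth = cfg$smooth, known = known,
    control = ctrl, mcmc_settings = ms, vi_control = vs,
    substeps = cfg$substeps, n_samples = cfg$n_samples,
    levels = cfg$levels, seed = cfg$seed))

  stage("artifacts", {
    p <- function(f) file.path(cfg$outdir, f)
    snap <- cfg; snap$known_spec <- NULL
    writeLines(jsonlite::toJSON(snap, auto_unbox = TRUE, digits = NA),
               p("config.json")); emit("config.json")
    map_to_json(fit$map, p("map.json")); emit("map.json")
    utils::write.csv(data.frame(iteration = seq_along(fit$map$trace),
                                objective = fit$map$trace),
                     p("map_trace.csv"), row.names = FALSE)
    emit("map_trace.csv")
    if (inherits(fit$posterior, "gaussian_posterior")) {
      posterior_write(fit$posterior, p("posterior"), fit$config)
      emit("posterior_mean.csv"); emit("posterior_cov.csv")
      emit("posterior.json")
    } else {
      chain_write(fit$posterior, p("chain.csv")); emit("chain.csv")
    }
    coefficients_write(fit$coef_samples, p("coefficient_samples.csv"))
    emit("coefficient_samples.csv")
    writeLines(jsonlite::toJSON(summary(fit), dataframe = "rows",
                                auto_unbox = TRUE, digits = NA),
               p("coefficient_summary.json"))
    emit("coefficient_summary.json")
    band <- predict(fit, n_samples = min(cfg$n_samples, 500L))
    utils::write.csv(as.data.frame(band), p("bands.csv"),
                     row.names = FALSE)
    emit("bands.csv")
    diag <- diagnostics(fit)
    writeLines(jsonlite::toJSON(diag, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                force = TRUE),
               p("diagnostics.json"))
    emit("diagnostics.json")
    NULL
  })
  emit("log.txt")
  writeLines(jsonlite::toJSON(list(outdir = cfg$outdir, files = manifest),
                              auto_unbox = TRUE),
             file.path(cfg$outdir, "manifest.json"))
  manifest <- c(manifest, "manifest.json")
  structure(list(fit = fit, outdir = cfg$outdir, manifest = manifest),
            class = "run_artifacts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_artifacts <- function(x, ...) {
  cat("experiment run artifacts in", x$outdir, "\n")
  cat(paste(" -", x$manifest, collapse = "\n"), "\n")
  invisible(x)
}
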