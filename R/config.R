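default_config <- function() {
  list(
    seed = 1L,
    graph = list(levels = c("I", "II", "III", "IV"),
                 arcs = list(c("I", "II"), c("II", "III"), c("III", "IV"))),
    observation = list(sensitivity = 0.81, specificity = 0.63),
    time = list(t_max = 10L, p_early = 0.3),
    sampler = list(n_walkers = NULL, n_steps = 600L, burn_in = 300L,
                   thin = 1L)
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills in documented defaults (MRI sensitivity
#' 0.81 / specificity 0.63, ten time steps, early-stage binomial parameter
#' 0.3, sampler settings) and validates every field. Unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path Path to a YAML file; `NULL` returns the pure defaults.
#' @return Validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, keypath = "")
  }
  validate_config(cfg)
}

merge_config <- function(base, user, keypath) {
  for (k in names(user)) {
    full <- if (nzchar(keypath)) paste0(keypath, ".", k) else k
    if (!k %in% names(base)) stop("unknown configuration key: ", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        k != "graph") {
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else if (k == "graph") {
      g <- user[[k]]
      bad <- setdiff(names(g), c("levels", "arcs"))
      if (length(bad)) stop("unknown configuration key: graph.", bad[1L])
      if (!is.null(g$levels)) base$graph$levels <- as.character(g$levels)
      if (!is.null(g$arcs)) base$graph$arcs <- lapply(g$arcs, as.character)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  for (k in c("sensitivity", "specificity")) {
    v <- cfg$observation[[k]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("observation.", k, " must be a probability in [0, 1]")
  }
  if (!is.numeric(cfg$time$p_early) || cfg$time$p_early < 0 ||
      cfg$time$p_early > 1)
    stop("time.p_early must be a probability in [0, 1]")
  if (cfg$time$t_max < 1) stop("time.t_max must be a positive integer")
  for (k in c("n_steps", "burn_in", "thin")) {
    if (!is.null(cfg$sampler[[k]]) && cfg$sampler[[k]] < 0)
      stop("sampler.", k, " must be non-negative")
  }
  lnl_graph(cfg$graph$levels, cfg$graph$arcs)  # side effect: validates
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname load_config
#' @param cfg A configuration list.
#' @export
save_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg$sampler <- cfg$sampler[!vapply(cfg$sampler, is.null, TRUE)]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_hash <- function(cfg) {
  # order-stable polynomial hash of the serialized configuration
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
             collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_objects <- function(cfg) {
  list(
    graph = lnl_graph(cfg$graph$levels, cfg$graph$arcs),
    obs = observation_model(cfg$observation$sensitivity,
                            cfg$observation$specificity),
    time = time_settings(cfg$time$t_max, cfg$time$p_early)
  )
}

#' Run a pipeline stage
#'
#' Programmatic equivalent of the command-line interface: executes one of
#' the `simulate`, `fit`, `risk` or `evaluate` stages from a configuration
#' and file arguments, writing CSV/JSON artifacts that embed the seed and
#' configuration hash they were produced with.
#'
#' @param command One of `"simulate"`, `"fit"`, `"risk"`, `"evaluate"`.
#' @param args Named list of stage arguments: `config` (YAML path,
#'   optional), `seed`, and per stage -- simulate: `n_early`, `n_late`,
#'   `out`; fit: `cohort`, `out` (posterior CSV; a `<out>.summary.json` is
#'   written alongside); risk: `posterior`, `diagnosis` (e.g.
#'   `"I=0,II=1,III=0,IV=0"`), `stage`, `level`, `out`; evaluate: `cohort`,
#'   `out` (report directory).
#' @return Exit status 0 (invisibly) on success; errors propagate.
#' @export
run_pipeline <- function(command = c("simulate", "fit", "risk", "evaluate"),
                         args = list()) {
  command <- match.arg(command)
  cfg <- load_config(args$config)
  if (!is.null(args$seed)) cfg$seed <- as.integer(args$seed)
  objects <- config_objects(cfg)
  meta <- c(seed = as.character(cfg$seed), config_hash = config_hash(cfg))
  log_line <- function(...) message(sprintf("[%s] %s: %s",
                                            format(Sys.time(), "%H:%M:%S"),
                                            command, sprintf(...)))
  switch(command,
    simulate = {
      n_early <- as.integer(args$n_early %||% 66L)
      n_late <- as.integer(args$n_late %||% 42L)
      theta <- default_generator_theta()
      cohort <- simulate_cohort(theta, n_early, n_late, seed = cfg$seed,
                                graph = objects$graph, obs = objects$obs,
                                time = objects$time)
      write_cohort(cohort, args$out)
      log_line("wrote %d patients to %s (seed %d)", nrow(cohort), args$out,
               cfg$seed)
    },
    fit = {
      cohort <- read_cohort(args$cohort, objects$graph)
      if (nrow(cohort) == 0L) stop("empty cohort")
      samples <- do.call(sample_posterior, c(
        list(cohort = cohort, graph = objects$graph, obs = objects$obs,
             time = objects$time, seed = cfg$seed),
        cfg$sampler[!vapply(cfg$sampler, is.null, TRUE)]))
      con <- file(args$out, "w")
      for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
      utils::write.csv(format(as.data.frame(samples$draws), digits = 17,
                              scientific = TRUE, trim = TRUE),
                       con, row.names = FALSE, quote = FALSE)
      close(con)
      summ <- summarize_posterior(samples)
      jsonlite::write_json(
        list(seed = cfg$seed, config_hash = unname(meta[["config_hash"]]),
             acceptance = samples$meta$acceptance,
             iact = as.list(samples$meta$iact),
             mean = as.list(stats::setNames(summ$mean, summ$parameter)),
             sd = as.list(stats::setNames(summ$sd, summ$parameter)),
             q16 = as.list(stats::setNames(summ$q16, summ$parameter)),
             q84 = as.list(stats::setNames(summ$q84, summ$parameter))),
        paste0(args$out, ".summary.json"), auto_unbox = TRUE, digits = NA)
      log_line("wrote %d draws to %s", nrow(samples$draws), args$out)
    },
    risk = {
      draws <- as.matrix(utils::read.csv(args$posterior, comment.char = "#"))
      z <- parse_diagnosis_arg(args$diagnosis, objects$graph)
      lv <- strsplit(args$level %||%
                       paste(objects$graph$levels, collapse = ","), ",")[[1]]
      queries <- data.frame(level = lv, stringsAsFactors = FALSE)
      queries$diagnosis <- I(rep(list(z), length(lv)))
      queries$stage <- args$stage %||% "early"
      rt <- risk_table(draws, queries, objects$graph, objects$obs,
                       objects$time)
      df <- as.data.frame(rt)[, c("level", "stage", "mean", "sd",
                                  "q16", "q84")]
      con <- file(args$out, "w")
      for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
      utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                       row.names = FALSE, quote = FALSE)
      close(con)
      log_line("wrote %d risk rows to %s", nrow(df), args$out)
    },
    evaluate = {
      cohort <- read_cohort(args$cohort, objects$graph)
      if (nrow(cohort) == 0L) stop("empty cohort")
      dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
      cv <- do.call(threefold_cv, c(
        list(cohort = cohort, graph = objects$graph, obs = objects$obs,
             time = objects$time, seed = cfg$seed),
        cfg$sampler[!vapply(cfg$sampler, is.null, TRUE)]))
      folds_df <- data.frame(patient_id = cohort$patient_id,
                             fold = cv$folds)
      utils::write.csv(folds_df, file.path(args$out, "folds.csv"),
                       row.names = FALSE)
      pvp <- predicted_vs_prevalence(cv$full_samples, cohort,
                                     graph = objects$graph,
                                     obs = objects$obs, time = objects$time)
      for (pat in names(pvp))
        utils::write.csv(data.frame(predicted = pvp[[pat]]$draws),
                         file.path(args$out,
                                   sprintf("pattern_%s.csv", pat)),
                         row.names = FALSE)
      jsonlite::write_json(
        list(seed = cfg$seed, config_hash = unname(meta[["config_hash"]]),
             fold_sizes = cv$fold_sizes,
             heldout_loglik = cv$heldout_loglik,
             full_loglik = cv$full_loglik,
             patterns = lapply(pvp, function(p)
               list(alpha = p$alpha, beta = p$beta, k = p$k, n = p$n))),
        file.path(args$out, "summary.json"), auto_unbox = TRUE, digits = NA)
      log_line("wrote report to %s (whole-dataset log-likelihood %.2f)",
               args$out, cv$full_loglik)
    }
  )
  invisible(0L)
}

parse_diagnosis_arg <- function(spec, graph) {
  if (is.null(spec)) stop("a --diagnosis argument is required")
  parts <- strsplit(strsplit(spec, ",")[[1]], "=")
  z <- stats::setNames(rep(NA_integer_, length(graph$levels)), graph$levels)
  for (p in parts) {
    if (length(p) != 2L || !p[1] %in% graph$levels)
      stop("malformed diagnosis entry: ", paste(p, collapse = "="))
    z[p[1]] <- switch(tolower(p[2]), neg = 0L, pos = 1L, unknown = NA_integer_,
                      "0" = 0L, "1" = 1L, na = NA_integer_,
                      stop("diagnosis status must be pos/neg/unknown"))
  }
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
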