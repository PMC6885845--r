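# Comparison harness: repeated seeded runs of UPSO and/or PSO over a set of
# graphs, reported as one row per run plus per-(graph, method) mean and SD —
# the standard multi-run reporting format for stochastic optimizers.

#' Compare optimizer variants over graphs and replicate runs
#'
#' Runs each requested method on each graph `replicates` times with distinct
#' deterministic seeds derived from `seed`, and records per run the best
#' modularity, conductance, effective community count, wall time, and
#' termination cause. Rerunning with the same inputs and seed reproduces the
#' report exactly.
#'
#' @param graphs A [weighted_graph()] or list of them; names are used as
#'   graph ids when present.
#' @param methods Character subset of `c("upso", "pso")`.
#' @param replicates Runs per (graph, method).
#' @param seed Base integer seed.
#' @param config An [upso_config()]; its `seed` field is overridden per run.
#' @return List with `runs` (one data.frame row per run) and `summary`
#'   (mean and SD of Q and conductance per graph and method; SD is 0 for a
#'   single replicate).
#' @export
compare_methods <- function(graphs, methods = c("upso", "pso"),
                            replicates = 1L, seed = 1L,
                            config = upso_config()) {
  if (inherits(graphs, "weighted_graph")) graphs <- list(graphs)
  if (!is.list(graphs) || length(graphs) == 0L) {
    stop("graphs must be a nonempty list of weighted graphs")
  }
  if (!all(methods %in% c("upso", "pso")) || length(methods) == 0L) {
    stop("methods must be a nonempty subset of c(\"upso\", \"pso\")")
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be at least 1")
  ids <- names(graphs)
  if (is.null(ids)) ids <- paste0("graph", seq_along(graphs))

  rows <- list()
  for (gi in seq_along(graphs)) {
    for (mi in seq_along(methods)) {
      for (r in seq_len(replicates)) {
        run_seed <- (as.integer(seed) + 7919L * gi + 131L * mi + r) %% .Machine$integer.max
        cfg <- config
        cfg$seed <- run_seed
        elapsed <- system.time({
          res <- if (methods[mi] == "upso") run_upso(graphs[[gi]], cfg)
                 else run_pso(graphs[[gi]], cfg)
        })[["elapsed"]]
        rows[[length(rows) + 1L]] <- data.frame(
          graph = ids[gi], method = methods[mi], replicate = r,
          seed = run_seed, best_Q = res$best_Q,
          conductance = res$best_conductance, chosen_K = res$chosen_K,
          wall_time = unname(elapsed),
          termination = res$terminations[[as.character(res$swept_K)]],
          stringsAsFactors = FALSE)
      }
    }
  }
  runs <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
  summary <- do.call(rbind, lapply(
    split(runs, list(runs$graph, runs$method), drop = TRUE),
    function(df) {
      q <- agg(df$best_Q)
      ph <- agg(df$conductance)
      data.frame(graph = df$graph[1L], method = df$method[1L],
                 n_runs = nrow(df),
                 mean_Q = q[["mean"]], sd_Q = q[["sd"]],
                 mean_conductance = ph[["mean"]], sd_conductance = ph[["sd"]],
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}
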