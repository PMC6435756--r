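#' Algorithm configuration
#'
#' @param theta positive randomness parameter of the Leiden refinement phase.
#'   Default 0.01; values in roughly `[0.0005, 0.1]` allow some, but not too
#'   much, randomness. Ignored by Louvain.
#' @param seed integer seed; every randomized order and draw in a run is
#'   derived from it, making runs bit-reproducible.
#' @param max_iterations maximum number of iterations (>= 1).
#' @param stop_policy `"until_stable"` stops after the first iteration that
#'   leaves the partition unchanged; `"fixed_iterations"` always runs
#'   `max_iterations`; `"until_converged"` (Leiden) keeps iterating until
#'   `converged_patience` consecutive iterations leave the partition unchanged
#'   and the node optimality and gamma-separation checkers both pass.
#' @param converged_patience number of consecutive unchanged iterations
#'   required by `"until_converged"`. The asymptotic guarantees rest on the
#'   randomized refinement exploring alternative splits across iterations, so
#'   a single unchanged iteration is weak evidence of convergence; the default
#'   of 10 gives the refinement ten fresh draws.
#' @return an object of class `ldn_config`.
#' @export
leiden_config <- function(theta = 0.01, seed = 1L, max_iterations = 10L,
                          stop_policy = c("until_stable", "fixed_iterations",
                                          "until_converged"),
                          converged_patience = 10L) {
  stop_policy <- match.arg(stop_policy)
  if (theta <= 0) stop("`theta` must be positive")
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L)
    stop("`max_iterations` must be at least 1")
  converged_patience <- as.integer(converged_patience)
  if (is.na(converged_patience) || converged_patience < 1L)
    stop("`converged_patience` must be at least 1")
  structure(list(theta = theta, seed = as.integer(seed),
                 max_iterations = max_iterations, stop_policy = stop_policy,
                 converged_patience = converged_patience),
            class = "ldn_config")
}

#' Run an algorithm iteratively
#'
#' Runs successive iterations of the chosen algorithm, each seeded with the
#' previous iteration's partition (the first starts from `init`, by default
#' all singletons), and records the quality trajectory, community counts,
#' per-iteration timings, change flags and the first stable iteration (one
#' that leaves the partition unchanged). Quality is non-decreasing across
#' iterations for both algorithms; for Louvain every iteration after a stable
#' one is stable, whereas Leiden may improve again after a stable iteration.
#'
#' @param g an `ldn_graph`.
#' @param spec an `ldn_qspec`.
#' @param algorithm `"leiden"` or `"louvain"`.
#' @param config an [`ldn_config`][leiden_config].
#' @param init optional starting `ldn_partition`.
#' @return an object of class `ldn_run`: list with `partition` (final),
#'   `membership` (final, named by node labels), `quality`, `n_communities`,
#'   `changed`, `seconds` (all per iteration), `stable_iteration` (first
#'   stable index or `NA`), `algorithm`, `spec`, `config`.
#' @export
run_algorithm <- function(g, spec, algorithm = c("leiden", "louvain"),
                          config = leiden_config(), init = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(g, "ldn_graph"), inherits(spec, "ldn_qspec"),
            inherits(config, "ldn_config"))
  set.seed(config$seed)
  p <- if (is.null(init)) singleton_partition(g) else init
  qs <- ncs <- secs <- numeric(0)
  changed <- logical(0)
  stable <- NA_integer_
  unchanged_streak <- 0L
  for (it in seq_len(config$max_iterations)) {
    t0 <- proc.time()[["elapsed"]]
    p_new <- if (algorithm == "leiden")
      leiden_iteration(g, p, spec, theta = config$theta)
    else
      louvain_iteration(g, p, spec)
    secs <- c(secs, proc.time()[["elapsed"]] - t0)
    ch <- !same_partition(p_new, p)
    qs <- c(qs, quality(g, p_new, spec))
    ncs <- c(ncs, p_new$C)
    changed <- c(changed, ch)
    if (!ch && is.na(stable)) stable <- it
    p <- p_new
    unchanged_streak <- if (ch) 0L else unchanged_streak + 1L
    if (config$stop_policy == "until_stable" && !ch) break
    if (config$stop_policy == "until_converged" &&
        unchanged_streak >= config$converged_patience &&
        is_node_optimal(g, p, spec) && is_gamma_separated(g, p, spec)) break
  }
  structure(list(
    partition = p,
    membership = stats::setNames(p$memb, g$labels),
    quality = qs,
    n_communities = as.integer(ncs),
    changed = changed,
    seconds = secs,
    stable_iteration = stable,
    algorithm = algorithm,
    spec = spec,
    config = config
  ), class = "ldn_run")
}

#' @rdname run_algorithm
#' @export
leiden <- function(g, spec, config = leiden_config(), init = NULL) {
  run_algorithm(g, spec, "leiden", config, init)
}

#' @rdname run_algorithm
#' @export
louvain <- function(g, spec, config = leiden_config(), init = NULL) {
  run_algorithm(g, spec, "louvain", config, init)
}

#' @export
print.ldn_run <- function(x, ...) {
  cat(sprintf("%s run (%s, gamma = %g): %d iteration(s)\n",
              x$algorithm, x$spec$objective, x$spec$gamma, length(x$quality)))
  cat(sprintf("  final quality %.6g in %d communities; stable iteration: %s\n",
              x$quality[length(x$quality)],
              x$n_communities[length(x$n_communities)],
              ifelse(is.na(x$stable_iteration), "none",
                     as.character(x$stable_iteration))))
  invisible(x)
}

run_record_list <- function(run) {
  list(
    algorithm = run$algorithm,
    objective = run$spec$objective,
    gamma = run$spec$gamma,
    theta = run$config$theta,
    seed = run$config$seed,
    stop_policy = run$config$stop_policy,
    iterations = lapply(seq_along(run$quality), function(i) list(
      iteration = i,
      quality = run$quality[i],
      n_communities = run$n_communities[i],
      seconds = run$seconds[i],
      changed = run$changed[i]
    )),
    stable_iteration = if (is.na(run$stable_iteration)) NULL else run$stable_iteration,
    n_communities = run$n_communities[length(run$n_communities)],
    quality = run$quality[length(run$quality)]
  )
}
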