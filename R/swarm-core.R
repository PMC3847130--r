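#' Nonlinear decreasing inertia update
#'
#' One step of the inertia recurrence
#' `w(t+1) = (w(t) - w_floor) * (max_iter - iter) / max_iter + w_floor`,
#' applied once per iteration with the 0-based iteration index, so the
#' inertia decays nonlinearly from its initial value (default 1.4) towards
#' the floor (default 0.4). At `iter = max_iter` the bracket vanishes and
#' exactly the floor remains.
#'
#' @param w_current Current inertia weight, at least `w_floor`.
#' @param iter Current iteration index, in `0..max_iter` (the loop uses
#'   `0..max_iter - 1`; the endpoint is reachable by direct call).
#' @param config A [swarm_config()] supplying `max_iter` and `w_floor`.
#' @return The next inertia weight.
#' @examples
#' cfg <- swarm_config(max_iter = 500)
#' update_inertia(1.4, 250, cfg)  # 0.9
#' update_inertia(1.4, 500, cfg)  # 0.4
#' @export
update_inertia <- function(w_current, iter, config) {
  max_iter <- config$max_iter
  if (is.null(max_iter) || max_iter < 1L)
    stop("invalid configuration: max_iter must be at least 1")
  stopifnot(iter >= 0, iter <= max_iter, w_current >= config$w_floor)
  (w_current - config$w_floor) * ((max_iter - iter) / max_iter) +
    config$w_floor
}

#' Initialize a swarm
#'
#' Creates `n_particles` particles over `n` gene dimensions. Each position
#' bit is set independently with probability `init_bit_prob`. The baseline
#' variant draws per-dimension velocities uniformly in `[-V_max, V_max]`
#' with `V_max = v_max_fraction * n`; the enhanced variant draws one
#' strictly positive scalar speed per particle, uniform on
#' `(speed_init_range[1], speed_init_range[2]]`. Every personal best starts
#' at the initial position with fitness -Inf, so the first evaluation
#' always installs a real fitness.
#'
#' @param n Number of genes (dimensions).
#' @param config A [swarm_config()].
#' @param variant `"epso"` (enhanced, scalar speed) or `"bpso"`
#'   (conventional, velocity vector).
#' @return A list of particles; each particle is a list with `position`,
#'   `velocity` or `speed`, `pbest_position`, `pbest_fitness`.
#' @export
initialize_swarm <- function(n, config, variant = c("epso", "bpso")) {
  variant <- match.arg(variant)
  stopifnot(n >= 1L)
  v_max <- config$v_max_fraction * n
  lapply(seq_len(config$n_particles), function(i) {
    pos <- as.integer(stats::runif(n) < config$init_bit_prob)
    p <- list(position = pos, pbest_position = pos, pbest_fitness = -Inf)
    if (variant == "bpso") {
      p$velocity <- stats::runif(n, -v_max, v_max)
    } else {
      lo <- config$speed_init_range[1]
      hi <- config$speed_init_range[2]
      # hi - runif*[0, hi-lo) gives (lo, hi]: strictly positive when lo >= 0
      p$speed <- hi - stats::runif(1) * (hi - lo)
    }
    p
  })
}

#' Personal- and global-best replacement rule
#'
#' The personal best is replaced iff the new fitness strictly exceeds the
#' stored one; the global best iff the (possibly updated) personal best
#' strictly exceeds it. Ties keep the incumbent: the fitness already
#' penalizes subset size, so no secondary tie-break is applied.
#'
#' @param particle A particle (list with `position`, `pbest_position`,
#'   `pbest_fitness`).
#' @param fitness Fitness of the particle's current position.
#' @param gbest Incumbent global best: list with `position` and `fitness`
#'   (`fitness = -Inf` for "none yet").
#' @return List with updated `particle` and `gbest`.
#' @export
update_bests <- function(particle, fitness, gbest) {
  if (fitness > particle$pbest_fitness) {
    particle$pbest_fitness <- fitness
    particle$pbest_position <- particle$position
  }
  if (particle$pbest_fitness > gbest$fitness) {
    gbest$fitness <- particle$pbest_fitness
    gbest$position <- particle$pbest_position
  }
  list(particle = particle, gbest = gbest)
}

#' Run the swarm gene-selection optimizer
#'
#' The main loop shared by both variants. Each iteration: evaluate the
#' fitness of every particle's position (LOOCV/SVM accuracy combined with
#' the subset-size reward), update personal and global bests, log the
#' iteration, update the inertia by its nonlinear recurrence, then move
#' every particle with the variant's velocity/speed and position rules.
#' The iteration budget is fixed: no early stopping and no global-best
#' reset.
#'
#' @param dataset An [expression_dataset()] (typically already reduced by
#'   [select_top_genes()]).
#' @param config A [swarm_config()]; `config$seed`, when non-NULL, seeds
#'   the run and makes the result bit-identical across calls.
#' @param variant `"epso"` or `"bpso"`.
#' @return An object of class `swarm_run`: list with `gbest_position`
#'   (0/1 vector), `gbest_genes` (identifiers), `gbest_fitness`,
#'   `gbest_accuracy`, `gbest_n_genes`, `trajectory` (data.frame with
#'   columns iteration, w, gbest_fitness, gbest_accuracy, gbest_num_genes;
#'   one row per iteration, fitness non-decreasing), `variant`, `config`,
#'   `elapsed` (seconds).
#' @examples
#' d <- synthetic_dataset(n_samples = 12, n_genes = 15, n_classes = 2,
#'                        n_informative = 2, effect_size = 8, seed = 1)
#' cfg <- swarm_config(n_particles = 5, max_iter = 3, seed = 1)
#' run <- run_swarm(d$dataset, cfg, variant = "epso")
#' run$gbest_n_genes
#' @export
run_swarm <- function(dataset, config, variant = c("epso", "bpso")) {
  variant <- match.arg(variant)
  if (!inherits(dataset, "expr_dataset")) stop("`dataset` must be an expr_dataset")
  n <- n_genes(dataset)
  if (n < 1L) stop("dataset has no genes")
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$seed)) set.seed(config$seed)

  v_max <- config$v_max_fraction * n
  swarm <- initialize_swarm(n, config, variant)
  gbest <- list(position = NULL, fitness = -Inf)
  gbest_eval <- list(accuracy = NA_real_, n_selected = NA_integer_)
  cache <- new.env(parent = emptyenv())

  traj <- data.frame(
    iteration = seq_len(config$max_iter) - 1L,
    w = NA_real_, gbest_fitness = NA_real_,
    gbest_accuracy = NA_real_, gbest_num_genes = NA_integer_
  )

  w <- config$w_init
  for (t in seq_len(config$max_iter) - 1L) {
    for (i in seq_along(swarm)) {
      ev <- evaluate_position(dataset, swarm[[i]]$position, config, cache)
      upd <- update_bests(swarm[[i]], ev$fitness, gbest)
      swarm[[i]] <- upd$particle
      # gbest can only change via a pbest just replaced by this evaluation,
      # so ev carries the stats of the new gbest position
      if (upd$gbest$fitness > gbest$fitness)
        gbest_eval <- ev[c("accuracy", "n_selected")]
      gbest <- upd$gbest
    }
    traj$w[t + 1L] <- w
    traj$gbest_fitness[t + 1L] <- gbest$fitness
    traj$gbest_accuracy[t + 1L] <- gbest_eval$accuracy
    traj$gbest_num_genes[t + 1L] <- gbest_eval$n_selected

    w <- update_inertia(w, t, config)

    for (i in seq_along(swarm)) {
      p <- swarm[[i]]
      if (variant == "bpso") {
        r1 <- stats::runif(n); r2 <- stats::runif(n)
        p$velocity <- bpso_velocity_step(p$velocity, p$position,
                                         p$pbest_position, gbest$position,
                                         w, config$c1, config$c2, r1, r2,
                                         v_max)
        r3 <- stats::runif(n)
        p$position <- bpso_position_step(p$velocity, r3)
      } else {
        r1 <- stats::runif(1); r2 <- stats::runif(1)
        p$speed <- epso_speed_step(p$speed, p$position, p$pbest_position,
                                   gbest$position, w, config$c1, config$c2,
                                   r1, r2, v_max)
        r3 <- stats::runif(n)
        p$position <- epso_position_step(p$speed, r3,
                                         config$sigmoid_steepness)
      }
      swarm[[i]] <- p
    }
  }

  structure(
    list(
      gbest_position = gbest$position,
      gbest_genes = dataset$genes[gbest$position == 1L],
      gbest_fitness = gbest$fitness,
      gbest_accuracy = gbest_eval$accuracy,
      gbest_n_genes = sum(gbest$position),
      trajectory = traj,
      variant = variant,
      config = config,
      elapsed = proc.time()[["elapsed"]] - t0
    ),
    class = "swarm_run"
  )
}

#' @export
print.swarm_run <- function(x, ...) {
  cat(sprintf("%s run: %d iterations x %d particles\n",
              toupper(x$variant), x$config$max_iter, x$config$n_particles))
  cat(sprintf("  best fitness: %.4f  LOOCV accuracy: %s  genes: %d\n",
              x$gbest_fitness,
              ifelse(is.na(x$gbest_accuracy), "NA",
                     sprintf("%.4f", x$gbest_accuracy)),
              x$gbest_n_genes))
  if (x$gbest_n_genes > 0 && x$gbest_n_genes <= 25)
    cat("  selected:", paste(x$gbest_genes, collapse = ", "), "\n")
  cat(sprintf("  elapsed: %.2f s\n", x$elapsed))
  invisible(x)
}

#' Write a per-iteration trajectory log
#'
#' Delimited text with columns iteration, w, gbest_fitness, gbest_accuracy,
#' gbest_num_genes.
#'
#' @param run A `swarm_run`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_trajectory <- function(run, path, sep = "\t") {
  utils::write.table(run$trajectory, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
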