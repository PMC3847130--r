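#' Swarm configuration
#'
#' All tunables of the swarm optimizers, with the published defaults:
#' 100 particles, 500 iterations, acceleration constants c1 = c2 = 2,
#' inertia decaying nonlinearly from 1.4 to a floor of 0.4, velocity/speed
#' clamp at one third of the gene count, and fitness weights w1 = 0.8,
#' w2 = 0.2 (accuracy weighted above subset size).
#'
#' @param n_particles Number of particles in the swarm.
#' @param max_iter Number of iterations (generations).
#' @param c1,c2 Acceleration constants towards the personal and global best;
#'   must lie in \[0, 2\].
#' @param w_init Initial inertia weight.
#' @param w_floor Inertia floor reached at the final iteration.
#' @param v_max_fraction The velocity/speed clamp is `v_max_fraction * n`
#'   where `n` is the gene count; default 1/3.
#' @param w1 Fitness weight on LOOCV accuracy, in \[0.6, 0.9\]. The subset
#'   size weight is always `w2 = 1 - w1`.
#' @param sigmoid_steepness Slope alpha of the enhanced optimizer's transfer
#'   function `1 / (1 + exp(-alpha * s))`; default 5, which reproduces the
#'   published transfer probabilities (0.993307 at s = 1).
#' @param init_bit_prob Probability that a position bit is initialized to 1;
#'   default 0.5 (a fair bit, matching the standard sigmoid's starting
#'   probability).
#' @param speed_init_range Interval from which the enhanced optimizer's
#'   initial speeds are drawn, uniform on `(min, max]`; default `c(0, 1)`
#'   i.e. strictly positive values at most 1.
#' @param svm_cost,svm_scale SVM cost parameter C and whether to standardize
#'   features inside the SVM. The kernel is RBF with gamma = 1 / (number of
#'   selected genes); multiclass is one-against-one.
#' @param empty_subset_fitness Fitness assigned to the empty gene subset.
#'   The default 0 removes the pathology of the size-reward term paying for
#'   selecting nothing.
#' @param seed Integer seed making a run fully reproducible; `NULL` leaves
#'   the random number generator state untouched.
#' @return A list of class `swarm_config`.
#' @examples
#' cfg <- swarm_config(n_particles = 20, max_iter = 50, seed = 1)
#' cfg$w2
#' @export
swarm_config <- function(n_particles = 100L,
                         max_iter = 500L,
                         c1 = 2,
                         c2 = 2,
                         w_init = 1.4,
                         w_floor = 0.4,
                         v_max_fraction = 1 / 3,
                         w1 = 0.8,
                         sigmoid_steepness = 5,
                         init_bit_prob = 0.5,
                         speed_init_range = c(0, 1),
                         svm_cost = 1,
                         svm_scale = FALSE,
                         empty_subset_fitness = 0,
                         seed = NULL) {
  n_particles <- as.integer(n_particles)
  max_iter <- as.integer(max_iter)
  stopifnot(
    n_particles >= 1L, max_iter >= 1L,
    c1 >= 0, c1 <= 2, c2 >= 0, c2 <= 2,
    w_init >= w_floor, w_floor >= 0,
    v_max_fraction > 0,
    w1 >= 0.6, w1 <= 0.9,
    sigmoid_steepness > 0,
    init_bit_prob >= 0, init_bit_prob <= 1,
    length(speed_init_range) == 2L,
    speed_init_range[1] >= 0, speed_init_range[2] > speed_init_range[1],
    svm_cost > 0
  )
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(
      n_particles = n_particles, max_iter = max_iter,
      c1 = c1, c2 = c2,
      w_init = w_init, w_floor = w_floor,
      v_max_fraction = v_max_fraction,
      w1 = w1, w2 = 1 - w1,
      sigmoid_steepness = sigmoid_steepness,
      init_bit_prob = init_bit_prob,
      speed_init_range = as.numeric(speed_init_range),
      svm_cost = svm_cost, svm_scale = isTRUE(svm_scale),
      empty_subset_fitness = empty_subset_fitness,
      seed = seed
    ),
    class = "swarm_config"
  )
}

#' @export
print.swarm_config <- function(x, ...) {
  cat("Swarm configuration\n")
  cat(sprintf("  particles: %d   iterations: %d\n", x$n_particles, x$max_iter))
  cat(sprintf("  c1 = %g, c2 = %g, inertia %g -> %g, V_max = %g * n\n",
              x$c1, x$c2, x$w_init, x$w_floor, x$v_max_fraction))
  cat(sprintf("  fitness weights: w1 = %g (accuracy), w2 = %g (subset size)\n",
              x$w1, x$w2))
  cat(sprintf("  transfer steepness alpha = %g, init bit prob = %g\n",
              x$sigmoid_steepness, x$init_bit_prob))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a swarm configuration from a YAML file
#'
#' The file is a flat mapping whose keys mirror the arguments of
#' [swarm_config()]; absent keys keep their defaults, unknown keys are an
#' error.
#'
#' @param path Path to a YAML file.
#' @return A `swarm_config`.
#' @export
read_swarm_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must be a flat YAML mapping")
  known <- names(formals(swarm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(swarm_config, vals)
}
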