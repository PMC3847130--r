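#' Standard sigmoid transfer function
#'
#' Maps a velocity component to the probability that the corresponding bit
#' becomes 1 in the conventional binary PSO: `Sig(v) = 1 / (1 + exp(-v))`.
#' At v = 0 every bit is a fair coin, which is why the baseline optimizer
#' tends to keep about half of all genes selected in high dimension.
#'
#' @param v Numeric vector of velocity components.
#' @return Probabilities in (0, 1), same length as `v`.
#' @examples
#' standard_sigmoid(c(0, 1, 2))  # 0.5, 0.731059, 0.880797
#' @export
standard_sigmoid <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  1 / (1 + exp(-v))
}

#' Conventional BPSO velocity update
#'
#' Per dimension d:
#' `v <- w * v + c1 * r1[d] * (pbest[d] - x[d]) + c2 * r2[d] * (gbest[d] - x[d])`,
#' then clamped to `[-v_max, v_max]`. The random factors `r1`, `r2` are
#' drawn independently per dimension.
#'
#' @param velocity Numeric velocity vector, length n.
#' @param position,pbest,gbest Binary (0/1) vectors of length n.
#' @param w Current inertia weight.
#' @param c1,c2 Acceleration constants.
#' @param r1,r2 Uniform draws on \[0, 1\], length n (or scalars, recycled).
#' @param v_max Symmetric clamp bound; components are limited to
#'   `[-v_max, v_max]`.
#' @return The updated, clamped velocity vector.
#' @export
bpso_velocity_step <- function(velocity, position, pbest, gbest,
                               w, c1, c2, r1, r2, v_max) {
  n <- length(velocity)
  if (length(position) != n || length(pbest) != n || length(gbest) != n)
    stop("velocity, position, pbest and gbest must share one length")
  v <- w * velocity +
    c1 * r1 * (pbest - position) +
    c2 * r2 * (gbest - position)
  pmin(pmax(v, -v_max), v_max)
}

#' Conventional BPSO position update
#'
#' A bit becomes 1 iff `standard_sigmoid(v) > r3`, with a fresh uniform draw
#' `r3` per dimension, per particle, per iteration.
#'
#' @param velocity Numeric velocity vector.
#' @param r3 Uniform draws on \[0, 1\], same length as `velocity`.
#' @return Integer 0/1 vector.
#' @examples
#' bpso_position_step(c(1, 0), r3 = c(0.5, 0.9))  # 1, 0
#' @export
bpso_position_step <- function(velocity, r3) {
  stopifnot(all(r3 >= 0), all(r3 <= 1))
  as.integer(standard_sigmoid(velocity) > r3)
}
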