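#' Distance between two binary particle positions
#'
#' The per-dimension difference `best - pos` takes values in \{-1, 0, +1\}.
#' A +1 marks a gene the best position selects but `pos` does not (a miss
#' that can cost accuracy); a -1 marks a gene `pos` selects needlessly (it
#' lengthens the subset). With `a` the number of +1 entries and `b` the
#' number of -1 entries, the distance is `|a - b|`. It is non-negative and
#' zero for identical positions, but it is not a metric: the triangle
#' inequality can fail, and distinct positions with a = b also give 0.
#'
#' @param best,pos Binary (0/1) vectors of equal length.
#' @return A list of class `position_diff` with elements `diff`
#'   (the \{-1,0,1\} vector), `a`, `b`, and `distance`.
#' @examples
#' d <- position_diff(c(0,0,1,1,1,0,1,0,0,0), c(1,1,1,0,1,1,0,1,0,0))
#' d$distance  # |2 - 4| = 2
#' @export
position_diff <- function(best, pos) {
  if (length(best) != length(pos))
    stop("positions differ in length: ", length(best), " vs ", length(pos))
  best <- as.integer(best)
  pos <- as.integer(pos)
  dvec <- best - pos
  a <- sum(dvec == 1L)
  b <- sum(dvec == -1L)
  structure(list(diff = dvec, a = a, b = b, distance = abs(a - b)),
            class = "position_diff")
}

# distance only, for the inner loop
position_distance <- function(best, pos) {
  dvec <- best - pos
  abs(sum(dvec == 1L) - sum(dvec == -1L))
}

#' Enhanced-PSO speed update
#'
#' The enhanced optimizer replaces the per-dimension velocity by one scalar,
#' non-negative speed per particle:
#' `s <- w * s + c1 * r1 * dist(pbest, X) + c2 * r2 * dist(gbest, X)`,
#' clamped to `[0, v_max]`. `r1` and `r2` are single uniform draws per
#' particle per iteration (not per dimension), and both distance terms are
#' non-negative, so a non-negative incoming speed can never turn negative.
#'
#' @param speed Current non-negative scalar speed.
#' @param position,pbest,gbest Binary (0/1) vectors of equal length.
#' @param w Current inertia weight (non-negative).
#' @param c1,c2 Acceleration constants.
#' @param r1,r2 Single uniform draws on \[0, 1\].
#' @param v_max Upper clamp bound for the speed.
#' @return The updated speed, in `[0, v_max]`.
#' @export
epso_speed_step <- function(speed, position, pbest, gbest,
                            w, c1, c2, r1, r2, v_max) {
  if (speed < 0)
    stop("corrupted particle state: negative speed ", speed)
  s <- w * speed +
    c1 * r1 * position_distance(pbest, position) +
    c2 * r2 * position_distance(gbest, position)
  min(max(s, 0), v_max)
}

#' Steepened sigmoid transfer function of the enhanced optimizer
#'
#' `Sig(s) = 1 / (1 + exp(-alpha * s))` for a non-negative speed s. Because
#' s >= 0 the value is always at least 0.5, and it is used as the
#' probability that a bit becomes 0 (see [epso_position_step()]): genes are
#' deselected with probability >= 0.5 at every dimension, which is the
#' mechanism that drives the search towards small subsets. The default
#' steepness alpha = 5 gives 0.993307 at s = 1 and 0.999955 at s = 2.
#'
#' @param s Non-negative speed (vectorized).
#' @param steepness Slope alpha > 0.
#' @return Probabilities in \[0.5, 1).
#' @examples
#' modified_sigmoid(c(0, 1, 2))  # 0.5, 0.993307, 0.999955
#' @export
modified_sigmoid <- function(s, steepness = 5) {
  stopifnot(steepness > 0)
  if (any(s < 0))
    stop("speed must be non-negative, got ", min(s))
  1 / (1 + exp(-steepness * s))
}

#' Enhanced-PSO position update
#'
#' The inverted bit rule: a bit becomes 0 iff
#' `modified_sigmoid(s, steepness) > r3`, else 1, with a fresh uniform draw
#' `r3` per dimension while the same scalar speed `s` governs every
#' dimension of the particle. Since the transfer value is at least 0.5,
#' `P(bit = 1) <= 0.5` always — the selection probability is capped.
#'
#' @param speed Non-negative scalar speed of the particle.
#' @param r3 Uniform draws on \[0, 1\], one per dimension.
#' @param steepness Transfer slope alpha.
#' @return Integer 0/1 vector, same length as `r3`.
#' @examples
#' epso_position_step(0, r3 = 0.7)  # 1: 0.5 > 0.7 is false
#' @export
epso_position_step <- function(speed, r3, steepness = 5) {
  stopifnot(length(speed) == 1L, all(r3 >= 0), all(r3 <= 1))
  as.integer(!(modified_sigmoid(speed, steepness) > r3))
}
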