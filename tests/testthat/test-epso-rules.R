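test_that("position distance reproduces the published worked example", {
  best <- c(0, 0, 1, 1, 1, 0, 1, 0, 0, 0)
  pos <- c(1, 1, 1, 0, 1, 1, 0, 1, 0, 0)
  d <- position_diff(best, pos)
  expect_equal(d$diff, c(-1, -1, 0, 1, 0, -1, 1, -1, 0, 0))
  expect_equal(d$a, 2)
  expect_equal(d$b, 4)
  expect_equal(d$distance, 2)
})

test_that("position distance is non-negative and definite", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    p <- as.integer(runif(n) < 0.5)
    q <- as.integer(runif(n) < 0.5)
    d <- position_diff(p, q)
    expect_gte(d$distance, 0)
    expect_equal(d$distance, abs(d$a - d$b))
    expect_lte(d$a + d$b, n)
  }
  p <- c(1L, 0L, 1L)
  expect_equal(position_diff(p, p)$distance, 0)
  # k set bits against the zero vector have distance k
  expect_equal(position_diff(c(1, 1, 1, 0, 0), rep(0, 5))$distance, 3)
  expect_error(position_diff(c(1, 0), c(1, 0, 1)), "length")
})

test_that("speed update matches hand evaluation, clamps, stays non-negative", {
  # all terms vanish when the particle sits on both bests
  x <- c(1L, 0L, 1L, 0L)
  expect_equal(epso_speed_step(0, x, x, x, w = 1, c1 = 2, c2 = 2,
                               r1 = 1, r2 = 1, v_max = 10), 0)
  # w*0 + 2*1*2 + 2*1*2 = 8
  pb <- c(1L, 1L, 0L, 0L, 0L, 0L)  # two missing bits: dist 2 from x6
  x6 <- c(0L, 0L, 0L, 0L, 0L, 0L)
  expect_equal(position_diff(pb, x6)$distance, 2)
  expect_equal(epso_speed_step(0, x6, pb, pb, w = 1, c1 = 2, c2 = 2,
                               r1 = 1, r2 = 1, v_max = 100), 8)
  # clamp and non-negativity under random admissible inputs
  set.seed(8)
  n <- 30
  vmax <- n / 3
  for (i in 1:50) {
    s <- epso_speed_step(runif(1, 0, vmax),
                         as.integer(runif(n) < 0.5),
                         as.integer(runif(n) < 0.5),
                         as.integer(runif(n) < 0.5),
                         w = runif(1, 0.4, 1.4), c1 = 2, c2 = 2,
                         r1 = runif(1), r2 = runif(1), v_max = vmax)
    expect_gte(s, 0)
    expect_lte(s, vmax)
  }
  expect_error(epso_speed_step(-1, x, x, x, 1, 2, 2, 1, 1, 10), "negative")
})

test_that("modified sigmoid reproduces the published transfer values", {
  expect_equal(modified_sigmoid(0), 0.5)
  expect_equal(round(modified_sigmoid(1), 6), 0.993307)
  expect_equal(round(modified_sigmoid(2), 6), 0.999955)
  # never below one half on the admissible domain
  expect_true(all(modified_sigmoid(seq(0, 40, by = 0.5)) >= 0.5))
  expect_error(modified_sigmoid(-0.1), "non-negative")
})

test_that("inverted bit rule caps the selection probability at one half", {
  expect_equal(epso_position_step(1, r3 = 0.5), 0L)  # 0.993 > 0.5: deselect
  expect_equal(epso_position_step(0, r3 = 0.7), 1L)  # 0.5 > 0.7 fails: select
  set.seed(21)
  # P(bit = 1) = 1 - Sig(alpha * s): Monte Carlo at alpha*s = 5
  draws <- epso_position_step(1, runif(1e5), steepness = 5)
  expect_lt(abs(mean(draws) - 0.006693), 0.002)
  for (s in c(0, 0.1, 0.4)) {
    frac <- mean(epso_position_step(s, runif(2e4)))
    expect_lte(frac, 0.5 + 0.02)
    expect_lt(abs(frac - (1 - modified_sigmoid(s))), 0.02)
  }
})

test_that("expected subset size after one enhanced step is n*(1 - Sig)", {
  set.seed(5)
  n <- 400
  for (s in c(0.2, 0.5, 1)) {
    sizes <- replicate(60, sum(epso_position_step(s, runif(n))))
    expect_equal(mean(sizes), n * (1 - modified_sigmoid(s)),
                 tolerance = max(1.5, 0.2 * n * (1 - modified_sigmoid(s))))
  }
})

test_that("speed non-negativity is preserved across a whole run", {
  d <- synthetic_dataset(n_samples = 12, n_genes = 15, n_classes = 2,
                         n_informative = 2, effect_size = 5, seed = 6)
  cfg <- swarm_config(n_particles = 4, max_iter = 6, seed = 3)
  n <- n_genes(d$dataset)
  set.seed(3)
  swarm <- initialize_swarm(n, cfg, "epso")
  gbest <- list(position = swarm[[1]]$position, fitness = 0)
  w <- cfg$w_init
  for (t in 0:5) {
    w <- update_inertia(w, t, cfg)
    for (i in seq_along(swarm)) {
      p <- swarm[[i]]
      p$speed <- epso_speed_step(p$speed, p$position, p$pbest_position,
                                 gbest$position, w, cfg$c1, cfg$c2,
                                 runif(1), runif(1), n / 3)
      expect_gte(p$speed, 0)
      p$position <- epso_position_step(p$speed, runif(n))
      swarm[[i]] <- p
    }
  }
})
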