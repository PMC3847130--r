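test_that("inertia recurrence matches hand-evaluated values", {
  cfg <- swarm_config(max_iter = 500)
  expect_equal(update_inertia(1.4, 0, cfg), 1.4)    # identity at iter 0
  expect_equal(update_inertia(1.4, 250, cfg), 0.9)  # (1.4-0.4)*0.5 + 0.4
  expect_equal(update_inertia(1.4, 500, cfg), 0.4)  # floor at the endpoint
  cfg10 <- swarm_config(max_iter = 10)
  expect_equal(update_inertia(1.4, 0, cfg10), 1.4)
})

test_that("inertia sequence is non-increasing and bounded over a run", {
  cfg <- swarm_config(max_iter = 80)
  w <- cfg$w_init
  ws <- numeric(cfg$max_iter)
  for (t in seq_len(cfg$max_iter) - 1L) {
    ws[t + 1L] <- w
    w <- update_inertia(w, t, cfg)
  }
  expect_true(all(diff(ws) <= 0))
  expect_true(all(ws >= cfg$w_floor & ws <= cfg$w_init))
})

test_that("degenerate inertia configuration is rejected", {
  cfg <- swarm_config(max_iter = 1)
  cfg$max_iter <- 0L
  expect_error(update_inertia(1.4, 0, cfg), "max_iter")
})

test_that("swarm initialization honours the bit probability and determinism", {
  cfg0 <- swarm_config(n_particles = 5, max_iter = 1, init_bit_prob = 0)
  cfg1 <- swarm_config(n_particles = 5, max_iter = 1, init_bit_prob = 1)
  set.seed(7)
  s0 <- initialize_swarm(40, cfg0, "bpso")
  set.seed(7)
  s1 <- initialize_swarm(40, cfg1, "epso")
  expect_true(all(vapply(s0, function(p) sum(p$position), numeric(1)) == 0))
  expect_true(all(vapply(s1, function(p) sum(p$position), numeric(1)) == 40))

  cfg <- swarm_config(n_particles = 8, max_iter = 1)
  set.seed(11); a <- initialize_swarm(30, cfg, "epso")
  set.seed(11); b <- initialize_swarm(30, cfg, "epso")
  expect_identical(a, b)

  # pbest starts at the initial position; speeds strictly positive
  expect_identical(a[[3]]$position, a[[3]]$pbest_position)
  expect_true(all(vapply(a, `[[`, numeric(1), "speed") > 0))
  expect_true(all(vapply(a, `[[`, numeric(1), "speed") <= 1))

  set.seed(2)
  bp <- initialize_swarm(30, cfg, "bpso")
  vmax <- cfg$v_max_fraction * 30
  expect_true(all(abs(unlist(lapply(bp, `[[`, "velocity"))) <= vmax))
})

test_that("best replacement is strict and ties keep the incumbent", {
  p <- list(position = c(1L, 0L), pbest_position = c(0L, 1L),
            pbest_fitness = 0.8)
  g <- list(position = c(0L, 1L), fitness = 0.85)

  up <- update_bests(p, 0.9, g)
  expect_equal(up$particle$pbest_fitness, 0.9)
  expect_identical(up$particle$pbest_position, c(1L, 0L))
  expect_equal(up$gbest$fitness, 0.9)

  tie <- update_bests(p, 0.8, g)  # equal fitness: nothing moves
  expect_identical(tie$particle, p)
  expect_identical(tie$gbest, g)

  worse <- update_bests(p, 0.5, g)
  expect_identical(worse$particle, p)
  expect_identical(worse$gbest, g)
})

test_that("single-particle single-iteration run reduces to one evaluation", {
  d <- synthetic_dataset(n_samples = 12, n_genes = 10, n_classes = 2,
                         n_informative = 2, effect_size = 8, seed = 4)
  cfg <- swarm_config(n_particles = 1, max_iter = 1, seed = 9)
  for (variant in c("epso", "bpso")) {
    run <- run_swarm(d$dataset, cfg, variant)
    expect_equal(nrow(run$trajectory), 1L)
    expect_equal(run$gbest_n_genes, sum(run$gbest_position))
    # gbest is that particle's evaluated initial position
    set.seed(9)
    init <- initialize_swarm(10, cfg, variant)
    expect_identical(run$gbest_position, init[[1]]$position)
  }
})

test_that("identical seed, config and dataset give bit-identical results", {
  d <- synthetic_dataset(n_samples = 14, n_genes = 20, n_classes = 2,
                         n_informative = 3, effect_size = 5, seed = 2)
  cfg <- swarm_config(n_particles = 6, max_iter = 8, seed = 123)
  for (variant in c("epso", "bpso")) {
    a <- run_swarm(d$dataset, cfg, variant)
    b <- run_swarm(d$dataset, cfg, variant)
    a$elapsed <- b$elapsed <- NULL
    expect_identical(a, b)
  }
})

test_that("global-best fitness is non-decreasing along every trajectory", {
  d <- synthetic_dataset(n_samples = 14, n_genes = 20, n_classes = 2,
                         n_informative = 3, effect_size = 5, seed = 2)
  for (seed in c(5, 6)) {
    cfg <- swarm_config(n_particles = 6, max_iter = 10, seed = seed)
    for (variant in c("epso", "bpso")) {
      run <- run_swarm(d$dataset, cfg, variant)
      expect_equal(nrow(run$trajectory), cfg$max_iter)
      expect_true(all(diff(run$trajectory$gbest_fitness) >= 0))
      expect_true(all(diff(run$trajectory$w) <= 0))
    }
  }
})

test_that("configuration invariants are enforced", {
  expect_error(swarm_config(c1 = 2.5))
  expect_error(swarm_config(w1 = 0.5))   # outside the stated [0.6, 0.9]
  expect_error(swarm_config(n_particles = 0))
  expect_error(swarm_config(init_bit_prob = 1.2))
  expect_equal(swarm_config(w1 = 0.7)$w2, 0.3)
})
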