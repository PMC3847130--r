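# Shared fixtures. The paired optimizer runs are expensive, so they are
# computed once on first use and memoised for the whole test session.

fixture_env <- new.env(parent = emptyenv())

# the desk-scale study dataset: 30 samples x 100 genes, 3 classes,
# 5 planted informative genes at effect size 5
study_dataset <- function() {
  if (is.null(fixture_env$study))
    fixture_env$study <- synthetic_dataset(seed = 1)
  fixture_env$study
}

# 10 matched-seed EPSO/BPSO pairs (20 particles, 50 iterations) on the
# study dataset, seeds 1..10
paired_runs <- function() {
  if (is.null(fixture_env$paired)) {
    d <- study_dataset()$dataset
    fixture_env$paired <- lapply(1:10, function(s) {
      cfg <- swarm_config(n_particles = 20, max_iter = 50, seed = s)
      list(epso = run_swarm(d, cfg, "epso"),
           bpso = run_swarm(d, cfg, "bpso"))
    })
  }
  fixture_env$paired
}
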