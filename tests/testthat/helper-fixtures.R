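# Shared simulated datasets, generated once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, spec) {
  if (is.null(.sim_cache[[key]])) {
    sim <- generate_genome(spec)
    tracks <- simulate_coverage(sim$truth, spec)
    .sim_cache[[key]] <- c(sim, list(tracks = tracks, spec = spec))
  }
  .sim_cache[[key]]
}

# The default study conditions: 60 genes, TEX enrichment 10, seed 42.
default_sim <- function() {
  cached_sim("default", simulation_spec(seed = 42))
}

# Larger instance used for the screen and promoter-recovery analyses
# (about 130 primary promoters, 13 planted bidirectional pairs).
screen_sim <- function() {
  cached_sim("screen", simulation_spec(n_genes = 150L,
                                       genome_length = 150000L,
                                       seed = 42))
}

# About 200 planted primary promoters with a larger IS complement for
# class-A exemplars.
pwm_sim <- function() {
  cached_sim("pwm", simulation_spec(n_genes = 250L,
                                    genome_length = 250000L,
                                    n_is_elements = 10L,
                                    seed = 42))
}

classified_default <- function() {
  if (is.null(.sim_cache$classified_default)) {
    sim <- default_sim()
    called <- call_tss(sim$tracks$TEX, sim$tracks$NOTEX)
    .sim_cache$classified_default <- classify_tss(called, sim$annotation)
  }
  .sim_cache$classified_default
}
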