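# Small simulation configuration shared by unit tests (fast to generate),
# and a lazily built cached instance.

small_config <- function(...) {
  sim_config(n_rgene_families = 6, n_background = 120, n_chromosomes = 2,
             n_hidden_per_species = 1,
             background_codons = c(150, 250), ...)
}

.test_env <- new.env()

small_sim <- function() {
  if (is.null(.test_env$sim)) {
    set.seed(101)
    .test_env$sim <- simulate_dataset(small_config())
  }
  .test_env$sim
}
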