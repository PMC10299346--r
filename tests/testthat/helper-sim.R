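# Shared simulated fixtures, built once per test session.

.sim_cache <- new.env(parent = emptyenv())

# small genome used by most module tests
test_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(n_families = 30L, seed = 7L)
    .sim_cache$small <- c(simulate_genome(cfg), list(config = cfg))
  }
  .sim_cache$small
}

test_analysis <- function() {
  if (is.null(.sim_cache$small_analysis)) {
    sim <- test_sim()
    .sim_cache$small_analysis <- analyze_genome(sim$genes)
  }
  .sim_cache$small_analysis
}

# default-size genome used by the acceptance property suite
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    cfg <- sim_config(seed = 20260101L)
    .sim_cache$default <- c(simulate_genome(cfg), list(config = cfg))
  }
  .sim_cache$default
}

default_analysis <- function() {
  if (is.null(.sim_cache$default_analysis)) {
    sim <- default_sim()
    .sim_cache$default_analysis <- analyze_genome(sim$genes)
  }
  .sim_cache$default_analysis
}

# map predicted families onto truth: majority true family per predicted family
family_truth_match <- function(families, truth) {
  merged <- merge(families, truth[, c("gene_id", "family_id")],
                  by = "gene_id", suffixes = c("_pred", "_true"))
  merged
}
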