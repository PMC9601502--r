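# Shortcuts used across test files.

example_species <- function(name, sp) {
  dplyr::filter(ddpcr_example(name), species == sp)
}

pork_pair <- c(target = "pork", reference = "beef")
chicken_pair <- c(target = "chicken", reference = "beef")

# Noise-free configuration: expected-value partitions, no replicate noise.
# The whole pipeline becomes a deterministic closed-form oracle under it.
noiseless_config <- function(k_true = 1.19, c_target = 300, ...) {
  sim_config(c_target = c_target, k_true = k_true, replicate_cv = 0,
             sampling = "expected", ...)
}
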