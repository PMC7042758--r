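# Shared fixtures, built in code.

# The study's parasite infection table: breeding populations (Northern,
# Central, Southern) and wintering areas x the five Plasmodium lineages
# (SYBOR21, GRW02, GRW09, LINOLI1, PSEGRI1).
table3_parasites <- function() {
  G_b <- rbind(Northern = c(0, 0, 1, 1, 1),
               Central = c(12, 16, 18, 0, 0),
               Southern = c(1, 5, 8, 0, 0))
  H_b <- matrix(c(50, 435, 90), 3, 5)
  G_nb <- rbind(Western = c(1, 6, 1, 0, 0),
                Central = c(0, 1, 74, 2, 22),
                Eastern = c(0, 0, 26, 1, 0),
                Southern = c(0, 2, 0, 34, 0))
  H_nb <- matrix(c(803, 2767, 506, 660), 4, 5)
  parasite_data(G_nb, H_nb, G_b, H_b)
}

# A small, fully in-support state for likelihood tests
small_state <- function(seed = 1) {
  set.seed(seed)
  sample_prior_state()
}

# A valid random simplex row
random_simplex <- function(n = 4) {
  x <- stats::rgamma(n, 1)
  x / sum(x)
}

tiny_sampler <- function(seed = 1, n_iter = 3000, burn_in = 1500, thin = 3,
                         n_chains = 2) {
  sampler_config(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = seed)
}
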