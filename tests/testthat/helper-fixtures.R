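# Shared fixtures: the two published worked-example parameter sets that pass
# all theoretical discriminators, and a degenerate no-repair set.

fig_set_a <- function() mhr_params(alpha = 0.26, c_r = 7.76, c_e = 0.83,
                                   mu_gamma = 0.31, gamma = 0.31)

fig_set_b <- function() mhr_params(alpha = 0.88, c_r = 37.5, c_e = 21.0,
                                   mu_gamma = 0.46, gamma = 2.10)

no_repair_set <- function() mhr_params(alpha = 0.5, c_r = 0, c_e = 1,
                                       mu_gamma = 0, gamma = 1)

# Synthetic combined-calibration data from the worked-example truth.
truth_datasets <- function(seed = 101) {
  spec <- synthetic_spec(fig_set_a())
  list(spec = spec,
       survival = generate_survival(spec, seed = seed),
       comet = generate_comet(spec, seed = seed + 1L))
}
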