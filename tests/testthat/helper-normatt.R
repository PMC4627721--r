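# Shared fixtures, built in code.

# Coarse grids keep the simulation-heavy tests fast; the fine default grid
# is exercised explicitly where grid convergence is the point.
test_grid <- function() neuron_grid(dx = 0.5, dtheta = 2)
cv_grid <- function() neuron_grid(dx = 1, dtheta = 3)

# Printed best-fit parameter sets used as worked examples.
params_t2_fs <- function() model_params(n = 2.16, sigma = 0.0020, w_I = 0.80,
                                        w_x = 4.70, w_v = 5.03, p = 0.17,
                                        sigma_n = 3.11)
params_t2_es <- function() model_params(n = 2.01, sigma = 0.0019, w_I = 0.80,
                                        w_x = 2.41, w_v = 4.99, p = 0.31,
                                        sigma_n = 2.95)
params_t3_fs <- function() model_params(n = 1.95, sigma = 0.0016, w_I = 0.67,
                                        w_x = 4.24, w_v = 5.03, p = 0.13,
                                        sigma_n = 2.92)

# A small synthetic cohort: four observers at the group-level reference
# parameters, full five-condition design.
group_cohort_design <- function(trials_per_cell = 50, seed = 1) {
  study_design(
    observer_params = sapply(paste0("S", 1:4),
                             function(i) reference_params("group"),
                             simplify = FALSE),
    trials_per_cell = trials_per_cell, seed = seed)
}
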