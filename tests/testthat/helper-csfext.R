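# Shared fixtures, built in code.

# Noiseless dataset generated from known parameters on a factorial grid.
noiseless_dataset <- function(omega = 14.54, m = 12.10, slope = 0.1446,
                              intercept = -5.5595, family = "arrhenius",
                              t_grid = c(80, 90, 99, 105),
                              fa_grid = c(60, 70, 80, 90),
                              time_grid = c(0.25, 0.5, 1, 1.5),
                              component = "xylan_plus_lignin") {
  truth <- list(list(
    constants = severity_constants(omega, m, t_ref = 70),
    model = solubilization_model(family, slope, intercept)))
  names(truth) <- component
  cfg <- simulation_config(t_grid = t_grid, fa_grid = fa_grid,
                           time_grid = time_grid, truth = truth,
                           noise_sigma = 0, seed = 1L)
  simulate_alpha(cfg)
}

# The spec of the published xylan-plus-lignin Arrhenius convention,
# used as ground truth across fitting tests.
xpl_truth <- list(omega = 14.54, m = 12.10, slope = 0.1446,
                  intercept = -5.5595)
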