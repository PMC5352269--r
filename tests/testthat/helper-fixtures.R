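# shared fixtures: everything is generated in code at test time

# a square 4 ns IRF whose support [300, 4300] aligns exactly with the
# 25 ps bin edges, so closed-form gated-exponential results are exact
square_irf <- function() irf_profile(seq(312.5, 4287.5, 25), rep(1, 160))

# compact simulation settings for fast tests
test_config <- function(...) {
  args <- utils::modifyList(list(n_row = 16, n_col = 16, dye_dim = 16,
                                 n_cells = 4, cell_radius_px = 4),
                            list(...))
  do.call(sim_config, args)
}

# calibration carrying only the simulator's true IRF (no background products)
true_cal <- function(cfg = test_config(), t0 = 0) {
  flim_calibration(sim_true_irf(cfg), t0 = t0)
}

# noise-free single-condition stack with known per-pixel expectation
expected_stack <- function(cfg, tau1, tau2 = NULL, beta = 0, photons = 1000,
                           shift = 0) {
  d <- cfg$sample_delays
  m <- sim_unit_decay(cfg, d, tau1, tau2, beta, shift)
  counts <- array(rep(photons * m, each = cfg$n_row * cfg$n_col),
                  c(cfg$n_row, cfg$n_col, length(d)))
  flim_stack(counts, d, width_ps = cfg$gate_width_ps, well = "A1", fov = 1L)
}

# Poisson realization of an expectation cube
poissonize <- function(stack) {
  flim_stack(array(rpois(length(stack$counts), stack$counts),
                   dim(stack$counts)),
             stack$gates$delay_ps, width_ps = stack$gates$width_ps[1],
             integration_ms = stack$gates$integration_ms[1],
             n_accumulations = stack$gates$n_accumulations[1],
             well = stack$well, fov = stack$fov)
}
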