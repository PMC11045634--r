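# Shared fixtures: small grids and parameter sets used across test files.

grid_1d <- function(n = 64, lo = -1, hi = 1) make_grid(c(lo, hi), n)
grid_2d <- function(n = 16, lo = 0, hi = 1) make_grid(c(lo, hi), c(n, n))
grid_3d <- function(n = 16) make_grid(c(-0.05, 0.05), c(n, n, n))

# parameters with every reaction and transport channel off; individual tests
# switch on the single mechanism under scrutiny
quiet_params <- function(...) {
  model_params(D_E = 0, D_F = 0, D_b = 0, D_m = 0, chi_E = 0, chi_F = 0,
               rho_cE = 0, rho_cF = 0, rho_bF = 0, rho_mF = 0, rho_mE = 0,
               rho_vF = 0, lambda_F = 0, lambda_b = 0, lambda_m = 0,
               lambda_vM = 0, lambda_vE = 0, r_met = 0, lam_intra = 0,
               lam_cpp = 0, sigma = 0, ...)
}

# closed-form Barenblatt profile for u_t = Lap(u^2) in 1D
barenblatt_1d <- function(x, t, C) {
  t^(-1 / 3) * pmax(0, C - x^2 / (12 * t^(2 / 3)))
}

# compact 3D tumour state used by EMT tests: density 3 ball, TGF-beta zero
# inside the ball and uniform outside
tumour_state <- function(n = 16, b_hi = 0.01, radius = 0.015, seed = 1) {
  set.seed(seed)
  g <- grid_3d(n)
  cE <- spherical_tumor_ic(g, list(c(0, 0, 0)), radius, 3)
  ic <- tgf_mmp_ic(g, (cE > 0) * 1, b_hi = b_hi)
  list(grid = g,
       state = density_state(g, cE = cE, b = ic$b, m = ic$m,
                             v = directional_ecm(g)))
}
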