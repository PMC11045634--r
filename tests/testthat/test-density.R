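test_that("porous-medium term: degeneracy, flat fields, mass neutrality", {
  g <- grid_2d(16)
  expect_true(all(pme_divergence(array(0, g$shape), g, 1) == 0))
  expect_equal(pme_divergence(array(0.7, g$shape), g, 1), array(0, g$shape))
  set.seed(4)
  c0 <- array(runif(prod(g$shape)), g$shape)
  expect_lt(abs(sum(pme_divergence(c0, g, 2.5))) * g$cell_volume, 1e-13)
  expect_error(pme_divergence(c0 - 2, g, 1), "negative")
})

test_that("1D porous-medium front converges in L1 to the Barenblatt profile", {
  C <- 0.02
  errs <- vapply(c(64, 128, 256), function(n) {
    g <- grid_1d(n)
    x <- cell_centres(g, 1)
    u <- array(barenblatt_1d(x, 1, C), n)
    tau <- 1
    while (tau < 2 - 1e-12) {
      dt <- min(0.2 * g$spacing[1]^2 / (4 * max(u)), 2 - tau)
      # u_t = Lap(u^2) = div(2 u grad u): coefficient 2 in the c*grad(c) form
      u <- u + dt * pme_divergence(u, g, 2)
      tau <- tau + dt
    }
    sum(abs(u - barenblatt_1d(x, 2, C))) * g$spacing[1]
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 2)
})

test_that("haptotaxis: flat matrix inert, drift speed chi, mass conserved", {
  g <- grid_2d(32)
  set.seed(2)
  c0 <- array(0, g$shape); c0[14:18, 14:18] <- runif(25) + 0.5
  expect_true(all(haptotaxis_divergence(c0, array(1, g$shape), g, 1e-2) == 0))
  v <- coord_field(g, function(x, y) x)
  chi <- 5e-3
  dt <- 1e-2
  x <- cell_centres(g, 1)
  com <- function(f) sum(f * coord_field(g, function(x, y) x)) / sum(f)
  c1 <- c0 + dt * haptotaxis_divergence(c0, v, g, chi, sign = 1)
  expect_equal(com(c1) - com(c0), chi * dt, tolerance = 0.05)
  # down-gradient for the fibroblast sign
  c2 <- c0 + dt * haptotaxis_divergence(c0, v, g, chi, sign = -1)
  expect_lt(com(c2), com(c0))
  expect_lt(abs(sum(c1) - sum(c0)) / sum(c0), 1e-12)
})

test_that("reaction kinetics match their closed forms", {
  g <- grid_2d(4)
  zero <- density_state(g)
  r0 <- reactions(zero, model_params())
  for (f in r0) expect_true(all(f == 0))
  # logistic epithelial growth at the published rate
  p <- quiet_params(rho_cE = 1.2)
  st <- density_state(g, cE = 0.1)
  dt <- 1e-4
  for (i in seq_len(5000)) st <- step_density(st, p, dt)
  t <- 5000 * dt
  expect_equal(st$cE[1, 1], 0.1 / (0.1 + 0.9 * exp(-1.2 * t)),
               tolerance = 1e-4)
  # exponential MMP decay
  p2 <- quiet_params(lambda_m = 2.62e-2)
  st2 <- density_state(g, m = 0.5)
  for (i in seq_len(200)) st2 <- step_density(st2, p2, 1e-2)
  expect_equal(st2$m[2, 2], 0.5 * exp(-2.62e-2 * 2), tolerance = 1e-4)
  # matrix decays at lambda_vM inside a stationary agent footprint only
  g3 <- grid_3d(8)
  p3 <- quiet_params(lambda_vM = 2)
  st3 <- density_state(g3, v = 1)
  cells <- cell_set(matrix(c(0, 0, 0), 1), 1e-9)
  fp <- footprint_indicator(cells, g3, K = g3$spacing[1] / 2)
  expect_equal(sum(fp), 1)
  for (i in seq_len(100)) st3 <- step_density(st3, p3, 1e-3, footprint = fp)
  inside <- fp > 0
  expect_equal(unique(st3$v[inside]), 1 * exp(-2 * 0.1), tolerance = 1e-3)
  expect_true(all(st3$v[!inside] == 1))
})

test_that("stable_dt honours the diffusion, advection and reaction limits", {
  g <- grid_3d(16)
  expect_equal(stable_dt(density_state(g), model_params()),
               model_params()$dt_max)
  # TGF-beta diffusion is the stiffest channel on a uniform state (cap lifted
  # so the scaling with h is visible)
  p <- model_params(dt_max = 10)
  st <- density_state(g, v = directional_ecm(g))
  h <- g$spacing[1]
  expect_lte(stable_dt(st, p), 0.4 * h^2 / (6 * p$D_b) * (1 + 1e-12))
  # refining the grid twice cuts the diffusive step by >= 4
  g2 <- grid_3d(32)
  st2 <- density_state(g2, v = directional_ecm(g2))
  expect_lte(stable_dt(st2, p), stable_dt(st, p) / 4 * (1 + 1e-12))
})

test_that("step_density: zero state absorbing, transport conserves mass", {
  g <- grid_2d(16)
  p <- model_params()
  st <- step_density(density_state(g), p, 1e-3)
  for (f in c("cE", "cF", "b", "m", "v")) expect_true(all(st[[f]] == 0))
  # 100 steps of pure diffusion + haptotaxis
  set.seed(9)
  c0 <- array(0, g$shape); c0[6:10, 6:10] <- runif(25)
  v <- coord_field(g, function(x, y) x + 0.5 * y)
  pt <- quiet_params(D_E = 1e-3, chi_E = 1e-3)
  st <- density_state(g, cE = c0, v = v)
  m0 <- field_mass(st$cE, g)
  for (i in seq_len(100)) st <- step_density(st, pt, 5e-3)
  expect_lt(abs(field_mass(st$cE, g) - m0) / m0, 1e-10)
  expect_true(all(st$cE >= 0))
})

test_that("degenerate diffusion keeps fronts compact; linear diffusion does not", {
  g <- grid_1d(64, 0, 1)
  u0 <- array(0, 64); u0[30:34] <- 1
  p <- quiet_params(D_E = 1e-2)
  run <- function(linear) {
    st <- density_state(g, cE = u0)
    lohi <- NULL
    for (i in seq_len(200)) {
      st <- step_density(st, p, 4e-3, linear_diffusion = linear)
      s <- which(st$cE > 0)
      lohi <- rbind(lohi, c(min(s), max(s)))
    }
    list(st = st, lohi = lohi)
  }
  pme <- run(FALSE)
  heat <- run(TRUE)
  # each support edge of the degenerate front moves at most one cell per step
  expect_lte(max(abs(diff(pme$lohi[, 1]))), 1)
  expect_lte(max(abs(diff(pme$lohi[, 2]))), 1)
  expect_lt(support_width(pme$st$cE)[1], 64)   # still compactly supported
  expect_true(all(heat$st$cE > 0))             # heat variant fills the domain
})

test_that("constant-mobility validation mode tracks the heat kernel", {
  # Gaussian spreading under linear diffusion: variance grows by 2 D t
  g <- grid_1d(128, -1, 1)
  x <- cell_centres(g, 1)
  s0 <- 0.1
  u <- array(exp(-x^2 / (2 * s0^2)), 128)
  D <- 1e-2
  p <- quiet_params(D_E = D)
  st <- density_state(g, cE = u)
  t_end <- 0.25
  dt <- 2e-4
  for (i in seq_len(t_end / dt)) st <- step_density(st, p, dt,
                                                    linear_diffusion = TRUE)
  s2 <- s0^2 + 2 * D * t_end
  exact <- s0 / sqrt(s2) * exp(-x^2 / (2 * s2))
  expect_lt(max(abs(st$cE - exact)), 5e-3)
})

test_that("numerical blow-up is reported with the offending field", {
  g <- grid_2d(8)
  st <- density_state(g, cE = 1)
  p <- quiet_params(rho_cE = 1)
  st$cE[1, 1] <- 1e308
  expect_error(step_density(st, p, 1e300), "cE")
})
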