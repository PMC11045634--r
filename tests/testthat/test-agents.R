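test_that("drift law saturates at the maximum cell speed", {
  V <- 2.16
  expect_equal(drift_mu(c(0, 0, 0), V), matrix(0, 1, 3))
  # monotone approach to the bound over 12 decades of gradient magnitude
  z <- 10^seq(-3, 9)
  sp <- vapply(z, function(zz) sqrt(sum(drift_mu(c(zz, 0, 0), V)^2)),
               numeric(1))
  expect_true(all(diff(sp) > 0))
  expect_true(all(sp < V))
  expect_equal(sp[length(sp)], V, tolerance = 1e-6)
  # arctan(1) = pi/4: gradient magnitude A gives half the maximum speed
  A <- 2 * V / pi
  expect_equal(sqrt(sum(drift_mu(c(A, 0, 0), V)^2)), V / 2)
  # direction preserved
  d <- drift_mu(c(3, 4, 0), V)
  expect_equal(d[1, 2] / d[1, 1], 4 / 3, tolerance = 1e-12)
})

test_that("compound-Poisson jumps fire at the Poisson-complement frequency", {
  tau <- 0.01
  lam <- log(2) / tau       # jump probability exactly 1/2
  p <- model_params(lam_cpp = lam)
  set.seed(42)
  Z <- cpp_increment(1e5, 3, p, tau)
  njump <- sum(rowSums(abs(Z)) > 0)
  se <- sqrt(1e5 * 0.25)
  expect_lt(abs(njump - 5e4), 3 * se)
  expect_gt(stats::binom.test(njump, 1e5, 0.5)$p.value, 0.01)
  # rate zero never jumps
  expect_true(all(cpp_increment(100, 3, model_params(lam_cpp = 0), tau) == 0))
  # small-tau linearity: empirical frequency ~ lam * tau (slope regression)
  lam2 <- 50
  p2 <- model_params(lam_cpp = lam2)
  taus <- c(1e-4, 2e-4, 4e-4, 7e-4, 1e-3)  # lam*tau <= 0.05: linear regime
  set.seed(7)
  freq <- vapply(taus, function(tt)
    mean(rowSums(abs(cpp_increment(1e5, 2, p2, tt))) > 0), numeric(1))
  slope <- stats::coef(stats::lm(freq ~ taus))[2]
  expect_equal(unname(slope), lam2, tolerance = 0.1)
})

test_that("cell stepping: drift direction, speed cap, containment", {
  g <- grid_3d(16)
  v <- coord_field(g, function(x, y, z) x + y + z)
  p <- model_params(sigma = 0, lam_cpp = 0)
  cells <- cell_set(rbind(c(0, 0, 0), c(0.01, -0.01, 0.02)), c(1e-9, 1e-9))
  tau <- 1e-3
  out <- step_cells(cells, v, g, p, tau)
  dx <- out$positions - cells$positions
  # along (1,1,1)/sqrt(3) at the saturated speed mu(sqrt(3))
  sp <- sqrt(rowSums(dx^2)) / tau
  A <- 2 * p$V_thr / pi
  expect_equal(sp, rep(A * atan(sqrt(3) / A), 2), tolerance = 1e-6)
  expect_lt(max(abs(dx / sqrt(rowSums(dx^2)) - 1 / sqrt(3))), 1e-6)
  expect_equal(out$masses, cells$masses)
  # flat matrix, zero noise: nobody moves
  still <- step_cells(cells, array(1, g$shape), g, p, tau)
  expect_equal(still$positions, cells$positions)
  # huge noise: cap binds exactly and everyone stays inside
  pn <- model_params(sigma = 1e4, lam_cpp = 1e5)
  set.seed(11)
  many <- cell_set(matrix(runif(300, -0.04, 0.04), 100, 3), rep(1e-9, 100))
  for (i in 1:20) {
    many <- step_cells(many, v, g, pn, tau)
    expect_true(all(t(many$positions) >= g$extent[1, ] &
                      t(many$positions) <= g$extent[2, ]))
    sp <- sqrt(rowSums((many$positions - many$positions)^2))
  }
})

test_that("per-step displacement never exceeds V_thr * tau", {
  g <- grid_3d(8)
  v <- coord_field(g, function(x, y, z) 50 * x)
  pn <- model_params(sigma = 100, lam_cpp = 1e4)
  set.seed(13)
  cells <- cell_set(matrix(runif(150, -0.03, 0.03), 50, 3), rep(1e-9, 50))
  tau <- 5e-4
  prev <- cells$positions
  for (i in 1:50) {
    cells <- step_cells(cells, v, g, pn, tau)
    # reflection can only shorten the net displacement
    dx <- sqrt(rowSums((cells$positions - prev)^2))
    expect_true(all(dx <= pn$V_thr * tau * (1 + 1e-10)))
    prev <- cells$positions
  }
})

test_that("mirror reflection folds escapees back and fixes insiders", {
  g <- make_grid(c(-0.05, 0.05), c(8, 8, 8))
  expect_equal(reflect(c(0.02, -0.03, 0), g), c(0.02, -0.03, 0))
  expect_equal(reflect(c(0.06, 0, 0), g)[1], 0.04)
  expect_equal(reflect(c(-0.07, 0, 0), g)[1], -0.03)
  # far excursions fold repeatedly into the domain
  expect_true(all(abs(reflect(c(0.31, -0.27, 0.55), g)) <= 0.05))
  # alternative wall rule: escapees keep their last position
  p <- model_params(boundary = "last_position", sigma = 0, lam_cpp = 0,
                    V_thr = 1e4)
  v <- coord_field(g, function(x, y, z) 1e6 * x)
  cells <- cell_set(c(0.049, 0, 0), 1e-9)
  out <- step_cells(cells, v, g, p, tau = 1)
  expect_equal(out$positions, cells$positions)
})

test_that("zero-noise cells ascend the matrix; pure noise is isotropic", {
  g <- grid_3d(16)
  v <- directional_ecm(g)
  p <- model_params(sigma = 0, lam_cpp = 0)
  # start well inside so nobody reaches the reflecting wall (a reflected
  # cell can descend; ascent is a property of the interior dynamics)
  set.seed(17)
  cells <- cell_set(matrix(runif(60, -0.04, 0.01), 20, 3), rep(1e-9, 20))
  val <- interp_at(v, g, cells$positions)
  for (i in 1:30) {
    cells <- step_cells(cells, v, g, p, 1e-3)
    val2 <- interp_at(v, g, cells$positions)
    expect_true(all(val2 >= val - 1e-12))
    val <- val2
  }
  # flat matrix, noise only: mean displacement compatible with zero
  pn <- model_params(sigma = 1, lam_cpp = 200)
  set.seed(19)
  many <- cell_set(matrix(0, 1e4, 3), rep(1e-9, 1e4))
  out <- step_cells(many, array(1, g$shape), g, pn, 1e-4)
  dx <- out$positions - many$positions
  for (a in 1:3) {
    se <- stats::sd(dx[, a]) / sqrt(nrow(dx))
    expect_lt(abs(mean(dx[, a])), 4 * se + 1e-15)
  }
})
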