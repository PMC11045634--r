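test_that("EMT rate is a shifted logistic with ceiling L", {
  p <- model_params(L = 0.05, k = 1e3, b_T = 0.01)
  expect_equal(emt_rate(0.01, p), 0.05 / 2)          # midpoint at threshold
  expect_equal(emt_rate(1.01, p), 0.05, tolerance = 1e-12)
  expect_lt(emt_rate(0, p), 0.05 * exp(-1e3 * 0.01) * 1.01)
  b <- seq(0, 0.05, by = 1e-3)
  expect_true(all(diff(emt_rate(b, p)) >= 0))        # saturates in the tail
  expect_true(all(diff(emt_rate(seq(0, 0.02, 1e-3), p)) > 0))
  # published defaults: ceiling 5e-3 per day
  expect_equal(emt_rate(1, model_params()), 5e-3, tolerance = 1e-9)
})

test_that("EMT sampling respects the density gate and the Poisson law", {
  g <- grid_3d(8)
  part <- make_partition(g, 2L)
  # gate: no eligible block -> no events no matter the signal
  set.seed(1)
  lowE <- array(0.01, g$shape)
  b_hi <- array(1, g$shape)
  ev <- sample_emt_events(lowE, b_hi, part, model_params(), tau = 100)
  expect_true(all(ev == 0))
  # no signal: essentially no events even on eligible blocks
  highE <- array(1, g$shape)
  ev0 <- replicate(50, sum(sample_emt_events(highE, array(0, g$shape), part,
                                             model_params(), tau = 1)))
  expect_equal(sum(ev0), 0)
  # single eligible block with intensity 2: Poisson moments
  g1 <- make_grid(c(0, 1), c(4, 4))
  p1 <- make_partition(g1, 4L)
  pL <- model_params(L = 4, k = 0, b_T = 0)      # zeta = L/2 = 2 everywhere
  cE1 <- array(1e6, g1$shape)                    # cap never binds
  set.seed(2)
  draws <- replicate(4000, sum(sample_emt_events(cE1, array(0, g1$shape),
                                                 p1, pL, tau = 1)))
  expect_lt(abs(mean(draws) - 2), 3 * sqrt(2 / 4000))
  expect_lt(abs(stats::var(draws) - 2), 0.3)
  # cap: converted mass never exceeds the block's epithelial mass
  pcap <- model_params(L = 1e4, k = 0, b_T = 0, C_ref = 0.1, m_cell = NA)
  cE2 <- array(0.2, g1$shape)
  set.seed(3)
  evc <- sample_emt_events(cE2, array(1, g1$shape), p1, pcap, tau = 10)
  pr <- metastasim:::resolve_params(pcap, p1)
  expect_true(all(evc * pr$m_cell <= 0.2 * p1$m_volume + 1e-15))
})

test_that("raising TGF-beta never decreases expected EMT events", {
  g <- grid_3d(8)
  part <- make_partition(g, 2L)
  p <- model_params(L = 0.5, k = 500, b_T = 5e-3)
  cE <- array(1, g$shape)
  means <- vapply(c(0, 2e-3, 5e-3, 1e-2, 5e-2), function(bv) {
    set.seed(9)
    mean(replicate(200, sum(sample_emt_events(cE, array(bv, g$shape), part,
                                              p, tau = 1))))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("EMT conversion conserves mass and creates rim agents", {
  tc <- tumour_state(16, radius = 0.015)
  part <- make_partition(tc$grid, 2L)
  p <- model_params(L = 50, k = 1e6, b_T = 1e-3)   # high rate: events certain
  cells <- cell_set(matrix(numeric(0), 0, 3), numeric(0))
  set.seed(4)
  ev <- sample_emt_events(tc$state$cE, tc$state$b, part, p, tau = 1)
  expect_gt(sum(ev), 0)
  tot0 <- field_mass(tc$state$cE, tc$grid)
  res <- apply_emt(tc$state, cells, ev, p, part)
  tot1 <- field_mass(res$state$cE, tc$grid) + sum(res$cells$masses)
  expect_lt(abs(tot1 - tot0) / tot0, 1e-12)
  expect_equal(length(res$cells$ids), sum(ev))
  expect_true(all(res$state$cE >= 0))
  # zero events: identity
  id0 <- apply_emt(tc$state, cells, array(0L, dim = part$m_shape), p, part)
  expect_identical(id0$state$cE, tc$state$cE)
  # events only on blocks straddling the tumour rim (TGF-beta is zero
  # inside, the density gate fails outside)
  interior <- apply(array((tc$state$cE > 0),
                          dim = as.vector(rbind(part$factor, part$m_shape))),
                    c(2, 4, 6), all)
  expect_equal(sum(ev[interior]), 0)
})

test_that("MET flags follow the Poisson-complement probability", {
  p <- model_params(r_met = log(2))
  set.seed(5)
  cells <- cell_set(matrix(0, 1e5, 3), rep(1e-9, 1e5))
  ids <- sample_met(cells, p, tau = 1)
  expect_gt(stats::binom.test(length(ids), 1e5, 0.5)$p.value, 1e-4)
  expect_length(sample_met(cells, model_params(r_met = 0), 1), 0)
  # published rate, small step: expected count r*tau*n
  p2 <- model_params()   # r = 0.1/d
  set.seed(6)
  hits <- 0
  for (i in 1:10) hits <- hits + length(sample_met(cells, p2, tau = 1e-3))
  expect_lt(abs(hits - 100), 3 * sqrt(100))
  # empty population: nothing to flag
  none <- cell_set(matrix(numeric(0), 0, 3), numeric(0))
  expect_length(sample_met(none, p, 1), 0)
})

test_that("MET deposition conserves mass and respects geometry", {
  g <- grid_2d(16)
  part <- make_partition(g, 4L)
  p <- model_params()
  # one cell wholly inside one block
  cells <- cell_set(c(0.125, 0.375), 5e-9)
  st <- density_state(g)
  res <- apply_met(st, cells, cells$ids, p, part)
  expect_equal(length(res$cells$ids), 0)
  expect_equal(field_mass(res$state$cE, g), 5e-9, tolerance = 1e-22)
  expect_equal(max(res$state$cE), 5e-9 / part$m_volume)
  # identity on empty id set
  res0 <- apply_met(st, cells, integer(0), p, part)
  expect_identical(res0$state$cE, st$cE)
  expect_error(apply_met(st, cells, 99L, p, part), "unknown")
})

test_that("joint mass is invariant under long EMT/MET alternation", {
  tc <- tumour_state(8, radius = 0.02)
  part <- make_partition(tc$grid, 2L)
  p <- model_params(L = 20, k = 1e6, b_T = 1e-3, r_met = 5)
  cells <- cell_set(matrix(numeric(0), 0, 3), numeric(0))
  st <- tc$state
  tot0 <- field_mass(st$cE, tc$grid)
  set.seed(7)
  for (i in seq_len(300)) {
    ev <- sample_emt_events(st$cE, st$b, part, p, tau = 0.1)
    r <- apply_emt(st, cells, ev, p, part)
    st <- r$state; cells <- r$cells
    ids <- sample_met(cells, p, tau = 0.1)
    r <- apply_met(st, cells, ids, p, part)
    st <- r$state; cells <- r$cells
  }
  tot <- field_mass(st$cE, tc$grid) + sum(cells$masses)
  expect_lt(abs(tot - tot0) / tot0, 1e-12)
  # ids are never reused
  expect_equal(anyDuplicated(cells$ids), 0)
})
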