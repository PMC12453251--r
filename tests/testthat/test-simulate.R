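test_that("pure transport conserves cell mass and leaks protein mass monotonically", {
  g <- quick_grid(n = 21, dt = 0.05)
  p <- transport_only_params(g)
  sim <- oa_simulate(p, NULL, end_age = 50 + 1000 * g$dt_days / 365,
                     grid = grid_spec(21, dt = 0.05), record_every_days = 5)
  stopifnot(length(sim$times) > 3)
  mass <- function(s) apply(sim$profiles[, match(s, c("C", "Cs", "Ch", "Cc",
                                                      "MP", "L2", "D")), ],
                            2, trap_mass, dx = g$dx)
  for (s in c("C", "Cs", "Ch")) {
    m <- mass(s)
    expect_lt(max(abs(m - m[1])) / m[1], 1e-8)
  }
  expect_equal(mass("Cc"), rep(mass("Cc")[1], length(sim$times)))  # immobile
  for (s in c("MP", "L2", "D")) {
    m <- mass(s)
    expect_true(all(diff(m) < 0), label = paste(s, "mass decreasing"))
  }
})

test_that("the time stepper agrees with an independent stiff ODE integration", {
  skip_if_not_installed("deSolve")
  g <- grid_spec(n_nodes = 9, dt_days = 0.01)
  p <- oa_params("female")
  sched <- dose_schedule("D", d_dose_days = c(0, 10), start_age = 50,
                         end_age = 51)
  days <- 11  # one day after the second dose, past the initial transient
  # independent route: method-of-lines RHS assembled from the package's
  # reaction and Laplacian primitives, integrated by deSolve::lsoda
  rhs <- function(t, y, parms) {
    m <- matrix(pmax(y, 0), ncol = 7)
    st <- species_state(g$x, m[, 1], m[, 2], m[, 3], m[, 4],
                        m[, 5], m[, 6], m[, 7])
    rt <- reaction_terms(st, t, p, u2_input = 0,
                         d_input = p$gamma_D * h_d(t, sched, p$mu_D))
    lap <- function(v, kind, delta)
      laplacian_with_bc(v, kind, g, delta, p$bc_leak_alpha)
    dCh <- rt$Ch + lap(m[, 3], "cell", p$delta_C)
    list(c(rt$C + lap(m[, 1], "cell", p$delta_C),
           rt$Cs + lap(m[, 2], "cell", p$delta_C),
           dCh,
           p$lambda_ChCc * dCh,
           rt$MP + lap(m[, 5], "protein_or_drug", p$delta_MP),
           rt$L2 + lap(m[, 6], "protein_or_drug", p$delta_L2),
           rt$D + lap(m[, 7], "protein_or_drug", p$delta_D)))
  }
  st0 <- initial_state(g$x)
  y0 <- as.vector(sapply(c("C", "Cs", "Ch", "Cc", "MP", "L2", "D"),
                         function(s) st0[[s]]))
  ode <- deSolve::lsoda(y0, c(0, days), rhs, NULL, rtol = 1e-9, atol = 1e-14)
  ref <- matrix(ode[2, -1], ncol = 7)

  sim <- oa_simulate(p, sched, end_age = 50 + days / 365, grid = g,
                     record_every_days = days)
  got <- sim$profiles[, , length(sim$times)]
  for (s in seq_len(7)) {
    denom <- max(abs(ref[, s]), 1e-12)
    # Cc integrates the (clipped) transient; compare it more loosely
    tol <- if (s == 4) 0.05 else 5e-3
    expect_lt(max(abs(got[, s] - pmax(ref[, s], 0))) / denom, tol,
              label = paste("species", s))
  }
})

test_that("halving the time step moves recorded averages by less than 0.1%", {
  p <- oa_params("female")
  sim1 <- oa_simulate(p, NULL, end_age = 55, grid = grid_spec(21, dt = 0.05),
                      record_every_days = 365)
  sim2 <- oa_simulate(p, NULL, end_age = 55, grid = grid_spec(21, dt = 0.025),
                      record_every_days = 365)
  a1 <- sim1$averages[-1, ]
  a2 <- sim2$averages[-1, ]
  for (s in c("C", "Cs", "Ch", "Cc", "L2"))
    expect_lt(max(abs(a1[, s] - a2[, s]) / pmax(abs(a2[, s]), 1e-12)),
              1e-3, label = s)
})

test_that("grid refinement from 21 to 41 nodes changes averages by under 1%", {
  p <- oa_params("male")
  sim1 <- oa_simulate(p, NULL, end_age = 60, grid = grid_spec(21),
                      record_every_days = 365)
  sim2 <- oa_simulate(p, NULL, end_age = 60, grid = grid_spec(41),
                      record_every_days = 365)
  for (s in c("C", "Cs", "Ch", "Cc", "L2"))
    expect_lt(max(abs(sim1$averages[-1, s] - sim2$averages[-1, s]) /
                    pmax(abs(sim2$averages[-1, s]), 1e-15)),
              0.01, label = s)
})

test_that("identical inputs give bitwise-identical trajectories", {
  p <- oa_params("female")
  sched <- make_schedule("fisetin_weekly_2d", 50, 52)
  s1 <- oa_simulate(p, sched, end_age = 52, grid = quick_grid(),
                    record_every_days = 30)
  s2 <- oa_simulate(p, sched, end_age = 52, grid = quick_grid(),
                    record_every_days = 30)
  expect_identical(s1$averages, s2$averages)
  expect_identical(s1$profiles, s2$profiles)
})

test_that("recording density does not alter the solution", {
  p <- oa_params("male")
  s1 <- oa_simulate(p, NULL, end_age = 51, grid = quick_grid(),
                    record_every_days = 365)
  s2 <- oa_simulate(p, NULL, end_age = 51, grid = quick_grid(),
                    record_every_days = 5)
  expect_identical(s1$averages[nrow(s1$averages), ],
                   s2$averages[nrow(s2$averages), ])
})

test_that("recorded averages are the trapezoidal means of the profiles", {
  sim <- oa_simulate(oa_params(), NULL, end_age = 51, grid = quick_grid(),
                     record_every_days = 73)
  dx <- diff(sim$x_grid[1:2])
  h <- max(sim$x_grid)
  for (k in seq_along(sim$times)) {
    m <- apply(sim$profiles[, , k], 2, trap_mass, dx = dx) / h
    expect_equal(unname(sim$averages[k, ]), m, tolerance = 1e-12)
  }
})

test_that("untreated disease progresses: chondrocytes fall, calcification rises", {
  sim <- oa_simulate(oa_params("male"), NULL, end_age = 90,
                     grid = grid_spec(21), record_every_days = 365)
  cavg <- sim$averages[, "C"]
  ccavg <- sim$averages[, "Cc"]
  expect_lt(cavg[length(cavg)], cavg[1])
  expect_true(all(diff(cavg[-1]) <= 1e-12))        # decreasing after onset
  expect_true(all(diff(ccavg) >= -1e-12))          # non-decreasing
  expect_gt(ccavg[length(ccavg)], 0)
})

test_that("age bounds are enforced", {
  expect_error(oa_simulate(oa_params(), end_age = 95, grid = quick_grid()),
               "ages")
  expect_error(oa_simulate(oa_params(), start_age = 40, end_age = 60,
                           grid = quick_grid()), "ages")
})
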